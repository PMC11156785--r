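# Small programmatic fixtures shared across the suite.

# quick phantom configuration for unit tests (small grid, deterministic)
quick_config <- function(...) {
  phantom_config(height = 48, width = 48, ...)
}

# a clean (artifact- and noise-free) slice: every repetition equals truth
clean_slice <- function(seed = 1, n_reps = 12) {
  generate_slice(quick_config(dropout_prob = 0, flicker_prob = 0,
                              noise_sigma = 0, n_reps = n_reps),
                 seed = seed)
}

# hand-built ROI set on a tiny grid, for closed-form score checks
tiny_rois <- function(H = 8, W = 8) {
  m <- function(rows, cols) {
    x <- matrix(FALSE, H, W)
    x[rows, cols] <- TRUE
    x
  }
  roi_set(left_lobe = m(1:4, 1:4), right_lobe = m(1:4, 5:8),
          vessels = m(5:6, 1:2), lesions = m(5:6, 5:6),
          background = m(7:8, 5:8))
}

# stack with specified per-repetition constant values
const_stack <- function(values, H = 4, W = 4) {
  array(rep(values, each = H * W), dim = c(H, W, length(values)))
}

# random small stack for oracle-equivalence tests
random_stack <- function(V = 1000, N = 6, seed = 1) {
  set.seed(seed)
  array(runif(V * N, 0.1, 2), dim = c(V, 1, N))
}
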