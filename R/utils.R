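# Internal helpers shared across modules.

# denominator guard used by every ratio-type score
.EPS <- 1e-12

.guard_denom <- function(x, what) {
  if (!is.finite(x)) return(x)   # propagate; callers diagnose non-finite
  if (abs(x) <= .EPS) {
    warning(sprintf("near-zero denominator in %s; guarded with epsilon", what),
            call. = FALSE)
    x <- .EPS
  }
  x
}

.check_stack <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("stack must be an H x W x N array", call. = FALSE)
  if (!all(is.finite(stack)))
    stop("stack contains non-finite values", call. = FALSE)
  invisible(stack)
}

.check_mask <- function(mask, image, name) {
  if (is.null(mask)) stop(sprintf("ROI '%s' is missing", name), call. = FALSE)
  if (!identical(dim(mask), dim(image)[1:2]))
    stop(sprintf("ROI '%s' is not on the image grid", name), call. = FALSE)
  if (!any(mask))
    stop(sprintf("ROI '%s' is empty", name), call. = FALSE)
  invisible(mask)
}

# Moving-average box filter with edge-replicating padding; k odd.
box_blur <- function(m, k) {
  stopifnot(is.matrix(m), k >= 1, k %% 2 == 1)
  if (k == 1) return(m)
  r <- (k - 1L) / 2L
  H <- nrow(m); W <- ncol(m)
  # replicate-pad
  ri <- c(rep(1L, r), seq_len(H), rep(H, r))
  ci <- c(rep(1L, r), seq_len(W), rep(W, r))
  mp <- m[ri, ci, drop = FALSE]
  # separable box via cumulative sums along each dimension
  cs <- apply(mp, 2, cumsum)
  cs0 <- rbind(matrix(0, 1, ncol(cs)), cs)
  rows <- cs[k:(H + 2 * r), , drop = FALSE] - cs0[seq_len(H), , drop = FALSE]
  cs2 <- t(apply(rows, 1, cumsum))
  cs20 <- cbind(matrix(0, H, 1), cs2)
  (cs2[, k:(W + 2 * r), drop = FALSE] - cs20[, seq_len(W), drop = FALSE]) / (k * k)
}

# Bilinear up-sampling of a coarse matrix onto an H x W grid (used for the
# smooth dropout field).
bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  # map target pixel centres into source coordinates
  sy <- (seq_len(H) - 0.5) / H * (h - 1) + 1
  sx <- (seq_len(W) - 0.5) / W * (w - 1) + 1
  y0 <- pmin(pmax(floor(sy), 1), h - 1); fy <- sy - y0
  x0 <- pmin(pmax(floor(sx), 1), w - 1); fx <- sx - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0 + 1, x0, drop = FALSE]
  c <- m[y0, x0 + 1, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
  FY <- matrix(fy, H, W); FX <- matrix(fx, H, W, byrow = TRUE)
  a * (1 - FY) * (1 - FX) + b * FY * (1 - FX) + c * (1 - FY) * FX + d * FY * FX
}

# Row-wise quantile (linear interpolation between order statistics, type 7)
# for a V x N matrix; returns a length-V vector.
.row_quantile <- function(M, q) {
  V <- nrow(M); N <- ncol(M)
  sorted <- matrix(M[order(row(M), M)], nrow = V, byrow = TRUE)
  h <- (N - 1) * q / 100
  lo <- floor(h); fr <- h - lo
  v <- sorted[cbind(seq_len(V), lo + 1)]
  if (fr > 0) v <- v * (1 - fr) + sorted[cbind(seq_len(V), lo + 2)] * fr
  v
}
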