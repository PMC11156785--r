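#' Normalize a repetition stack
#'
#' One mean and one standard deviation are computed jointly over all N
#' images of the slice; the record is kept so predictions can be mapped
#' back to the intensity scale.
#'
#' @param stack H x W x N repetition stack with nonzero variance.
#' @return List with `stack` (normalized), `center` and `scale`.
#' @export
normalize_stack <- function(stack) {
  .check_stack(stack)
  mu <- mean(stack)
  sd <- stats::sd(as.vector(stack))
  if (sd == 0) stop("stack has zero variance", call. = FALSE)
  list(stack = (stack - mu) / sd, center = mu, scale = sd)
}

#' Invert a normalization record
#' @param image Normalized image or stack.
#' @param record Record from [normalize_stack()].
#' @return De-normalized array.
#' @export
denormalize <- function(image, record) {
  image * record$scale + record$center
}

#' Random translation/scaling augmentation of a slice
#'
#' Samples one translation (uniform within +/- `max_translate` of the
#' width/height) and one scale factor (uniform in `scale_range`) per slice
#' and applies them identically to all repetition images, the truth image
#' (when present) and every ROI mask. Images are resampled bilinearly with
#' zero fill outside the grid; masks are re-binarized at 0.5 after
#' interpolation. If a transform empties a required mask it is resampled
#' (up to `max_retries`), then an error is raised.
#'
#' @param slice A `phantom_slice` (or any list with `stack`, `rois`, and
#'   optionally `truth`).
#' @param max_translate Maximum shift as a fraction of each dimension.
#' @param scale_range Length-2 scale-factor interval.
#' @param max_retries Resampling attempts for degenerate transforms.
#' @return The transformed slice (same structure).
#' @export
augment_slice <- function(slice, max_translate = 0.1,
                          scale_range = c(0.90, 1.05), max_retries = 10) {
  d <- dim(slice$stack); H <- d[1]; W <- d[2]
  required <- c("left_lobe", "right_lobe", "vessels", "background")
  for (try in seq_len(max_retries)) {
    tx <- stats::runif(1, -max_translate, max_translate) * W
    ty <- stats::runif(1, -max_translate, max_translate) * H
    s <- stats::runif(1, scale_range[1], scale_range[2])
    out <- .apply_affine_slice(slice, ty, tx, s)
    ok <- all(vapply(required, function(nm) any(out$rois[[nm]]), logical(1)))
    if (ok) return(out)
  }
  stop("augmentation emptied a required ROI after repeated retries",
       call. = FALSE)
}

# scale about the image centre by s, then translate by (ty, tx)
.apply_affine_slice <- function(slice, ty, tx, s) {
  d <- dim(slice$stack); H <- d[1]; W <- d[2]; N <- d[3]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  sy <- cy + (yy - cy - ty) / s
  sx <- cx + (xx - cx - tx) / s

  sample_bilinear <- function(img) {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    get <- function(yi, xi) {
      v <- matrix(0, H, W)
      ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
      v[ok] <- img[cbind(yi[ok], xi[ok])]
      v
    }
    get(y0, x0) * (1 - fy) * (1 - fx) + get(y0 + 1, x0) * fy * (1 - fx) +
      get(y0, x0 + 1) * (1 - fy) * fx + get(y0 + 1, x0 + 1) * fy * fx
  }

  out <- slice
  for (n in seq_len(N)) out$stack[, , n] <- sample_bilinear(slice$stack[, , n])
  if (!is.null(slice$truth)) out$truth <- sample_bilinear(slice$truth)
  masks <- lapply(unclass(slice$rois), function(m)
    sample_bilinear(m * 1) > 0.5)
  out$rois <- structure(masks, class = "roi_set")
  out
}

#' Patient-wise train/test split
#'
#' Patients — never individual slices — are shuffled by the seed and
#' partitioned so that the training set holds `ceiling(train_frac *
#' n_patients)` patients. No patient contributes slices to both sets.
#'
#' @param dataset List of slices with `patient_id` set.
#' @param train_frac Fraction of patients assigned to training.
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` slice lists.
#' @export
split_patientwise <- function(dataset, train_frac = 0.8, seed = 1L) {
  ids <- vapply(dataset, function(s) s$patient_id, numeric(1))
  pts <- unique(ids)
  if (length(pts) < 2) stop("need at least 2 patients to split",
                            call. = FALSE)
  set.seed(seed)
  shuffled <- sample(pts)
  n_train <- ceiling(train_frac * length(pts))
  train_ids <- shuffled[seq_len(n_train)]
  list(train = dataset[ids %in% train_ids],
       test = dataset[!(ids %in% train_ids)])
}

#' Moving-window early-stopping rule
#'
#' Pure function of the per-epoch loss sequence: training stops once the
#' mean loss over the latest `window` epochs is not lower than the mean
#' over the `window` epochs before that (requires at least `2 * window`
#' epochs).
#'
#' @param losses Numeric vector of epoch losses, oldest first.
#' @param window Window length in epochs.
#' @return `TRUE` if the rule fires.
#' @export
early_stop <- function(losses, window) {
  stopifnot(window >= 1)
  n <- length(losses)
  if (n < 2 * window) return(FALSE)
  recent <- mean(losses[(n - window + 1):n])
  previous <- mean(losses[(n - 2 * window + 1):(n - window)])
  recent >= previous
}

#' Training configuration
#'
#' Two profiles: `"paper"` carries the full-scale hyperparameters (batch
#' 64, 3000 pretraining epochs, 100-epoch stopping window); `"desk"` is a
#' small-problem profile sized for CPU-scale phantom experiments.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param ... Named overrides of individual fields (`learning_rate`,
#'   `beta1`, `beta2`, `batch_size`, `pretrain_epochs`, `stop_window`,
#'   `max_epochs`, `augment`, `seed`).
#' @return Object of class `train_config`.
#' @export
train_config <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- list(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
              batch_size = 8, pretrain_epochs = 50, stop_window = 10,
              max_epochs = 60, augment = TRUE, seed = 1L,
              profile = profile)
  if (profile == "paper") {
    cfg$learning_rate <- 1e-4
    cfg$batch_size <- 64
    cfg$pretrain_epochs <- 3000
    cfg$stop_window <- 100
    cfg$max_epochs <- 10000
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop(sprintf("unknown field '%s'", nm),
                                  call. = FALSE)
    cfg[[nm]] <- over[[nm]]
  }
  stopifnot(cfg$learning_rate > 0, cfg$stop_window >= 1,
            cfg$batch_size >= 1, cfg$max_epochs >= 1)
  class(cfg) <- "train_config"
  cfg
}

# prepare per-slice training tensors once
.prep_slice <- function(slice, dirs_per_rep = 3) {
  nr <- normalize_stack(slice$stack)
  ref <- trace_reference(slice$stack, dirs_per_rep)
  list(x = nr$stack, record = nr[c("center", "scale")], rois = slice$rois,
       reference = ref, mip = mip(slice$stack))
}

# network output (linear, normalized space) -> nonnegative intensity image
.head_to_intensity <- function(o, record) {
  z <- o * record$scale + record$center
  y <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))   # softplus
  attr(y, "dsig") <- 1 / (1 + exp(-z)) * record$scale     # dy/do
  y
}

#' Fit the feature-guided artifact-correction network
#'
#' Trains a U-Net to map the N normalized repetition images of a slice to
#' one corrected image, in two stages mirroring the training protocol:
#' first pretraining against the trace-weighted reference under
#' mean-squared error, then feature-guided training minimizing the
#' composite loss of [total_loss()], with moving-window early stopping and
#' selection of the weights that achieved the lowest recorded epoch loss.
#' Optimization is Adam throughout.
#'
#' @param train_set List of slices (each with `stack` and `rois`).
#' @param val_set Optional held-out slices; when supplied, the early-
#'   stopping rule and the best-weights selection monitor the validation
#'   loss (computed without augmentation) instead of the training loss.
#' @param spec A [unet_spec()]; `in_channels` must equal N.
#' @param weights A [loss_weights()].
#' @param config A [train_config()].
#' @param dirs_per_rep Diffusion directions per repetition group, for the
#'   reference image.
#' @param verbose Print per-epoch losses?
#' @return Object of class `pulsenet` with elements `params` (best
#'   weights), `final_params`, `spec`, `weights`, `config`,
#'   `pretrain_history`, `history` (data frame of per-epoch loss terms,
#'   including `val` when a validation set is monitored), `best_epoch` and
#'   `n_params`.
#' @export
fit_pulsenet <- function(train_set, val_set = NULL, spec = unet_spec(),
                         weights = loss_weights(),
                         config = train_config("desk"),
                         dirs_per_rep = 3, verbose = FALSE) {
  stopifnot(length(train_set) >= 1, inherits(spec, "unet_spec"),
            inherits(config, "train_config"))
  set.seed(config$seed)
  prep0 <- lapply(train_set, .prep_slice, dirs_per_rep = dirs_per_rep)
  if (!is.null(val_set) && length(val_set) == 0) val_set <- NULL
  prep_val <- if (!is.null(val_set))
    lapply(val_set, .prep_slice, dirs_per_rep = dirs_per_rep)
  params <- unet_init(spec)
  n_par <- unet_n_params(params)

  # ---- stage 1: pretraining on the trace-weighted reference (MSE) ----
  state <- .adam_init(params)
  pre_hist <- numeric(0)
  for (ep in seq_len(config$pretrain_epochs)) {
    ord <- sample(length(prep0))
    ep_loss <- 0
    for (bstart in seq(1, length(ord), config$batch_size)) {
      bidx <- ord[bstart:min(bstart + config$batch_size - 1, length(ord))]
      acc <- NULL
      for (i in bidx) {
        sl <- prep0[[i]]
        fw <- unet_forward(params, sl$x, training = TRUE)
        target <- (sl$reference - sl$record$center) / sl$record$scale
        diff <- fw$out - target
        ep_loss <- ep_loss + mean(diff^2)
        dout <- 2 * diff / length(diff)
        acc <- .grad_accumulate(acc, unet_backward(params, fw$cache, dout),
                                scale = 1 / length(bidx))
      }
      upd <- .adam_step(params, acc, state, lr = config$learning_rate,
                        beta1 = config$beta1, beta2 = config$beta2)
      params <- upd$params; state <- upd$state
    }
    pre_hist <- c(pre_hist, ep_loss / length(prep0))
    if (verbose) message(sprintf("pretrain epoch %d: mse %.5f", ep,
                                 pre_hist[ep]))
  }

  # ---- stage 2: feature-guided training ----
  state <- .adam_init(params)
  hist <- list()
  losses <- numeric(0)
  best <- list(loss = Inf, params = params, epoch = 0L)
  for (ep in seq_len(config$max_epochs)) {
    prep <- if (config$augment)
      lapply(train_set, function(s)
        .prep_slice(augment_slice(s), dirs_per_rep)) else prep0
    ord <- sample(length(prep))
    terms <- c(dc = 0, cnr = 0, pa = 0, vd = 0, di = 0, pa2 = 0, xi = 0,
               total = 0)
    for (bstart in seq(1, length(ord), config$batch_size)) {
      bidx <- ord[bstart:min(bstart + config$batch_size - 1, length(ord))]
      acc <- NULL
      for (i in bidx) {
        sl <- prep[[i]]
        fw <- unet_forward(params, sl$x, training = TRUE)
        y <- .head_to_intensity(fw$out, sl$record)
        dsig <- attr(y, "dsig"); attr(y, "dsig") <- NULL
        lb <- total_loss(y, NULL, sl$reference, sl$rois,
                         weights, precomputed_mip = sl$mip)
        gy <- loss_gradient(y, NULL, sl$reference, sl$rois, weights)
        dout <- gy * dsig
        acc <- .grad_accumulate(acc, unet_backward(params, fw$cache, dout),
                                scale = 1 / length(bidx))
        for (nm in names(terms))
          terms[nm] <- terms[nm] + lb[[nm]] / length(prep)
      }
      upd <- .adam_step(params, acc, state, lr = config$learning_rate,
                        beta1 = config$beta1, beta2 = config$beta2)
      params <- upd$params; state <- upd$state
    }
    if (!is.finite(terms["total"]))
      stop("training aborted: non-finite epoch loss", call. = FALSE)
    monitored <- terms[["total"]]
    if (!is.null(prep_val)) {
      vl <- vapply(prep_val, function(sl) {
        fw <- unet_forward(params, sl$x, training = FALSE)
        y <- .head_to_intensity(fw$out, sl$record)
        attr(y, "dsig") <- NULL
        total_loss(y, NULL, sl$reference, sl$rois, weights,
                   precomputed_mip = sl$mip)$total
      }, numeric(1))
      monitored <- mean(vl)
      terms <- c(terms, val = monitored)
    }
    losses <- c(losses, monitored)
    hist[[ep]] <- c(epoch = ep, terms)
    if (verbose) message(sprintf("epoch %d: loss %.5f", ep, monitored))
    if (monitored < best$loss)
      best <- list(loss = monitored, params = params, epoch = ep)
    if (early_stop(losses, config$stop_window)) break
  }

  structure(list(params = best$params, final_params = params, spec = spec,
                 weights = weights, config = config,
                 pretrain_history = pre_hist,
                 history = as.data.frame(do.call(rbind, hist)),
                 best_epoch = best$epoch, n_params = n_par),
            class = "pulsenet")
}

#' Predict a corrected image from a repetition stack
#'
#' Normalizes the stack (per slice, matching training), runs the network,
#' and maps the output back to the nonnegative intensity scale via a
#' softplus applied after de-normalization.
#'
#' @param object A fitted `pulsenet`.
#' @param stack H x W x N repetition stack (N = `in_channels`).
#' @param ... Unused.
#' @return H x W nonnegative corrected image.
#' @export
predict.pulsenet <- function(object, stack, ...) {
  nr <- normalize_stack(stack)
  fw <- unet_forward(object$params, nr$stack, training = FALSE)
  y <- .head_to_intensity(fw$out, nr[c("center", "scale")])
  attr(y, "dsig") <- NULL
  y
}

#' @export
print.pulsenet <- function(x, ...) {
  cat(sprintf("pulsenet: U-Net depth %d, base %d channels, %d inputs (%s parameters)\n",
              x$spec$depth, x$spec$base_channels, x$spec$in_channels,
              format(x$n_params, big.mark = ",")))
  cat(sprintf("  pretrained %d epochs; feature-trained %d epochs (best at %d, loss %.5f)\n",
              length(x$pretrain_history), nrow(x$history), x$best_epoch,
              min(x$history$total)))
  invisible(x)
}

#' @export
summary.pulsenet <- function(object, ...) {
  cat("Feature-guided artifact-correction network\n\n")
  print(object)
  cat("\nLoss weights:\n")
  print(unlist(unclass(object$weights)))
  cat("\nFinal-epoch loss terms:\n")
  print(utils::tail(object$history, 1), row.names = FALSE)
  invisible(object)
}

#' @export
coef.pulsenet <- function(object, ...) {
  unlist(unclass(object$weights))
}

#' @export
plot.pulsenet <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$total, type = "l",
                 xlab = "epoch", ylab = "composite loss",
                 main = "Feature-guided training loss", ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}
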