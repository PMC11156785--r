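#' Trace-weighted reference image
#'
#' Builds the unprocessed trace-weighted reference from a repetition stack:
#' each consecutive group of `dirs_per_rep` images (one per diffusion
#' direction) is combined by a voxelwise geometric mean, and the group
#' results are averaged arithmetically. With the default acquisition of 4
#' repetitions x 3 orthogonal directions this is the conventional
#' direction-averaged trace image.
#'
#' @param stack H x W x N array of co-registered repetition images.
#' @param dirs_per_rep Number of diffusion directions per repetition group;
#'   `N` must be divisible by it.
#' @return H x W reference image (nonnegative).
#' @export
trace_reference <- function(stack, dirs_per_rep = 3) {
  .check_stack(stack)
  N <- dim(stack)[3]
  if (N %% dirs_per_rep != 0)
    stop(sprintf("N = %d not divisible by dirs_per_rep = %d", N,
                 dirs_per_rep), call. = FALSE)
  n_groups <- N / dirs_per_rep
  acc <- matrix(0, dim(stack)[1], dim(stack)[2])
  for (g in seq_len(n_groups)) {
    idx <- (g - 1) * dirs_per_rep + seq_len(dirs_per_rep)
    prod <- matrix(1, dim(stack)[1], dim(stack)[2])
    for (i in idx) prod <- prod * stack[, , i]
    acc <- acc + prod^(1 / dirs_per_rep)
  }
  acc / n_groups
}

#' Pulsation-artifact score (PA)
#'
#' Ratio of the mean intensity in the left liver lobe (R1) to the mean
#' intensity in the right liver lobe (R2). Pulsation-induced signal loss
#' darkens the left lobe, so lower values indicate a stronger artifact;
#' higher is better.
#'
#' @param image H x W image.
#' @param rois A [roi_set()].
#' @return Scalar ratio.
#' @export
pa_score <- function(image, rois) {
  .check_mask(rois$left_lobe, image, "left_lobe")
  .check_mask(rois$right_lobe, image, "right_lobe")
  mean(image[rois$left_lobe]) /
    .guard_denom(mean(image[rois$right_lobe]), "PA (right-lobe mean)")
}

#' Vessel-darkness score (VD)
#'
#' Mean background-parenchyma intensity divided by mean vessel intensity.
#' Vessels are dark in good diffusion images; brightened vessels (which risk
#' being mistaken for lesions) lower the score. Higher is better.
#'
#' @inheritParams pa_score
#' @return Scalar ratio.
#' @export
vd_score <- function(image, rois) {
  .check_mask(rois$vessels, image, "vessels")
  .check_mask(rois$background, image, "background")
  mean(image[rois$background]) /
    .guard_denom(mean(image[rois$vessels]), "VD (vessel mean)")
}

#' Lesion contrast-to-noise ratio (CNR)
#'
#' Difference between the mean lesion intensity and the mean background-
#' parenchyma intensity, divided by the standard deviation of the background
#' parenchyma. The denominator can collapse when an image becomes constant
#' over the liver, in which case the value is epsilon-guarded with a
#' warning.
#'
#' @inheritParams pa_score
#' @return Scalar ratio.
#' @export
cnr_score <- function(image, rois) {
  .check_mask(rois$lesions, image, "lesions")
  .check_mask(rois$background, image, "background")
  bg <- image[rois$background]
  if (length(bg) < 2) stop("background ROI needs >= 2 voxels", call. = FALSE)
  (mean(image[rois$lesions]) - mean(bg)) /
    .guard_denom(stats::sd(bg), "CNR (background standard deviation)")
}

#' Data-consistency score (DC)
#'
#' One minus the mean absolute deviation between the image and the
#' reference over the right liver lobe (the region not corrupted by the
#' pulsation artifact), relative to the mean reference intensity there;
#' floored at zero. Identical images score 1.
#'
#' @param image,reference H x W images on the same grid.
#' @param rois A [roi_set()].
#' @return Scalar in \[0, 1\].
#' @export
dc_score <- function(image, reference, rois) {
  if (!identical(dim(image), dim(reference)))
    stop("image and reference shapes differ", call. = FALSE)
  .check_mask(rois$right_lobe, image, "right_lobe")
  m <- rois$right_lobe
  ref_mean <- .guard_denom(mean(reference[m]), "DC (reference right-lobe mean)")
  max(0, 1 - mean(abs(image[m] - reference[m])) / ref_mean)
}

#' Raw feature scores of one image
#'
#' Convenience wrapper computing PA, VD, CNR (and DC when a reference is
#' supplied) in one call. CNR is reported as `NA` when the lesion mask is
#' empty.
#'
#' @inheritParams dc_score
#' @param reference Optional reference image for DC.
#' @return Named list `pa`, `vd`, `cnr`, and `dc` when `reference` given.
#' @export
feature_scores <- function(image, rois, reference = NULL) {
  out <- list(pa = pa_score(image, rois), vd = vd_score(image, rois),
              cnr = if (any(rois$lesions)) cnr_score(image, rois) else NA_real_)
  if (!is.null(reference)) out$dc <- dc_score(image, reference, rois)
  out
}

#' Total quality score
#'
#' Arithmetic mean of the four reference-normalized feature scores. The
#' reference image itself scores exactly 1; values above 1 indicate an
#' image-quality gain over the unprocessed trace-weighted image.
#'
#' @param pa_n,dc_n,vd_n,cnr_n Reference-normalized feature scores.
#' @return Scalar quality score.
#' @export
qtotal <- function(pa_n, dc_n, vd_n, cnr_n) {
  v <- c(pa_n, dc_n, vd_n, cnr_n)
  if (!all(is.finite(v)) || any(v < 0))
    stop("qtotal inputs must be finite and nonnegative", call. = FALSE)
  mean(v)
}

#' Reference-normalized feature scores and Qtotal
#'
#' Computes PA, VD and CNR on both the processed and the reference image,
#' normalizes the processed values to the reference (so the reference scores
#' 1 by construction), computes DC of the processed image against the
#' reference, and aggregates the four normalized scores into the total
#' quality score.
#'
#' @param processed,reference H x W images on the ROI grid.
#' @param rois A [roi_set()].
#' @return Object of class `dwi_scores`: list with `pa_n`, `dc_n`, `vd_n`,
#'   `cnr_n`, `qtotal`, plus the raw score lists `raw_processed` and
#'   `raw_reference`.
#' @export
normalized_scores <- function(processed, reference, rois) {
  if (!identical(dim(processed), dim(reference)))
    stop("processed and reference shapes differ", call. = FALSE)
  raw_p <- feature_scores(processed, rois)
  raw_r <- feature_scores(reference, rois)
  for (f in c("pa", "vd", "cnr")) {
    if (!is.na(raw_r[[f]]) && abs(raw_r[[f]]) <= .EPS)
      stop(sprintf("reference %s score is degenerate (<= epsilon)",
                   toupper(f)), call. = FALSE)
  }
  pa_n <- raw_p$pa / raw_r$pa
  vd_n <- raw_p$vd / raw_r$vd
  cnr_n <- if (is.na(raw_p$cnr)) NA_real_ else raw_p$cnr / raw_r$cnr
  dc_n <- dc_score(processed, reference, rois)
  qt <- if (is.na(cnr_n)) mean(c(pa_n, dc_n, vd_n)) else
    qtotal(pa_n, dc_n, vd_n, cnr_n)
  structure(list(pa_n = pa_n, dc_n = dc_n, vd_n = vd_n, cnr_n = cnr_n,
                 qtotal = qt, raw_processed = raw_p, raw_reference = raw_r),
            class = "dwi_scores")
}

#' @export
print.dwi_scores <- function(x, ...) {
  cat("Normalized image-quality scores (reference = 1):\n")
  cat(sprintf("  PA %.4f  DC %.4f  VD %.4f  CNR %s\n", x$pa_n, x$dc_n,
              x$vd_n, ifelse(is.na(x$cnr_n), "NA",
                             sprintf("%.4f", x$cnr_n))))
  cat(sprintf("  Qtotal %.4f\n", x$qtotal))
  invisible(x)
}

#' Score a set of slices and average
#'
#' Applies a combination function (or uses precomputed images) to every
#' slice, scores each against its trace-weighted reference, and returns the
#' per-slice table plus unweighted means over slices. Slices whose lesion
#' mask is empty contribute to PA/VD/DC only.
#'
#' @param dataset List of slices (each with `stack` and `rois`, e.g.
#'   [generate_slice()] output).
#' @param images List of processed H x W images, one per slice.
#' @param dirs_per_rep Passed to [trace_reference()].
#' @return List with `table` (per-slice data frame) and `mean` (named
#'   vector of mean normalized scores and Qtotal).
#' @export
score_dataset <- function(dataset, images, dirs_per_rep = 3) {
  stopifnot(length(dataset) == length(images))
  rows <- lapply(seq_along(dataset), function(i) {
    sl <- dataset[[i]]
    ref <- trace_reference(sl$stack, dirs_per_rep)
    s <- normalized_scores(images[[i]], ref, sl$rois)
    data.frame(slice = i, pa_n = s$pa_n, dc_n = s$dc_n, vd_n = s$vd_n,
               cnr_n = s$cnr_n, qtotal = s$qtotal)
  })
  tab <- do.call(rbind, rows)
  means <- c(pa_n = mean(tab$pa_n), dc_n = mean(tab$dc_n),
             vd_n = mean(tab$vd_n), cnr_n = mean(tab$cnr_n, na.rm = TRUE),
             qtotal = mean(tab$qtotal))
  list(table = tab, mean = means)
}
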