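#' Loss weights of the feature-guided composite loss
#'
#' The seven nonnegative coefficients weighting the terms of the composite
#' training loss. Defaults follow the tuned values: CNR is weighted highest
#' (it needs the strongest pull), DC lowest among the four feature terms (a
#' low weight permits stronger processing), and the left-lobe MIP-deficit
#' and reference-deviation terms are small so their contributions are of
#' the same order of magnitude as the rest.
#'
#' @param lam_dc,lam_cnr,lam_pa,lam_vd Weights of the four (raw) feature
#'   scores, entering with negative sign (higher score = lower loss).
#' @param lam_di Weight of the score-dispersion penalty.
#' @param lam_pa2 Weight of the left-lobe MIP-deficit penalty.
#' @param lam_xi Weight of the RMS deviation from the reference image.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(lam_dc = 0.5, lam_cnr = 1.5, lam_pa = 1,
                         lam_vd = 1, lam_di = 0.5, lam_pa2 = 0.05,
                         lam_xi = 0.05) {
  w <- list(lam_dc = lam_dc, lam_cnr = lam_cnr, lam_pa = lam_pa,
            lam_vd = lam_vd, lam_di = lam_di, lam_pa2 = lam_pa2,
            lam_xi = lam_xi)
  if (any(unlist(w) < 0)) stop("loss weights must be >= 0", call. = FALSE)
  class(w) <- "loss_weights"
  w
}

#' Maximum intensity projection over repetitions
#'
#' Voxelwise maximum across the repetition axis — the brightest signal
#' available at each voxel in any repetition.
#'
#' @param stack H x W x N repetition stack.
#' @return H x W image.
#' @export
mip <- function(stack) {
  .check_stack(stack)
  d <- dim(stack)
  M <- matrix(stack, d[1] * d[2], d[3])
  matrix(do.call(pmax, asplit(M, 2)), d[1], d[2])
}

#' Left-lobe MIP-deficit term (PA2)
#'
#' Mean of the repetition-wise maximum intensity projection over the left
#' lobe (R1) minus the mean of the predicted image there. Positive when the
#' prediction is darker than the brightest available voxels; penalizing it
#' makes brightening the left lobe preferable to darkening the right lobe
#' (which the plain PA ratio cannot distinguish).
#'
#' @param mip_image H x W MIP image (see [mip()]).
#' @param predicted H x W predicted image.
#' @param rois A [roi_set()].
#' @return Scalar.
#' @export
pa2_term <- function(mip_image, predicted, rois) {
  .check_mask(rois$left_lobe, predicted, "left_lobe")
  mean(mip_image[rois$left_lobe]) - mean(predicted[rois$left_lobe])
}

#' Dispersion of the four feature scores (DI)
#'
#' Population variance (divide by 4) of the four raw feature scores.
#' Penalizing it stops the optimizer from letting one score diverge (the
#' classic failure is an exploding CNR when the liver is flattened to a
#' constant) at the expense of the others.
#'
#' @param dc,cnr,pa,vd Raw feature scores.
#' @return Scalar variance.
#' @export
dispersion <- function(dc, cnr, pa, vd) {
  v <- c(dc, cnr, pa, vd)
  if (!all(is.finite(v))) stop("dispersion inputs must be finite",
                               call. = FALSE)
  mean((v - mean(v))^2)
}

#' Reference-deviation term (xi)
#'
#' Root-mean-square deviation between the predicted and the reference
#' image: the Euclidean norm of the difference divided by the square root
#' of the voxel count, so the weight is independent of image resolution.
#' Keeps the overall image impression and the dark background.
#'
#' @param predicted,reference H x W images on one grid.
#' @return Scalar (>= 0).
#' @export
xi_term <- function(predicted, reference) {
  if (!identical(dim(predicted), dim(reference)))
    stop("predicted and reference shapes differ", call. = FALSE)
  sqrt(mean((predicted - reference)^2))
}

#' Feature-guided composite loss
#'
#' The training loss
#' \deqn{L = -\lambda_{DC} DC - \lambda_{CNR} CNR - \lambda_{PA} PA -
#'   \lambda_{VD} VD + \lambda_{DI} DI + \lambda_{PA2} PA_2 +
#'   \lambda_\xi \xi}
#' where DC, CNR, PA and VD are the raw (unnormalized) feature scores of
#' the predicted image, DI their population variance, PA2 the left-lobe
#' MIP deficit and xi the RMS deviation from the reference. The feature
#' scores enter negatively because higher scores mean better images while
#' the optimizer minimizes. When the slice has no lesion ROI the CNR term
#' is dropped and its weight redistributed equally over the PA, VD and DC
#' terms.
#'
#' @param predicted H x W predicted image.
#' @param stack H x W x N repetition stack (for the MIP).
#' @param reference H x W trace-weighted reference image.
#' @param rois A [roi_set()].
#' @param weights A [loss_weights()].
#' @param precomputed_mip Optional precomputed MIP image (saves recomputing
#'   it when the stack is fixed, e.g. inside a training loop).
#' @param xi_norm Form of the reference-deviation term entering the loss:
#'   `"l2"` (default) uses the plain Euclidean norm of the difference,
#'   which at image resolution puts the weighted ξ contribution on the
#'   same order of magnitude as the feature terms; `"rms"` uses the
#'   resolution-independent root-mean-square form of [xi_term()].
#' @return Object of class `loss_breakdown`: list with the seven terms
#'   (`dc`, `cnr`, `pa`, `vd`, `di`, `pa2`, `xi` — the last on the scale
#'   selected by `xi_norm`), the effective weights used, and `total`.
#' @export
total_loss <- function(predicted, stack, reference, rois,
                       weights = loss_weights(), precomputed_mip = NULL,
                       xi_norm = c("l2", "rms")) {
  stopifnot(inherits(weights, "loss_weights"))
  xi_norm <- match.arg(xi_norm)
  w <- .effective_weights(weights, has_lesion = any(rois$lesions))
  pa <- pa_score(predicted, rois)
  vd <- vd_score(predicted, rois)
  dc <- dc_score(predicted, reference, rois)
  has_les <- any(rois$lesions)
  cnr <- if (has_les) cnr_score(predicted, rois) else 0
  feats <- c(dc = dc, cnr = cnr, pa = pa, vd = vd)
  if (!all(is.finite(feats)))
    stop(sprintf("non-finite loss; diverging term(s): %s",
                 paste(names(feats)[!is.finite(feats)], collapse = ", ")),
         call. = FALSE)
  di <- if (has_les) dispersion(dc, cnr, pa, vd) else
    mean((c(dc, pa, vd) - mean(c(dc, pa, vd)))^2)
  m <- if (is.null(precomputed_mip)) mip(stack) else precomputed_mip
  p2 <- pa2_term(m, predicted, rois)
  xi <- xi_term(predicted, reference)
  if (xi_norm == "l2") xi <- xi * sqrt(length(predicted))
  total <- -w$lam_dc * dc - w$lam_cnr * cnr - w$lam_pa * pa -
    w$lam_vd * vd + w$lam_di * di + w$lam_pa2 * p2 + w$lam_xi * xi
  if (!is.finite(total)) {
    terms <- c(dc = dc, cnr = cnr, pa = pa, vd = vd, di = di, pa2 = p2,
               xi = xi)
    bad <- names(terms)[!is.finite(terms)]
    stop(sprintf("non-finite loss; diverging term(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(dc = dc, cnr = cnr, pa = pa, vd = vd, di = di, pa2 = p2,
                 xi = xi, weights = w, total = total),
            class = "loss_breakdown")
}

# lesion-free slices: drop CNR and share its weight over PA, VD, DC
.effective_weights <- function(weights, has_lesion) {
  w <- unclass(weights)
  if (!has_lesion) {
    add <- w$lam_cnr / 3
    w$lam_cnr <- 0
    w$lam_pa <- w$lam_pa + add
    w$lam_vd <- w$lam_vd + add
    w$lam_dc <- w$lam_dc + add
  }
  w
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("Feature-guided loss breakdown:\n")
  cat(sprintf("  DC %.4f  CNR %.4f  PA %.4f  VD %.4f\n",
              x$dc, x$cnr, x$pa, x$vd))
  cat(sprintf("  DI %.4f  PA2 %.4f  xi %.4f\n", x$di, x$pa2, x$xi))
  cat(sprintf("  total %.5f\n", x$total))
  invisible(x)
}

#' Gradient of the composite loss with respect to the predicted image
#'
#' Analytic voxelwise derivative of [total_loss()] in the predicted image,
#' holding the masks, stack and reference fixed. All score terms are means
#' and ratios over fixed masks, so the gradient is exact except on the
#' measure-zero sets where DC's floor or xi at exactly zero make the loss
#' non-differentiable; there a subgradient of 0 is used.
#'
#' @inheritParams total_loss
#' @return H x W gradient array.
#' @export
loss_gradient <- function(predicted, stack, reference, rois,
                          weights = loss_weights(),
                          xi_norm = c("l2", "rms")) {
  xi_norm <- match.arg(xi_norm)
  has_les <- any(rois$lesions)
  w <- .effective_weights(weights, has_lesion = has_les)
  H <- dim(predicted)[1]; W <- dim(predicted)[2]
  g <- matrix(0, H, W)

  r1 <- rois$left_lobe; r2 <- rois$right_lobe
  vs <- rois$vessels; bg <- rois$background; ls <- rois$lesions
  n1 <- sum(r1); n2 <- sum(r2); nv <- sum(vs); nb <- sum(bg)

  m1 <- mean(predicted[r1]); m2 <- mean(predicted[r2])
  mv <- mean(predicted[vs]); mb <- mean(predicted[bg])
  m2g <- .guard_denom(m2, "PA gradient"); mvg <- .guard_denom(mv, "VD gradient")

  pa <- m1 / m2g
  vd <- mb / mvg
  dc <- dc_score(predicted, reference, rois)

  # dPA/dy
  g_pa <- matrix(0, H, W)
  g_pa[r1] <- 1 / (n1 * m2g)
  g_pa[r2] <- g_pa[r2] - m1 / (n2 * m2g^2)
  # dVD/dy
  g_vd <- matrix(0, H, W)
  g_vd[bg] <- g_vd[bg] + 1 / (nb * mvg)
  g_vd[vs] <- g_vd[vs] - mb / (nv * mvg^2)
  # dDC/dy (0 where floored)
  g_dc <- matrix(0, H, W)
  refm <- .guard_denom(mean(reference[r2]), "DC gradient")
  raw_dc <- 1 - mean(abs(predicted[r2] - reference[r2])) / refm
  if (raw_dc > 0)
    g_dc[r2] <- -sign(predicted[r2] - reference[r2]) / (n2 * refm)
  # dCNR/dy (sample standard deviation in the denominator)
  cnr <- 0
  g_cnr <- matrix(0, H, W)
  if (has_les) {
    nl <- sum(ls)
    bgv <- predicted[bg]
    s <- .guard_denom(stats::sd(bgv), "CNR gradient")
    cnr <- (mean(predicted[ls]) - mb) / s
    g_cnr[ls] <- 1 / (nl * s)
    g_cnr[bg] <- g_cnr[bg] - 1 / (nb * s) -
      (mean(predicted[ls]) - mb) * (bgv - mb) / ((nb - 1) * s^3)
  }

  # feature terms
  g <- g - w$lam_pa * g_pa - w$lam_vd * g_vd - w$lam_dc * g_dc -
    w$lam_cnr * g_cnr

  # DI: population variance of the active scores
  if (has_les) {
    sc <- c(dc, cnr, pa, vd)
    gl <- list(g_dc, g_cnr, g_pa, g_vd)
  } else {
    sc <- c(dc, pa, vd)
    gl <- list(g_dc, g_pa, g_vd)
  }
  dbar <- mean(sc)
  for (i in seq_along(sc))
    g <- g + w$lam_di * (2 / length(sc)) * (sc[i] - dbar) * gl[[i]]

  # PA2: -mean over R1
  g[r1] <- g[r1] - w$lam_pa2 / n1

  # xi: deviation from the reference (RMS or plain L2)
  diff <- predicted - reference
  xi <- sqrt(mean(diff^2))
  if (xi > 0) {
    gxi <- diff / (length(diff) * xi)
    if (xi_norm == "l2") gxi <- gxi * sqrt(length(diff))
    g <- g + w$lam_xi * gxi
  }

  g
}
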