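#' Weighted averaging of repetitions
#'
#' Voxelwise weighted mean with weights \eqn{w_n = I_n^\beta}: bright voxels
#' (those not hit by pulsation dropout) dominate the average for large
#' `beta`; `beta = 0` recovers the plain arithmetic mean. Where every
#' repetition is zero, all weights are taken as 1.
#'
#' @param stack H x W x N repetition stack.
#' @param beta Nonnegative weighting exponent.
#' @return H x W combined image.
#' @export
combine_weighted_average <- function(stack, beta) {
  .check_stack(stack)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  d <- dim(stack)
  M <- matrix(stack, d[1] * d[2], d[3])
  W <- M^beta
  sw <- rowSums(W)
  zero <- sw == 0
  out <- rowSums(W * M)
  out[!zero] <- out[!zero] / sw[!zero]
  out[zero] <- rowMeans(M)[zero]   # all-zero voxels: mean = 0
  matrix(out, d[1], d[2])
}

#' Generalized power-mean combination
#'
#' Voxelwise \eqn{((1/N) \sum_n I_n^p)^{1/p}}. `p = 1` is the arithmetic
#' mean; increasing `p` pulls the result toward the brightest repetition.
#'
#' @inheritParams combine_weighted_average
#' @param p Exponent, at least 1.
#' @return H x W combined image.
#' @export
combine_p_mean <- function(stack, p) {
  .check_stack(stack)
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  d <- dim(stack)
  M <- matrix(stack, d[1] * d[2], d[3])
  matrix(rowMeans(M^p)^(1 / p), d[1], d[2])
}

#' Percentile combination
#'
#' Voxelwise q-th percentile across repetitions, with linear interpolation
#' between order statistics. `q = 50` is the voxelwise median and `q = 100`
#' the maximum intensity projection.
#'
#' @inheritParams combine_weighted_average
#' @param q Percentile in \[0, 100\].
#' @return H x W combined image.
#' @export
combine_percentile <- function(stack, q) {
  .check_stack(stack)
  if (q < 0 || q > 100) stop("q must lie in [0, 100]", call. = FALSE)
  d <- dim(stack)
  M <- matrix(stack, d[1] * d[2], d[3])
  matrix(.row_quantile(M, q), d[1], d[2])
}

#' Outlier-exclusion combination
#'
#' The informed-RESTORE-style algorithm: (1) the voxelwise coefficient of
#' variation across repetitions (std/mean; 0 where the mean is 0) flags
#' regions of high inter-repetition variation; (2) the map is smoothed with
#' a `ks2` x `ks2` box filter (edge-replicating padding) so that only
#' spatially extended variation — the pulsation dropout signature — gates
#' the correction while small vessels are blurred away; (3) where the
#' smoothed map exceeds `thr`, up to `k` iterations per voxel drop the
#' current minimum repetition value if it lies below mean − 1.0 std of the
#' currently retained values; (4) the output is the mean of the retained
#' values inside the gated region and the plain mean elsewhere. At least
#' two repetitions always survive.
#'
#' @inheritParams combine_weighted_average
#' @param k Maximum exclusion iterations per voxel.
#' @param ks2 Odd box-filter kernel size in pixels.
#' @param thr Correction threshold on the smoothed variation map
#'   (dimensionless, since the map is a coefficient of variation).
#' @return H x W combined image.
#' @export
combine_outlier_exclusion <- function(stack, k = 10, ks2 = 21, thr = 0.3) {
  .check_stack(stack)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (ks2 < 1 || ks2 %% 2 != 1) stop("ks2 must be odd and >= 1", call. = FALSE)
  if (thr < 0) stop("thr must be >= 0", call. = FALSE)
  d <- dim(stack); N <- d[3]
  if (N < 2) stop("need at least 2 repetitions", call. = FALSE)
  M <- matrix(stack, d[1] * d[2], N)

  mu <- rowMeans(M)
  s2 <- (rowSums(M^2) - N * mu^2) / (N - 1)
  s2[s2 < 0] <- 0
  cv <- ifelse(mu > 0, sqrt(s2) / mu, 0)
  cv_s <- box_blur(matrix(cv, d[1], d[2]), ks2)
  mask <- as.vector(cv_s > thr)

  out <- mu
  if (any(mask) && k > 0) {
    V <- M[mask, , drop = FALSE]
    retained <- matrix(TRUE, nrow(V), N)
    for (it in seq_len(k)) {
      n_ret <- rowSums(retained)
      s1 <- rowSums(V * retained)
      sq <- rowSums(V^2 * retained)
      m <- s1 / n_ret
      var_s <- (sq - n_ret * m^2) / pmax(n_ret - 1, 1)
      var_s[var_s < 0] <- 0
      sd_s <- sqrt(var_s)
      Vm <- V
      Vm[!retained] <- Inf
      jmin <- max.col(-Vm, ties.method = "first")
      vmin <- Vm[cbind(seq_len(nrow(V)), jmin)]
      act <- (n_ret > 2) & (vmin < m - sd_s)
      if (!any(act)) break
      retained[cbind(which(act), jmin[act])] <- FALSE
    }
    out[mask] <- rowSums(V * retained) / rowSums(retained)
  }
  matrix(out, d[1], d[2])
}

#' Exception-set combination
#'
#' Per voxel, greedily builds an exception set E of repetitions to discard:
#' at each step the repetition whose removal maximally reduces the
#' (population) variance of the retained values is a candidate, and the
#' removal is accepted only if the smoothing factor
#' (variance reduction) x (count retained after removal) / |E| exceeds
#' `sf_min`. The output is the mean of the retained values.
#'
#' @inheritParams combine_weighted_average
#' @param max_excl Maximum size of the exception set (at most N − 2).
#' @param sf_min Smoothing-factor acceptance threshold; `Inf` disables all
#'   removals (plain mean).
#' @return H x W combined image.
#' @export
combine_exception_set <- function(stack, max_excl, sf_min) {
  .check_stack(stack)
  d <- dim(stack); N <- d[3]
  if (max_excl < 0 || max_excl > N - 2)
    stop("max_excl must lie in [0, N - 2]", call. = FALSE)
  M <- matrix(stack, d[1] * d[2], N)
  retained <- matrix(TRUE, nrow(M), N)
  active <- rep(TRUE, nrow(M))
  for (t in seq_len(max_excl)) {
    if (!any(active)) break
    idx <- which(active)
    V <- M[idx, , drop = FALSE]
    R <- retained[idx, , drop = FALSE]
    n <- rowSums(R)
    s1 <- rowSums(V * R)
    sq <- rowSums(V^2 * R)
    var0 <- sq / n - (s1 / n)^2
    # leave-one-out population variance for every retained candidate
    n1 <- n - 1
    varj <- (sq - V^2) / n1 - ((s1 - V) / n1)^2
    varj[!R] <- Inf
    jbest <- max.col(-varj, ties.method = "first")
    vbest <- varj[cbind(seq_len(nrow(V)), jbest)]
    red <- var0 - vbest
    sf <- red * n1 / t
    acc <- is.finite(sf) & (sf > sf_min)
    if (!any(acc)) { active[] <- FALSE; break }
    retained[cbind(idx[acc], jbest[acc])] <- FALSE
    active[idx[!acc]] <- FALSE
  }
  out <- rowSums(M * retained) / rowSums(retained)
  matrix(out, d[1], d[2])
}

#' Run a named combination algorithm
#'
#' Dispatcher over the five conventional algorithms, taking parameters as a
#' named list — the unit the parameter grid search iterates over.
#'
#' @inheritParams combine_weighted_average
#' @param algorithm One of `"weighted_average"`, `"outlier_exclusion"`,
#'   `"p_mean"`, `"percentile"`, `"exception_set"`.
#' @param params Named list of the algorithm's parameters.
#' @return H x W combined image.
#' @export
combine_stack <- function(stack, algorithm, params = list()) {
  switch(match.arg(algorithm,
                   c("weighted_average", "outlier_exclusion", "p_mean",
                     "percentile", "exception_set")),
    weighted_average = combine_weighted_average(stack, params$beta),
    outlier_exclusion = combine_outlier_exclusion(stack, params$k,
                                                  params$ks2, params$thr),
    p_mean = combine_p_mean(stack, params$p),
    percentile = combine_percentile(stack, params$q),
    exception_set = combine_exception_set(stack, params$max_excl,
                                          params$sf_min))
}

#' Quality-score-maximizing parameter search
#'
#' Runs one combination algorithm over a parameter grid, scores every grid
#' point on every slice against the trace-weighted reference, and returns
#' the grid point with the highest mean Qtotal (ties broken by grid order).
#'
#' @param dataset List of slices (each with `stack` and `rois`).
#' @param algorithm Algorithm name as in [combine_stack()].
#' @param grid List of named parameter lists.
#' @param dirs_per_rep Passed to [trace_reference()].
#' @return List with `best_params`, `best_qtotal` and `table`, a data frame
#'   with one row per grid point (parameters, mean normalized scores,
#'   Qtotal).
#' @export
grid_search <- function(dataset, algorithm, grid, dirs_per_rep = 3) {
  if (length(grid) == 0) stop("parameter grid is empty", call. = FALSE)
  rows <- lapply(grid, function(params) {
    imgs <- lapply(dataset, function(sl) combine_stack(sl$stack, algorithm,
                                                       params))
    sc <- score_dataset(dataset, imgs, dirs_per_rep)
    cbind(as.data.frame(params), as.data.frame(as.list(sc$mean)))
  })
  tab <- do.call(rbind, rows)
  tab$algorithm <- algorithm
  best <- which.max(tab$qtotal)
  list(best_params = grid[[best]], best_qtotal = tab$qtotal[best],
       table = tab)
}
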