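test_that("weighted averaging matches hand arithmetic and its limits", {
  st <- const_stack(c(1, 3))
  expect_equal(combine_weighted_average(st, 0), matrix(2, 4, 4))
  expect_equal(combine_weighted_average(st, 1), matrix(2.5, 4, 4))
  expect_equal(combine_weighted_average(st, 50), matrix(3, 4, 4),
               tolerance = 1e-6)
  expect_error(combine_weighted_average(st, -1), "beta")
  # all-zero voxels stay zero
  z <- array(0, c(2, 2, 3))
  expect_equal(combine_weighted_average(z, 2), matrix(0, 2, 2))
})

test_that("p-mean matches the generalized power mean", {
  st <- const_stack(c(1, 2, 3))
  expect_equal(combine_p_mean(st, 1), matrix(2, 4, 4))
  expect_equal(combine_p_mean(st, 2), matrix(sqrt(14 / 3), 4, 4))
  expect_equal(combine_p_mean(st, 200), matrix(3, 4, 4), tolerance = 1e-2)
  expect_error(combine_p_mean(st, 0.5), "p must")
})

test_that("percentile combination interpolates order statistics", {
  st <- const_stack(c(1, 2, 3, 4))
  expect_equal(combine_percentile(st, 50), matrix(2.5, 4, 4))
  expect_equal(combine_percentile(st, 75), matrix(3.25, 4, 4))
  expect_equal(combine_percentile(st, 100), matrix(4, 4, 4))
  expect_error(combine_percentile(st, 101), "q must")
  st3 <- const_stack(c(5, 1, 9))
  expect_equal(combine_percentile(st3, 50), matrix(5, 4, 4))
})

test_that("oracle equivalences hold on random stacks", {
  st <- random_stack(V = 1000, N = 6, seed = 2)
  plain <- apply(st, c(1, 2), mean)
  expect_equal(combine_p_mean(st, 1), plain)
  expect_equal(combine_outlier_exclusion(st, k = 0, ks2 = 3, thr = 0.1),
               plain)
  med <- apply(st, c(1, 2), median)
  expect_equal(combine_percentile(st, 50), med)
  expect_equal(combine_percentile(st, 100), mip(st))
  # quantile cross-check against stats::quantile (type 7)
  q <- combine_percentile(st, 37)
  qref <- apply(st, c(1, 2), quantile, probs = 0.37, names = FALSE)
  expect_equal(q, qref)
})

test_that("outlier exclusion drops the traced minimum and only that", {
  # voxel (1, 1, 1, 0.1) inside the gated region with many iterations:
  # 0.1 is below mean - sd of the retained set, the remaining values are
  # not, so the output is exactly 1
  st <- const_stack(c(1, 1, 1, 0.1), H = 8, W = 8)
  out <- combine_outlier_exclusion(st, k = 10, ks2 = 3, thr = 0)
  expect_equal(out, matrix(1, 8, 8))
  # threshold above the variation-map maximum leaves the plain mean
  out2 <- combine_outlier_exclusion(st, k = 10, ks2 = 3, thr = 1e6)
  expect_equal(out2, matrix(mean(c(1, 1, 1, 0.1)), 8, 8))
})

test_that("outlier exclusion always retains at least two repetitions", {
  set.seed(3)
  st <- array(runif(50 * 4, 0, 1), dim = c(50, 1, 4))
  out <- combine_outlier_exclusion(st, k = 10, ks2 = 1, thr = 0)
  M <- matrix(st, 50, 4)
  lo2 <- t(apply(M, 1, function(v) mean(sort(v)[3:4])))
  expect_true(all(out <= matrix(lo2, 50, 1) + 1e-12))
  expect_true(all(out >= apply(M, 1, min) - 1e-12))
})

test_that("exception set removes the variance-dominating value greedily", {
  st <- const_stack(c(1, 1, 1, 1, 1, 0.2), H = 2, W = 2)
  expect_equal(combine_exception_set(st, 2, 0), matrix(1, 2, 2))
  expect_equal(combine_exception_set(st, 2, Inf),
               matrix(mean(c(1, 1, 1, 1, 1, 0.2)), 2, 2))
  # all equal: no removal
  expect_equal(combine_exception_set(const_stack(rep(2, 6)), 2, 0),
               matrix(2, 4, 4))
  expect_error(combine_exception_set(st, 5, 0), "max_excl")
})

test_that("exception-set greedy matches brute-force subset enumeration", {
  # brute force: over all exclusion subsets of size <= max_excl, follow the
  # same acceptance rule on the best subset of each size
  brute <- function(v, max_excl, sf_min) {
    keep <- seq_along(v)
    for (t in seq_len(max_excl)) {
      combos <- utils::combn(keep, length(keep) - 1, simplify = FALSE)
      vars <- vapply(combos, function(s) mean((v[s] - mean(v[s]))^2),
                     numeric(1))
      v0 <- mean((v[keep] - mean(v[keep]))^2)
      best <- which.min(vars)
      sf <- (v0 - vars[best]) * (length(keep) - 1) / t
      if (!(sf > sf_min)) break
      keep <- combos[[best]]
    }
    mean(v[keep])
  }
  st <- random_stack(V = 1000, N = 6, seed = 7)
  out <- combine_exception_set(st, 2, 0)
  M <- matrix(st, 1000, 6)
  expected <- apply(M, 1, brute, max_excl = 2, sf_min = 0)
  expect_equal(as.vector(out), expected)
})

test_that("all five algorithms are invariant to repetition order", {
  st <- random_stack(V = 200, N = 8, seed = 5)
  set.seed(6)
  perm <- sample(8)
  stp <- st[, , perm, drop = FALSE]
  expect_equal(combine_weighted_average(st, 2),
               combine_weighted_average(stp, 2))
  expect_equal(combine_p_mean(st, 3), combine_p_mean(stp, 3))
  expect_equal(combine_percentile(st, 30), combine_percentile(stp, 30))
  expect_equal(combine_outlier_exclusion(st, 3, 1, 0.1),
               combine_outlier_exclusion(stp, 3, 1, 0.1))
  expect_equal(combine_exception_set(st, 2, 0),
               combine_exception_set(stp, 2, 0))
})

test_that("combined outputs are bounded by the voxelwise min and max", {
  st <- random_stack(V = 300, N = 6, seed = 8)
  lo <- apply(st, c(1, 2), min) - 1e-12
  hi <- apply(st, c(1, 2), max) + 1e-12
  for (img in list(combine_weighted_average(st, 2), combine_p_mean(st, 3),
                   combine_percentile(st, 80),
                   combine_outlier_exclusion(st, 2, 1, 0.1),
                   combine_exception_set(st, 2, 0))) {
    expect_true(all(img >= lo & img <= hi))
  }
})

test_that("grid search returns the Qtotal argmax with stable ties", {
  ds <- lapply(1:3, function(s) generate_slice(quick_config(), seed = 40 + s))
  grid <- list(list(p = 1), list(p = 2.5))
  gs <- grid_search(ds, "p_mean", grid)
  expect_equal(nrow(gs$table), 2)
  expect_equal(gs$best_qtotal, max(gs$table$qtotal))
  expect_equal(gs$best_params,
               grid[[which.max(gs$table$qtotal)]])
  # single-point grid returns that point
  gs1 <- grid_search(ds, "p_mean", list(list(p = 1)))
  expect_equal(gs1$best_params, list(p = 1))
  expect_error(grid_search(ds, "p_mean", list()), "empty")
})
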