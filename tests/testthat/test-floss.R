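test_that("MIP is the voxelwise maximum and matches the 100th percentile", {
  st <- const_stack(c(0.2, 0.9, 0.5))
  expect_equal(mip(st), matrix(0.9, 4, 4))
  one <- const_stack(0.7)
  expect_equal(mip(one), matrix(0.7, 4, 4))
  rnd <- random_stack(V = 500, N = 5, seed = 11)
  expect_equal(mip(rnd), combine_percentile(rnd, 100))
})

test_that("PA2 is the left-lobe MIP deficit", {
  sl <- generate_slice(quick_config(), seed = 12)
  m <- mip(sl$stack)
  expect_equal(pa2_term(m, m, sl$rois), 0)
  expect_equal(pa2_term(m, m - 0.3, sl$rois), 0.3)
  # plain mean is darker than the MIP wherever dropouts create spread
  pm <- combine_p_mean(sl$stack, 1)
  expect_gt(pa2_term(m, pm, sl$rois), 0)
})

test_that("dispersion is the population variance of the four scores", {
  expect_equal(dispersion(1, 1, 1, 1), 0)
  expect_equal(dispersion(1, 1, 1, 0), 0.1875)
  expect_equal(dispersion(0, 1, 1, 1), dispersion(1, 1, 1, 0))
  set.seed(13)
  v <- runif(4)
  expect_equal(dispersion(v[1], v[2], v[3], v[4]),
               mean((v - mean(v))^2))
})

test_that("xi is the RMS deviation from the reference", {
  a <- matrix(runif(16), 4, 4)
  expect_equal(xi_term(a, a), 0)
  expect_equal(xi_term(a + 0.25, a), 0.25)
  b <- matrix(c(3, 4), 2, 1)
  expect_equal(xi_term(b, matrix(0, 2, 1)), sqrt(25 / 2))
  expect_error(xi_term(a, matrix(0, 2, 2)), "shapes")
})

test_that("the composite loss is the stated linear combination of terms", {
  sl <- generate_slice(quick_config(), seed = 14)
  ref <- trace_reference(sl$stack)
  pred <- combine_p_mean(sl$stack, 2)
  w <- loss_weights()
  lb <- total_loss(pred, sl$stack, ref, sl$rois, w)
  expect_equal(lb$total,
               -w$lam_dc * lb$dc - w$lam_cnr * lb$cnr - w$lam_pa * lb$pa -
                 w$lam_vd * lb$vd + w$lam_di * lb$di +
                 w$lam_pa2 * lb$pa2 + w$lam_xi * lb$xi)
  # zero weights give zero loss
  w0 <- loss_weights(0, 0, 0, 0, 0, 0, 0)
  expect_equal(total_loss(pred, sl$stack, ref, sl$rois, w0)$total, 0)
})

test_that("the loss is exactly linear in the weight vector", {
  sl <- generate_slice(quick_config(), seed = 15)
  ref <- trace_reference(sl$stack)
  pred <- combine_percentile(sl$stack, 70)
  set.seed(16)
  base <- total_loss(pred, sl$stack, ref, sl$rois, loss_weights())
  terms <- c(-base$dc, -base$cnr, -base$pa, -base$vd, base$di, base$pa2,
             base$xi)
  for (i in 1:10) {
    lam <- runif(7, 0, 2)
    w <- loss_weights(lam[1], lam[2], lam[3], lam[4], lam[5], lam[6],
                      lam[7])
    lb <- total_loss(pred, sl$stack, ref, sl$rois, w)
    expect_equal(lb$total, sum(lam * terms))
  }
})

test_that("analytic loss gradient agrees with finite differences", {
  sl <- generate_slice(quick_config(n_reps = 6), seed = 17)
  ref <- trace_reference(sl$stack, 3)
  set.seed(18)
  pred <- combine_p_mean(sl$stack, 1) * matrix(runif(48 * 48, 0.9, 1.1),
                                               48, 48)
  w <- loss_weights()
  g <- loss_gradient(pred, sl$stack, ref, sl$rois, w)
  m <- mip(sl$stack)
  f <- function(p) total_loss(p, NULL, ref, sl$rois, w,
                              precomputed_mip = m)$total
  roi_any <- sl$rois$left_lobe | sl$rois$right_lobe | sl$rois$vessels |
    sl$rois$lesions | sl$rois$background
  idx <- sample(which(roi_any), 15)
  eps <- 1e-6
  for (i in idx) {
    p1 <- pred; p1[i] <- p1[i] + eps
    p2 <- pred; p2[i] <- p2[i] - eps
    num <- (f(p1) - f(p2)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("brightening the left lobe slightly decreases the loss", {
  sl <- generate_slice(quick_config(), seed = 19)
  ref <- trace_reference(sl$stack)
  pred <- combine_p_mean(sl$stack, 1)
  w <- loss_weights()
  m <- mip(sl$stack)
  l0 <- total_loss(pred, NULL, ref, sl$rois, w, precomputed_mip = m)$total
  up <- pred
  up[sl$rois$left_lobe] <- up[sl$rois$left_lobe] + 1e-3
  l1 <- total_loss(up, NULL, ref, sl$rois, w, precomputed_mip = m)$total
  expect_lt(l1, l0)
})

test_that("pa2 is nonnegative whenever the prediction is below the MIP", {
  sl <- generate_slice(quick_config(), seed = 20)
  m <- mip(sl$stack)
  set.seed(21)
  pred <- m * matrix(runif(48 * 48, 0, 1), 48, 48)
  expect_gte(pa2_term(m, pred, sl$rois), 0)
})

test_that("lesion-free slices redistribute the CNR weight", {
  sl <- generate_slice(quick_config(), seed = 22)
  sl$rois$lesions[] <- FALSE
  ref <- trace_reference(sl$stack)
  pred <- combine_p_mean(sl$stack, 1)
  lb <- total_loss(pred, sl$stack, ref, sl$rois, loss_weights())
  expect_equal(lb$cnr, 0)
  expect_equal(lb$weights$lam_cnr, 0)
  expect_equal(lb$weights$lam_pa, 1 + 0.5)
  expect_true(is.finite(lb$total))
})

test_that("non-finite losses abort with a diagnostic naming the term", {
  sl <- generate_slice(quick_config(), seed = 23)
  ref <- trace_reference(sl$stack)
  pred <- combine_p_mean(sl$stack, 1)
  pred[1, 1] <- Inf
  pred[sl$rois$background][1] <- Inf
  expect_error(total_loss(pred, sl$stack, ref, sl$rois, loss_weights()),
               "diverging")
})
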