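test_that("trace reference follows geometric-then-arithmetic averaging", {
  # constant stack is a fixed point
  expect_equal(trace_reference(const_stack(rep(2, 6)), 3),
               matrix(2, 4, 4))
  # one group of 3 with voxel values (1, 8, 1): cube root of 8
  expect_equal(trace_reference(const_stack(c(1, 8, 1)), 3),
               matrix(2, 4, 4))
  # two groups (1,1,8) and (8,8,1): mean of 2 and 4
  expect_equal(trace_reference(const_stack(c(1, 1, 8, 8, 8, 1)), 3),
               matrix(3, 4, 4))
  expect_error(trace_reference(const_stack(c(1, 2)), 3), "divisible")
})

test_that("feature scores match their closed forms on hand-built images", {
  rois <- tiny_rois()
  img <- matrix(1, 8, 8)
  expect_equal(pa_score(img, rois), 1.0)
  expect_equal(vd_score(img, rois), 1.0)
  # lesion mean equal to a (non-degenerate) background mean gives CNR 0
  img0 <- img
  img0[rois$background] <- rep(c(0.8, 1.2), length.out = sum(rois$background))
  expect_equal(cnr_score(img0, rois), 0.0)

  img2 <- img
  img2[rois$left_lobe] <- 0.5
  expect_equal(pa_score(img2, rois), 0.5)

  img3 <- img
  img3[rois$vessels] <- 2.0
  expect_equal(vd_score(img3, rois), 0.5)

  img4 <- img
  img4[rois$lesions] <- 3
  img4[rois$background] <- c(0.5, 1.5)   # mean 1, sd 0.5 pattern
  bg <- img4[rois$background]
  expect_equal(cnr_score(img4, rois), (3 - mean(bg)) / sd(bg))
})

test_that("data consistency is relative deviation over R2, floored at 0", {
  rois <- tiny_rois()
  ref <- matrix(runif(64, 0.5, 1.5), 8, 8)
  expect_equal(dc_score(ref, ref, rois), 1.0)
  expect_equal(dc_score(ref * 1.1, ref, rois), 0.9)
  zero <- ref; zero[rois$right_lobe] <- 0
  expect_equal(dc_score(zero, ref, rois), 0.0)
  expect_error(dc_score(matrix(1, 4, 4), ref, rois), "shapes")
})

test_that("reference scored against itself yields exactly 1 everywhere", {
  sl <- generate_slice(quick_config(), seed = 8)
  ref <- trace_reference(sl$stack)
  s <- normalized_scores(ref, ref, sl$rois)
  expect_identical(s$pa_n, 1)
  expect_identical(s$vd_n, 1)
  expect_identical(s$cnr_n, 1)
  expect_identical(s$dc_n, 1)
  expect_identical(s$qtotal, 1)
})

test_that("normalized scores are invariant to a joint positive rescaling", {
  sl <- generate_slice(quick_config(), seed = 9)
  ref <- trace_reference(sl$stack)
  proc <- combine_p_mean(sl$stack, 2)
  a <- normalized_scores(proc, ref, sl$rois)
  b <- normalized_scores(proc * 3.7, ref * 3.7, sl$rois)
  expect_equal(a$pa_n, b$pa_n)
  expect_equal(a$vd_n, b$vd_n)
  expect_equal(a$cnr_n, b$cnr_n)
  expect_equal(a$dc_n, b$dc_n)
})

test_that("raising R1 raises pa_n and raising vessels lowers vd_n", {
  sl <- generate_slice(quick_config(), seed = 10)
  ref <- trace_reference(sl$stack)
  proc <- combine_p_mean(sl$stack, 1)
  base <- normalized_scores(proc, ref, sl$rois)
  up1 <- proc; up1[sl$rois$left_lobe] <- up1[sl$rois$left_lobe] + 0.1
  s1 <- normalized_scores(up1, ref, sl$rois)
  expect_gt(s1$pa_n, base$pa_n)
  upv <- proc; upv[sl$rois$vessels] <- upv[sl$rois$vessels] + 0.1
  sv <- normalized_scores(upv, ref, sl$rois)
  expect_lt(sv$vd_n, base$vd_n)
})

test_that("qtotal is the exact arithmetic mean of its four inputs", {
  set.seed(4)
  for (i in 1:25) {
    v <- runif(4, 0, 3)
    expect_identical(qtotal(v[1], v[2], v[3], v[4]), mean(v))
  }
  expect_error(qtotal(1, 1, 1, -1), "nonnegative")
})

test_that("degenerate constant-liver image triggers the epsilon guard", {
  rois <- tiny_rois()
  img <- matrix(1, 8, 8)
  img[rois$lesions] <- 2
  expect_warning(v <- cnr_score(img, rois), "denominator")
  expect_gt(v, 1e6)
})
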