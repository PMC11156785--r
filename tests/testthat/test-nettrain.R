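test_that("stack normalization is exact and invertible", {
  sl <- generate_slice(quick_config(), seed = 31)
  nr <- normalize_stack(sl$stack)
  expect_equal(mean(nr$stack), 0, tolerance = 1e-6)
  expect_equal(sd(as.vector(nr$stack)), 1, tolerance = 1e-6)
  expect_equal(denormalize(nr$stack, nr), sl$stack)
  # affine invariance: scale + offset normalize to the same array
  nr2 <- normalize_stack(sl$stack * 2.5 + 1.0)
  expect_equal(nr$stack, nr2$stack)
  expect_error(normalize_stack(array(1, c(4, 4, 2))), "variance")
})

test_that("augmentation applies one rigid transform to images and masks", {
  sl <- clean_slice(seed = 32)
  # identity transform leaves everything unchanged
  id <- liverdwi:::.apply_affine_slice(sl, 0, 0, 1)
  expect_equal(id$stack, sl$stack, tolerance = 1e-12)
  expect_identical(id$rois$left_lobe, sl$rois$left_lobe)
  # pure integer translation shifts mask centroids exactly
  tr <- liverdwi:::.apply_affine_slice(sl, 0, 5, 1)
  c0 <- colMeans(which(sl$rois$left_lobe, arr.ind = TRUE))
  c1 <- colMeans(which(tr$rois$left_lobe, arr.ind = TRUE))
  expect_equal(unname(c1 - c0), c(0, 5))
  # same seed, same draw
  set.seed(9); a <- augment_slice(sl)
  set.seed(9); b <- augment_slice(sl)
  expect_identical(a$stack, b$stack)
  expect_identical(a$rois$vessels, b$rois$vessels)
})

test_that("patient-wise split respects counts and disjointness", {
  cfg <- quick_config(n_reps = 2)
  ds <- generate_dataset(10, 5, cfg, seed = 33)
  sp <- split_patientwise(ds, 0.8, seed = 1)
  expect_length(sp$train, 40)
  expect_length(sp$test, 10)
  ids <- function(set) unique(vapply(set, `[[`, numeric(1), "patient_id"))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  # property: disjoint for many seeds, and reproducible
  for (s in 1:100) {
    sp1 <- split_patientwise(ds, 0.8, seed = s)
    expect_length(intersect(ids(sp1$train), ids(sp1$test)), 0)
    expect_length(sp1$train, 40)
  }
  sp2 <- split_patientwise(ds, 0.8, seed = 1)
  expect_identical(ids(sp$train), ids(sp2$train))
  expect_error(split_patientwise(ds[1:5], 0.8, seed = 1), "patients")
})

test_that("the early-stopping rule is a pure function of the loss curve", {
  # strictly decreasing: never stops
  dec <- seq(10, 1, length.out = 30)
  for (n in seq(2, 30)) expect_false(early_stop(dec[1:n], 5))
  # flat windows: stops as soon as two full windows exist
  expect_true(early_stop(rep(5, 10), 5))
  expect_false(early_stop(rep(5, 9), 5))
  # recent window worse than previous: stops
  expect_true(early_stop(c(1, 1, 1, 2, 2, 2), 3))
  # recent window better: continues
  expect_false(early_stop(c(2, 2, 2, 1, 1, 1), 3))
  # equality counts as "not lower" and fires the rule
  expect_true(early_stop(c(3, 3, 3, 3), 2))
})

test_that("pretraining reduces the reconstruction error", {
  cfg <- phantom_config(height = 32, width = 32, n_reps = 6)
  ds <- generate_dataset(2, 2, cfg, seed = 34)
  spec <- unet_spec(in_channels = 6, depth = 2, base_channels = 4)
  fit <- fit_pulsenet(ds, spec = spec,
                      config = train_config("desk", pretrain_epochs = 15,
                                            max_epochs = 1, batch_size = 1,
                                            augment = FALSE, seed = 3))
  expect_lt(tail(fit$pretrain_history, 1), fit$pretrain_history[1])
  # prediction contract: nonnegative, input-sized
  p <- predict(fit, ds[[1]]$stack)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p >= 0))
})

test_that("training histories and methods behave as documented", {
  cfg <- phantom_config(height = 32, width = 32, n_reps = 6)
  ds <- generate_dataset(2, 2, cfg, seed = 35)
  spec <- unet_spec(6, 2, 4)
  fit <- fit_pulsenet(ds[1:3], ds[4], spec = spec,
                      config = train_config("desk", pretrain_epochs = 2,
                                            max_epochs = 3, batch_size = 1,
                                            augment = FALSE, seed = 4))
  expect_s3_class(fit, "pulsenet")
  expect_true(all(c("epoch", "total", "val") %in% names(fit$history)))
  expect_lte(nrow(fit$history), 3)
  expect_equal(unname(coef(fit)), unname(unlist(unclass(loss_weights()))))
  expect_output(print(fit), "pulsenet")
  # deterministic given the seed
  fit2 <- fit_pulsenet(ds[1:3], ds[4], spec = spec,
                       config = train_config("desk", pretrain_epochs = 2,
                                             max_epochs = 3, batch_size = 1,
                                             augment = FALSE, seed = 4))
  expect_equal(fit$history$total, fit2$history$total)
})
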