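# CT preprocessing (HU normalization, rotation augmentation, crop/resize)
# and the 3D residual CNN.

test_that("HU normalization maps the window to [0, 1] linearly", {
  v <- ct_volume(array(c(-1000, 400, -300, -2000, 1000), c(5, 1, 1)))
  out <- hu_normalize(v, -1000, 400)
  expect_equal(out$voxels[1, 1, 1], 0)
  expect_equal(out$voxels[2, 1, 1], 1)
  expect_equal(out$voxels[3, 1, 1], 0.5)
  expect_equal(out$voxels[4, 1, 1], 0)   # clipped below
  expect_equal(out$voxels[5, 1, 1], 1)   # clipped above
  expect_error(hu_normalize(v, 100, 100), "greater")
  # monotone in H
  h <- sort(rnorm(20, -500, 300))
  o <- hu_normalize(array(h, c(20, 1, 1)), -1000, 400)$voxels
  expect_true(all(diff(as.vector(o)) >= 0))
  expect_true(min(o) >= 0 && max(o) <= 1)
})

test_that("the dataset HU window spans the training volumes", {
  vols <- list(ct_volume(array(c(-900, -100), c(2, 1, 1))),
               ct_volume(array(c(-500, 350), c(2, 1, 1))))
  expect_equal(hu_range_from_volumes(vols), c(-900, 350))
})

test_that("rotation augmentation preserves shape and replays under a seed", {
  set.seed(77)
  vol <- array(rnorm(4 * 16 * 16), c(4, 16, 16))
  expect_identical(augment_rotate(vol, theta = 0), vol)
  out <- augment_rotate(vol, theta = 10)
  expect_identical(dim(out), dim(vol))
  # same angle applied identically to every slice
  m <- copdfuse:::rotation_map(16, 16, 10, "nearest")
  for (z in 1:4) {
    expect_equal(out[z, , ],
                 copdfuse:::apply_slice_map(vol[z, , ], m, 0))
  }
  # inverse pair restores a centered impulse under nearest neighbor
  imp <- array(0, c(2, 15, 15)); imp[, 8, 8] <- 1
  back <- augment_rotate(augment_rotate(imp, theta = 12), theta = -12)
  expect_equal(back[, 8, 8], c(1, 1))
  # fixed seed gives a fixed angle sequence
  set.seed(5); a1 <- augment_rotate(vol, max_deg = 15)
  set.seed(5); a2 <- augment_rotate(vol, max_deg = 15)
  expect_identical(a1, a2)
})

test_that("crop_resize is identity at target shape and mean-preserving", {
  vol <- array(rnorm(6 * 12 * 12), c(6, 12, 12))
  expect_equal(crop_resize(vol, c(6, 12, 12), crop_fraction = 1), vol)
  # interpolating a constant volume stays constant
  cv <- array(3.5, c(5, 9, 11))
  out <- crop_resize(cv, c(4, 6, 8))
  expect_equal(dim(out), c(4L, 6L, 8L))
  expect_true(all(abs(out - 3.5) < 1e-12))
  # 2x downscale of a checkerboard block-averages to the mean
  cb <- array(rep((outer(1:8, 1:8, `+`) %% 2), each = 4), c(4, 8, 8))
  down <- crop_resize(cb, c(4, 4, 4))
  expect_true(all(abs(down - 0.5) < 1e-9))
  # center crop reduces the field of view before resampling
  big <- array(0, c(2, 10, 10)); big[, 5:6, 5:6] <- 1
  cropped <- crop_resize(big, c(2, 2, 2), crop_fraction = 0.2)
  expect_true(all(cropped == 1))
})

test_that("the lite CNN propagates shapes to (out_dim, 2)", {
  cfg <- cnn_config(input_shape = c(8, 32, 32), out_dim = 64, seed = 1)
  model <- ct_model(cfg)
  vol <- array(runif(8 * 32 * 32), c(8, 32, 32))
  out <- cnn_forward(list(vol), model)
  expect_identical(dim(out$z_v), c(1L, 64L))
  expect_identical(dim(out$logits), c(1L, 2L))
  expect_error(cnn_forward(list(array(0, c(4, 8, 8))), model), "shape")
})

test_that("eval-mode CNN forward is deterministic and order-preserving", {
  cfg <- cnn_config(input_shape = c(6, 16, 16), seed = 2)
  model <- ct_model(cfg)
  set.seed(3)
  vols <- lapply(1:4, function(i) array(runif(6 * 16 * 16), c(6, 16, 16)))
  o1 <- cnn_forward(vols, model)
  o2 <- cnn_forward(vols, model)
  expect_identical(o1$z_v, o2$z_v)
  # permuting the batch permutes the rows (batch statistics are symmetric)
  perm <- c(3, 1, 4, 2)
  o3 <- cnn_forward(vols[perm], model)
  expect_equal(o3$z_v, o1$z_v[perm, ], tolerance = 1e-12)
})

test_that("image-only pretraining learns and validates its contracts", {
  spec <- synthetic_spec(n_samples = 60, modality_signal = "ct_only",
                         seed = 23)
  ds <- generate_paired_dataset(spec)
  expect_error(pretrain_cnn(ds$volumes, rep(1, 60), cnn_config()),
               "both classes")

  cfg <- cnn_config(seed = 4, epochs = 4, lr = 1e-3)
  m <- pretrain_cnn(ds$volumes, ds$labels, cfg)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])

  # lr = 0 leaves the Xavier initialization untouched
  m0 <- pretrain_cnn(ds$volumes, ds$labels,
                     cnn_config(seed = 4, epochs = 1, lr = 0))
  init <- ct_model(cnn_config(seed = 4, epochs = 1, lr = 0))
  expect_identical(m0$params, init$params)

  # seeded runs are identical
  m2 <- pretrain_cnn(ds$volumes, ds$labels, cfg)
  expect_identical(m$history$loss, m2$history$loss)
  expect_identical(m$params, m2$params)
})

test_that("the full bottleneck backbone is constructed behind the same interface", {
  arch <- copdfuse:::cnn_arch("resnet50_3d")
  expect_identical(arch[[1]]$cout, 64L)
  # stages of 3, 4, 6, 3 bottleneck blocks with expansion 4
  types <- vapply(arch[-1], `[[`, character(1), "type")
  expect_identical(unname(table(types)[["bottleneck"]]), 16L)
  expect_identical(arch[[length(arch)]]$cout, 2048L)
})
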