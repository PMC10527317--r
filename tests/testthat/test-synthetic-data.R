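# The paired-modality generator: determinism, calibration of the injected
# correlation / effect structure, and the Bayes-rule oracle properties.

test_that("same seed gives byte-identical tables and volumes", {
  spec <- synthetic_spec(n_samples = 40, seed = 123)
  a <- generate_pb_table(spec)
  b <- generate_pb_table(spec)
  expect_identical(a$values, b$values)
  expect_identical(a$labels, b$labels)
  expect_identical(a$repeated, b$repeated)
  va <- generate_volumes(spec, a$labels)
  vb <- generate_volumes(spec, a$labels)
  expect_identical(lapply(va, `[[`, "voxels"), lapply(vb, `[[`, "voxels"))
})

test_that("null configuration has no correlations and equal class means", {
  spec <- synthetic_spec(n_samples = 1000, correlated_blocks = list(),
                         informative_features = list(list(index = 1L,
                                                          delta = 0)),
                         outlier_fraction = 0, repeated_meas_rate = 0,
                         seed = 2)
  tab <- generate_pb_table(spec)
  R <- cor(tab$values)
  expect_lt(max(abs(R[upper.tri(R)])), 0.12)
  dm <- colMeans(tab$values[tab$labels == 1, ]) -
    colMeans(tab$values[tab$labels == 0, ])
  expect_lt(max(abs(dm)), 0.15)
})

test_that("block correlation and informative shifts match the spec at n = 1000", {
  spec <- synthetic_spec(
    n_samples = 1000,
    correlated_blocks = list(list(features = c(2L, 3L, 4L), rho = 0.9)),
    informative_features = list(list(index = 10L, delta = 1)),
    outlier_fraction = 0, repeated_meas_rate = 0, seed = 5)
  tab <- generate_pb_table(spec)
  within <- cor(tab$values[, 2:4])
  expect_lt(max(abs(within[upper.tri(within)] - 0.9)), 0.05)
  shift <- mean(tab$values[tab$labels == 1, 10]) -
    mean(tab$values[tab$labels == 0, 10])
  expect_lt(abs(shift - 1), 0.2)
})

test_that("outlier fraction and magnitude are as configured", {
  spec <- synthetic_spec(n_samples = 1000, seed = 9)
  tab <- generate_pb_table(spec)
  mask <- attr(tab, "outlier_cells")
  expect_lt(abs(mean(mask) - spec$outlier_fraction),
            0.5 * spec$outlier_fraction)
  # injected cells sit >= ~4.5 sigma out even after sd inflation
  flagged <- detect_outliers_3sigma(tab)
  expect_gt(sum(flagged & mask) / sum(mask), 0.95)
})

test_that("invalid block and degenerate volume specs are rejected", {
  expect_error(synthetic_spec(correlated_blocks =
                                list(list(features = c(1L, 2L), rho = 1))),
               "positive-definite")
  expect_error(synthetic_spec(volume_shape = c(1L, 8L, 8L)), "depth")
  expect_error(generate_volumes(synthetic_spec(n_samples = 4),
                                labels = c(0, 2, 1, 1)), "binary")
})

test_that("pb_only forces a zero volume effect; label balance is binomial", {
  spec <- synthetic_spec(modality_signal = "pb_only")
  expect_identical(spec$volume_effect, 0)
  spec2 <- synthetic_spec(n_samples = 400, label_balance = 0.5, seed = 3)
  tab <- generate_pb_table(spec2)
  expect_lt(abs(sum(tab$labels) - 200), 3 * sqrt(400 * 0.25))
})

test_that("zero volume effect gives equal class intensity; positive effect separates", {
  spec0 <- synthetic_spec(n_samples = 60, volume_effect = 0, seed = 21,
                          modality_signal = "pb_only")
  tab <- generate_pb_table(spec0)
  v0 <- generate_volumes(spec0, tab$labels)
  mu <- vapply(v0, function(v) mean(v$voxels), numeric(1))
  expect_gt(t.test(mu ~ tab$labels)$p.value, 0.01)

  spec1 <- synthetic_spec(n_samples = 200, modality_signal = "ct_only",
                          seed = 22)
  labels <- with(list(), {set.seed(22); rbinom(200, 1, 0.5)})
  v1 <- generate_volumes(spec1, labels)
  # threshold on the generator's own statistic: low-attenuation fraction
  frac <- vapply(v1, function(v) mean(v$voxels < -950), numeric(1))
  thr <- mean(tapply(frac, labels, mean))
  expect_gt(mean((frac > thr) == labels), 0.9)
})

test_that("complementary mode: joint Bayes accuracy exceeds both marginals", {
  spec <- synthetic_spec(modality_signal = "complementary", seed = 1)
  acc <- bayes_accuracy(spec, n_mc = 10000)
  expect_gt(acc$joint, acc$pb + 0.02)
  expect_gt(acc$joint, acc$ct + 0.02)
  expect_gt(acc$pb, 0.6)
  expect_gt(acc$ct, 0.6)
})

test_that("redundant mode couples the modalities through a shared latent", {
  # within-class correlation between the PB informative score and the
  # low-attenuation fraction: positive when both modalities read one
  # latent severity (population value ~0.10), zero when the signals are
  # conditionally independent given the class
  r_within <- function(mode) {
    spec <- synthetic_spec(n_samples = 2000, modality_signal = mode,
                           seed = 4)
    tab <- generate_pb_table(spec)
    vols <- generate_volumes(spec, tab$labels,
                             latent = attr(tab, "latent"))
    frac <- vapply(vols, function(v) mean(v$voxels < -950), numeric(1))
    score <- rowMeans(tab$values[, c(7, 23, 4, 13)])
    mean(vapply(0:1, function(cl) {
      cor(score[tab$labels == cl], frac[tab$labels == cl])
    }, numeric(1)))
  }
  r_red <- r_within("redundant")
  r_comp <- r_within("complementary")
  expect_gt(r_red, 0.055)
  expect_lt(abs(r_comp), 0.055)
  expect_gt(r_red, r_comp + 0.04)
})

test_that("paired dataset aligns tables, volumes and labels", {
  ds <- generate_paired_dataset(synthetic_spec(n_samples = 20, seed = 6))
  expect_length(ds$volumes, 20)
  expect_identical(ds$labels, ds$table$labels)
  expect_true(all(vapply(ds$volumes, function(v)
    all(dim(v$voxels) == c(16, 32, 32)), logical(1))))
  expect_true(all(vapply(ds$volumes, function(v)
    min(v$voxels) >= -1000 && max(v$voxels) <= 400, logical(1))))
})
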