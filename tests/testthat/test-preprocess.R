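# Tabular preprocessing: 3-sigma screening, class-restricted KNN
# imputation, least-squares repeated-measurement resolution.

mk_table <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- rep_len(c(0, 1), nrow(values))
  feature_table(values, labels, paste0("f", seq_len(ncol(values))))
}

test_that("3-sigma rule flags exactly the analytic set", {
  # population sd: column c(0,0,0,0,100) has mu 20, sigma 40 -> 100 is 2
  # sigma out and must NOT be flagged
  tab <- mk_table(cbind(c(0, 0, 0, 0, 100), rnorm(5)),
                  labels = c(0, 1, 0, 1, 0))
  m <- detect_outliers_3sigma(tab)
  expect_false(any(m[, 1]))

  # 99 zeros and one 1000: mu = 10, sigma ~ 99.5 -> 1000 is ~9.9 sigma
  x <- c(rep(0, 99), 1000)
  tab2 <- mk_table(cbind(x, rnorm(100)))
  m2 <- detect_outliers_3sigma(tab2)
  expect_identical(which(m2[, 1]), 100L)

  # constant column flags nothing
  tab3 <- mk_table(cbind(rep(5, 10), rnorm(10)))
  expect_false(any(detect_outliers_3sigma(tab3)[, 1]))
})

test_that("the inequality at exactly three sigma is strict", {
  # symmetric column engineered so the extremes sit at exactly 3 sigma:
  # c(-a, 0, ..., 0, a) with n values has sigma = a*sqrt(2/n); choose n=18
  # so a = 3 * sigma  =>  a = a * 3 * sqrt(2/18) = a, i.e. exactly 3 sigma
  x <- c(-3, rep(0, 16), 3)
  sigma <- sqrt(mean((x - mean(x))^2))
  expect_equal(max(x), 3 * sigma)
  tab <- mk_table(cbind(x, rnorm(18)))
  expect_false(any(detect_outliers_3sigma(tab)[, 1]))
})

test_that("all-missing columns are rejected by name", {
  tab <- mk_table(cbind(NA_real_ * 1:6, rnorm(6)))
  expect_error(detect_outliers_3sigma(tab), "f1")
})

test_that("KNN imputation: k = 1 copies the nearest same-class donor", {
  # feature f1 defines distance; f2 holds the values to impute
  X <- rbind(c(0.00, NA), c(0.10, 7), c(0.90, 9), c(0.05, 3), c(5, 100))
  tab <- mk_table(X, labels = c(1, 1, 1, 0, 1))
  out <- knn_impute(tab, k = 1)
  # nearest same-class donor of sample 1 is sample 2 (d = .1) not 4 (class 0)
  expect_equal(unname(out$values[1, 2]), 7)
  expect_identical(out$values[-1, ], tab$values[-1, ])  # donors untouched
})

test_that("KNN imputation: constant neighborhood returns the constant", {
  X <- cbind(c(0, 1, 2, 3, 4), c(NA, 5, 5, 5, 5))
  tab <- mk_table(X, labels = rep(1, 5))
  for (k in c(1, 3, 10)) {
    expect_equal(unname(knn_impute(tab, k = k)$values[1, 2]), 5)
  }
})

test_that("KNN imputation: k = 3 averages the three nearest donors", {
  # donors at distances .1 < .2 < .3 < .4 < .5 carry values 1, 2, 3, 4, 100
  X <- rbind(c(0.0, NA),
             c(0.1, 1), c(0.2, 2), c(0.3, 3), c(0.4, 4), c(0.5, 100))
  tab <- mk_table(X, labels = rep(1, 6))
  expect_equal(unname(knn_impute(tab, k = 3)$values[1, 2]), 2)
})

test_that("imputation with no eligible donor fails informatively", {
  X <- cbind(c(0, 1, 2), c(NA, 9, 9))
  tab <- mk_table(X, labels = c(1, 0, 0))
  expect_error(knn_impute(tab), "same-class")
})

test_that("imputation never alters unflagged cells and is idempotent", {
  set.seed(31)
  spec <- synthetic_spec(n_samples = 120, seed = 31)
  tab <- generate_pb_table(spec)
  mask <- detect_outliers_3sigma(tab)
  out1 <- knn_impute(tab, mask)
  expect_identical(out1$values[!mask], tab$values[!mask])
  out2 <- knn_impute(out1, mask)    # frozen mask: re-running is a no-op
  expect_equal(out2$values, out1$values)
})

test_that("flag rate on the default generator tracks the configured rate", {
  spec <- synthetic_spec(n_samples = 1000, seed = 13)
  tab <- generate_pb_table(spec)
  rate <- mean(detect_outliers_3sigma(tab))
  expect_lt(abs(rate - spec$outlier_fraction), 0.5 * spec$outlier_fraction)
})

test_that("repeated measurements resolve by least squares", {
  expect_equal(resolve_measurements(5, 7, target_time = 0), 7)
  expect_equal(resolve_measurements(c(0, 2), c(1, 3), target_time = 1), 2)
  # three points: slope/intercept by the normal equations
  t <- c(0, 1, 2); v <- c(1, 1, 4)
  slope <- sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
  icpt <- mean(v) - slope * mean(t)
  expect_equal(resolve_measurements(t, v, target_time = 3),
               icpt + slope * 3, tolerance = 1e-12)
  # repeated records at a single time collapse to their mean
  expect_equal(resolve_measurements(c(2, 2, 2), c(1, 5, 6), 9), 4)
})

test_that("table-level resolution writes resolved cells and clears records", {
  tab <- mk_table(matrix(0, 2, 2), labels = c(0, 1))
  tab$repeated <- data.frame(sample = c(1L, 1L), feature = "f2",
                             time = c(0, 2), value = c(1, 3))
  out <- resolve_repeated_measurements(tab, target_time = 4)
  expect_equal(unname(out$values[1, 2]), 5)   # extrapolated line
  expect_null(out$repeated)
})

test_that("preprocess_pb fits statistics on the requested rows only", {
  set.seed(17)
  X <- matrix(rnorm(60 * 3), 60, 3)
  X[1, 1] <- 100                          # outlier in the held-out part
  tab <- mk_table(X)
  fit_rows <- 31:60
  prep <- preprocess_pb(tab, fit_rows = fit_rows)
  # mu/sigma from fit rows only: the cell is still flagged and imputed
  expect_true(prep$mask[1, 1])
  expect_lt(abs(prep$table$values[1, 1]), 5)
  expect_equal(prep$report$n_flagged, sum(prep$mask))
})
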