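# Tabular preprocessing: 3-sigma outlier screening, class-restricted KNN
# imputation, and least-squares resolution of repeated measurements.

#' Flag cells deviating more than three standard deviations from the mean
#'
#' A cell is flagged iff `|x - mu| > 3 * sigma` with the column mean and
#' population (ddof = 0) standard deviation computed over finite entries.
#' The inequality is strict, so a value at exactly three sigma is kept, and
#' constant columns (`sigma == 0`) flag nothing. To avoid leaking held-out
#' statistics, `fit_rows` restricts the mu/sigma estimation to training rows
#' while the mask still covers every row.
#'
#' @param table a [feature_table()].
#' @param n_sigma flag threshold in standard deviations (default 3).
#' @param fit_rows row indices used to estimate mu and sigma (default: all).
#' @return logical samples-by-features matrix of class `outlier_mask` with
#'   the per-column `mu`/`sigma` attached as attributes.
#' @export
detect_outliers_3sigma <- function(table, n_sigma = 3, fit_rows = NULL) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(X))
  mu <- numeric(ncol(X)); sigma <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[fit_rows, j]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      stop("column '", table$feature_names[j], "' has no finite values")
    }
    if (length(v) < 2L) {
      stop("column '", table$feature_names[j],
           "' needs >= 2 finite values to estimate sigma")
    }
    mu[j] <- mean(v)
    sigma[j] <- sqrt(mean((v - mu[j])^2))   # population SD
  }
  mask <- sweep(abs(sweep(X, 2L, mu)), 2L, n_sigma * sigma, ">")
  mask[!is.finite(X)] <- FALSE
  mask[, sigma == 0] <- FALSE
  structure(mask, mu = mu, sigma = sigma, class = c("outlier_mask", "matrix",
                                                    "array"))
}

#' Class-restricted K-nearest-neighbor imputation
#'
#' Flagged (and missing) cells are treated as unobserved and filled with the
#' mean of the target column over the `k` nearest neighbors, where neighbor
#' search is restricted to samples of the same class. Distances are
#' Euclidean over z-scored, mutually observed, non-flagged columns, rescaled
#' by `sqrt(p / n_shared)` so samples with different observation overlap are
#' comparable (the convention of scikit-learn's KNNImputer, which the study
#' population was processed with). Distance ties prefer the lower sample
#' index. If fewer than `k` eligible donors exist, all of them are used.
#'
#' @param table a [feature_table()].
#' @param mask logical matrix from [detect_outliers_3sigma()] (cells to
#'   treat as missing); `NA` cells in the table are always imputed.
#' @param k neighbor count (default 10).
#' @param donor_rows row indices allowed to act as donors (training rows in
#'   a cross-validation setting); default all rows.
#' @return a [feature_table()] with all flagged/missing cells filled.
#'   Unflagged cells are never altered.
#' @export
knn_impute <- function(table, mask = NULL, k = 10L, donor_rows = NULL) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  n <- nrow(X); p <- ncol(X)
  if (is.null(mask)) mask <- matrix(FALSE, n, p)
  if (!all(dim(mask) == dim(X))) stop("mask shape must match the table")
  if (is.null(donor_rows)) donor_rows <- seq_len(n)
  miss <- mask | !is.finite(X)
  obs <- !miss
  Xobs <- X; Xobs[miss] <- NA_real_

  # z-scoring for the distance metric, over observed cells
  mu <- colMeans(Xobs, na.rm = TRUE)
  sd_ <- apply(Xobs, 2L, function(v) stats::sd(v, na.rm = TRUE))
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  Z <- sweep(sweep(Xobs, 2L, mu), 2L, sd_, "/")

  out <- X
  todo <- which(miss, arr.ind = TRUE)
  if (nrow(todo) == 0L) return(table)
  for (r in seq_len(nrow(todo))) {
    i <- todo[r, 1L]; j <- todo[r, 2L]
    cand <- donor_rows[table$labels[donor_rows] == table$labels[i] &
                         donor_rows != i]
    cand <- cand[obs[cand, j]]
    if (length(cand) == 0L) {
      stop("no eligible same-class donor for sample ", i, ", feature '",
           table$feature_names[j], "'")
    }
    shared <- obs[cand, , drop = FALSE] &
      matrix(obs[i, ], length(cand), p, byrow = TRUE)
    diff2 <- (Z[cand, , drop = FALSE] -
                matrix(Z[i, ], length(cand), p, byrow = TRUE))^2
    diff2[!shared] <- 0
    ns <- rowSums(shared)
    d <- ifelse(ns > 0, sqrt(p / ns * rowSums(diff2)), Inf)
    ord <- order(d, cand)                     # ties -> lower index
    sel <- cand[ord][seq_len(min(k, length(cand)))]
    out[i, j] <- mean(X[sel, j])
  }
  res <- feature_table(out, table$labels, table$feature_names,
                       repeated = table$repeated)
  attr(res, "imputed_cells") <- miss
  res
}

#' Resolve multiple timestamped measurements to one value
#'
#' One record returns its value; two or more records with at least two
#' distinct times are resolved by an ordinary least-squares line of value on
#' time, evaluated at `target_time` (the day of the lung function test);
#' repeated records at a single time collapse to their mean.
#'
#' @param times numeric measurement times.
#' @param values numeric measurement values, same length.
#' @param target_time time at which the resolved value is taken.
#' @return scalar resolved value.
#' @export
resolve_measurements <- function(times, values, target_time) {
  stopifnot(length(times) == length(values), length(times) >= 1L)
  if (length(values) == 1L) return(values)
  if (length(unique(times)) == 1L) return(mean(values))
  fit <- stats::lm.fit(cbind(1, times), values)
  sum(fit$coefficients * c(1, target_time))
}

#' Resolve all repeated-measurement records of a table
#'
#' Applies [resolve_measurements()] to every (sample, feature) group in the
#' table's long-format repeated records and writes the resolved value into
#' the corresponding cell.
#'
#' @param table a [feature_table()] with a `repeated` record frame.
#' @param target_time evaluation time, a scalar or per-sample vector
#'   (default 4, the generator's test-day convention).
#' @return the table with resolved cells and `repeated` set to `NULL`.
#' @export
resolve_repeated_measurements <- function(table, target_time = 4) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$repeated) || nrow(table$repeated) == 0L) return(table)
  tt <- if (length(target_time) == 1L) {
    rep(target_time, nrow(table$values))
  } else target_time
  X <- table$values
  rec <- table$repeated
  for (grp in split(rec, list(rec$sample, rec$feature), drop = TRUE)) {
    i <- grp$sample[1L]
    j <- match(grp$feature[1L], table$feature_names)
    X[i, j] <- resolve_measurements(grp$time, grp$value, tt[i])
  }
  feature_table(X, table$labels, table$feature_names, repeated = NULL)
}

#' Full PB preprocessing pass
#'
#' Repeated-measurement resolution, 3-sigma screening and class-restricted
#' KNN imputation in the order the pipeline applies them. Statistics are fit
#' on `fit_rows` only, so held-out folds never contribute mu/sigma or
#' donors.
#'
#' @param table a [feature_table()].
#' @param k imputation neighbor count.
#' @param n_sigma outlier threshold.
#' @param fit_rows rows used to fit statistics and donate neighbors.
#' @param target_time repeated-measurement evaluation time.
#' @return list with the cleaned `table`, the outlier `mask`, and a `report`
#'   list (flag counts and per-column rates).
#' @export
preprocess_pb <- function(table, k = 10L, n_sigma = 3, fit_rows = NULL,
                          target_time = 4) {
  table <- resolve_repeated_measurements(table, target_time)
  mask <- detect_outliers_3sigma(table, n_sigma = n_sigma, fit_rows = fit_rows)
  cleaned <- knn_impute(table, mask, k = k, donor_rows = fit_rows)
  report <- list(
    n_cells = length(mask),
    n_flagged = sum(mask),
    flag_rate = mean(mask),
    per_column_rate = stats::setNames(colMeans(mask), table$feature_names)
  )
  list(table = cleaned, mask = mask, report = report)
}

#' Write a preprocessing report as JSON
#'
#' @param report the `report` element of [preprocess_pb()].
#' @param path output file.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
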