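# Core S3 containers shared across modules.

#' Construct a PB feature table
#'
#' A samples-by-features matrix of physiological/biochemical indicators with
#' binary stage labels (1 = advanced stage) and, optionally, long-format
#' repeated-measurement records.
#'
#' @param values numeric matrix, samples in rows, indicators in columns.
#'   Missing values are allowed.
#' @param labels integer/numeric vector in \{0, 1\}, one per row.
#' @param feature_names character vector, one per column.
#' @param repeated optional `data.frame` with columns `sample`, `feature`,
#'   `time`, `value` holding multiple timestamped measurements per cell.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, labels, feature_names = colnames(values),
                          repeated = NULL) {
  values <- as.matrix(values)
  if (is.null(feature_names)) {
    feature_names <- paste0("feature_", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length (", length(feature_names),
         ") != number of columns (", ncol(values), ")")
  }
  if (length(labels) != nrow(values)) {
    stop("labels length (", length(labels), ") != number of rows (",
         nrow(values), ")")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (!is.null(repeated)) {
    need <- c("sample", "feature", "time", "value")
    if (!all(need %in% names(repeated))) {
      stop("repeated records need columns: ", paste(need, collapse = ", "))
    }
  }
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = as.integer(labels), repeated = repeated),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " indicators; ", sum(x$labels), " advanced-stage\n", sep = "")
  if (!is.null(x$repeated)) {
    cat("  repeated measurements: ", nrow(x$repeated), " records\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Construct a CT volume
#'
#' @param voxels 3D numeric array (depth, height, width) of Hounsfield units.
#' @param spacing voxel spacing in mm, length 3.
#' @param sample_id identifier linking the volume to a table row.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), sample_id = NA_character_) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (!all(is.finite(voxels))) stop("voxels must be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 sample_id = sample_id),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<ct_volume> ", paste(d, collapse = "x"), " voxels, HU range [",
      round(min(x$voxels)), ", ", round(max(x$voxels)), "], id=", x$sample_id,
      "\n", sep = "")
  invisible(x)
}

#' Construct a paired tabular + volumetric dataset
#'
#' @param table a [feature_table()].
#' @param volumes list of [ct_volume()] objects, one per table row.
#' @param labels binary stage labels (1 = advanced stage).
#' @param split_assignments optional per-sample partition ids.
#' @return an object of class `paired_dataset`.
#' @export
paired_dataset <- function(table, volumes, labels = table$labels,
                           split_assignments = NULL) {
  if (length(volumes) != nrow(table$values)) {
    stop("number of volumes (", length(volumes),
         ") != number of table rows (", nrow(table$values), ")")
  }
  if (length(labels) != length(volumes)) stop("labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  structure(list(table = table, volumes = volumes, labels = as.integer(labels),
                 split_assignments = split_assignments),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat("<paired_dataset> ", length(x$labels), " samples (",
      sum(x$labels), " advanced-stage); volumes ",
      paste(dim(x$volumes[[1]]$voxels), collapse = "x"), "\n", sep = "")
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}
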