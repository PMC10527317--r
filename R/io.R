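# Dataset serialization: CSV tables, long-format repeated measurements,
# NIfTI volumes and a JSON manifest linking sample ids to files.

#' Write a paired dataset to disk
#'
#' Layout: `table.csv` (sample_id, indicators, label), `repeated.csv`
#' (sample_id, feature, time, value; only when present), one NIfTI file per
#' volume under `volumes/`, and `manifest.json` mapping sample ids to
#' files.
#'
#' @param dataset a [paired_dataset()].
#' @param dir output directory (created if needed).
#' @param compress write `.nii.gz` (default) or plain `.nii`.
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir, compress = TRUE) {
  stopifnot(inherits(dataset, "paired_dataset"))
  dir.create(file.path(dir, "volumes"), showWarnings = FALSE,
             recursive = TRUE)
  ids <- vapply(dataset$volumes, function(v) v$sample_id, character(1))
  if (anyNA(ids)) ids <- sprintf("S%04d", seq_along(dataset$volumes))
  df <- data.frame(sample_id = ids, dataset$table$values,
                   label = dataset$labels, check.names = FALSE)
  utils::write.csv(df, file.path(dir, "table.csv"), row.names = FALSE)
  if (!is.null(dataset$table$repeated)) {
    rep_df <- dataset$table$repeated
    rep_df$sample_id <- ids[rep_df$sample]
    utils::write.csv(rep_df[, c("sample_id", "feature", "time", "value")],
                     file.path(dir, "repeated.csv"), row.names = FALSE)
  }
  ext <- if (compress) ".nii.gz" else ".nii"
  files <- character(length(ids))
  for (i in seq_along(ids)) {
    files[i] <- file.path("volumes", paste0(ids[i], ext))
    RNifti::writeNifti(dataset$volumes[[i]]$voxels,
                       file.path(dir, files[i]))
  }
  manifest <- list(
    n_samples = length(ids),
    volume_shape = dim(dataset$volumes[[1]]$voxels),
    samples = data.frame(sample_id = ids, volume = files,
                         label = dataset$labels)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a paired dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return a [paired_dataset()].
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  tab <- utils::read.csv(file.path(dir, "table.csv"), check.names = FALSE)
  ids <- tab$sample_id
  values <- as.matrix(tab[, setdiff(names(tab), c("sample_id", "label")),
                          drop = FALSE])
  repeated <- NULL
  if (file.exists(file.path(dir, "repeated.csv"))) {
    rep_df <- utils::read.csv(file.path(dir, "repeated.csv"))
    rep_df$sample <- match(rep_df$sample_id, ids)
    repeated <- rep_df[, c("sample", "feature", "time", "value")]
  }
  table <- feature_table(values, tab$label, colnames(values), repeated)
  volumes <- lapply(seq_len(nrow(manifest$samples)), function(i) {
    f <- file.path(dir, manifest$samples$volume[i])
    if (!file.exists(f)) {
      stop("manifest names a missing volume for sample '",
           manifest$samples$sample_id[i], "': ", f)
    }
    vox <- as.array(RNifti::readNifti(f))
    ct_volume(vox, sample_id = manifest$samples$sample_id[i])
  })
  paired_dataset(table, volumes, tab$label)
}

#' Write per-indicator selection scores as CSV
#'
#' @param scores data frame from [pooling_scores()] or an
#'   `indicator_report`.
#' @param path output file.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}
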