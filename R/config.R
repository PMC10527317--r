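# YAML run configuration: nested sections per pipeline stage, strict key
# validation, and resolved-config provenance written next to every run's
# outputs.

default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "copdfuse_run",
    synthetic_data = list(n_samples = 300L, n_features = 24L,
                          modality_signal = "complementary",
                          outlier_fraction = 0.0167,
                          repeated_meas_rate = 0.05,
                          volume_shape = c(16L, 32L, 32L),
                          label_balance = 0.5),
    pb_preprocess = list(k = 10L, n_sigma = 3, target_time = 4),
    gnn = list(n_layers = 4L, hidden_dim = 16L, dropout = 0.1,
               pooling_ratio = 0.5, out_dim = 64L, lr = 3e-3,
               epochs = 200L, batch_size = 48L),
    cnn = list(backbone = "resnet_lite_3d", out_dim = 64L,
               epochs = 15L, batch_size = 10L, augment = TRUE),
    fusion = list(rank = 4L, tokens = 8L, d_model = 32L, heads = 4L,
                  lr = 1e-3, epochs = 10L, batch_size = 10L),
    train_eval = list(mode = "ratio_3_1_1", folds = 5L, pretrain_ct = TRUE,
                      shortlist = 4L)
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) stop("unknown config key: ", here)
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected with the offending path; omitted keys take
#' the package defaults.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  structure(cfg, class = "run_config")
}

#' Write the fully resolved configuration next to a run's outputs
#'
#' @param config a `run_config`.
#' @param dir output directory.
#' @return invisibly, the path written.
#' @export
write_resolved_config <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Turn config sections into the typed constructor calls.
config_to_spec <- function(cfg) {
  s <- cfg$synthetic_data
  synthetic_spec(n_samples = s$n_samples, n_features = s$n_features,
                 modality_signal = s$modality_signal,
                 outlier_fraction = s$outlier_fraction,
                 repeated_meas_rate = s$repeated_meas_rate,
                 volume_shape = unlist(s$volume_shape),
                 label_balance = s$label_balance, seed = cfg$seed)
}

config_to_gnn <- function(cfg) {
  do.call(gnn_config, c(cfg$gnn, list(seed = cfg$seed)))
}

config_to_cnn <- function(cfg) {
  do.call(cnn_config, c(cfg$cnn, list(seed = cfg$seed)))
}

config_to_fusion <- function(cfg) {
  do.call(fusion_config, c(cfg$fusion, list(seed = cfg$seed)))
}
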