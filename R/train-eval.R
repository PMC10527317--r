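# Splits, joint end-to-end training, confusion-matrix metrics and AUC,
# cross-validation, indicator ranking and group statistics.

#' Stratified data splits
#'
#' `ratio_3_1_1` partitions each class 60/20/20 into train/validation/test;
#' `kfold` assigns stratified fold ids. Both are deterministic under
#' `seed`.
#'
#' @param labels binary label vector.
#' @param mode `"ratio_3_1_1"` or `"kfold"`.
#' @param folds fold count for `kfold` (default 5).
#' @param seed RNG seed.
#' @return for ratio mode, a list of disjoint, exhaustive index vectors
#'   `train`, `val`, `test`; for kfold mode, an integer fold id per sample
#'   (every class appears in every fold).
#' @export
make_splits <- function(labels, mode = c("ratio_3_1_1", "kfold"), folds = 5L,
                        seed = 1L) {
  mode <- match.arg(mode)
  n <- length(labels)
  with_seed(seed, {
    if (mode == "ratio_3_1_1") {
      train <- integer(); val <- integer(); test <- integer()
      for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        nc <- length(idx)
        ntr <- round(0.6 * nc); nva <- round(0.2 * nc)
        train <- c(train, idx[seq_len(ntr)])
        val <- c(val, idx[ntr + seq_len(nva)])
        test <- c(test, idx[(ntr + nva + 1L):nc])
      }
      list(train = sort(train), val = sort(val), test = sort(test))
    } else {
      fold <- integer(n)
      for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        if (length(idx) < folds) {
          stop("class ", cl, " has fewer samples (", length(idx),
               ") than folds (", folds, ")")
        }
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
      fold
    }
  })
}

#' Confusion counts with late-stage COPD as the positive class
#'
#' @param pred predicted 0/1 labels.
#' @param labels true 0/1 labels.
#' @return list of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, labels) {
  stopifnot(length(pred) == length(labels))
  structure(list(TP = sum(pred == 1 & labels == 1),
                 FP = sum(pred == 1 & labels == 0),
                 FN = sum(pred == 0 & labels == 1),
                 TN = sum(pred == 0 & labels == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (recall), specificity and F1 by their
#' standard confusion-matrix formulas. A metric whose denominator is zero
#' is reported as `NA`, never silently as 0.
#'
#' @param counts a [confusion_counts()] or list/vector with `TP`, `FP`,
#'   `FN`, `TN`.
#' @return list of class `metrics_record` with `acc`, `pre`, `sen`, `spe`,
#'   `f1`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  if (any(c(TP, FP, FN, TN) < 0)) stop("counts must be non-negative")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- sdiv(TP + TN, TP + TN + FP + FN)
  pre <- sdiv(TP, TP + FP)
  sen <- sdiv(TP, TP + FN)
  spe <- sdiv(TN, TN + FP)
  f1 <- if (!is.na(pre) && !is.na(sen) && (pre + sen) > 0) {
    2 * pre * sen / (pre + sen)
  } else NA_real_
  structure(list(acc = acc, pre = pre, sen = sen, spe = spe, f1 = f1),
            class = "metrics_record")
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half (rank / Mann-Whitney
#' formulation).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels true 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)               # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate class probabilities against labels
#'
#' Thresholds the advanced-stage probability at 0.5, computes the
#' confusion-matrix metrics and the AUC of the probability itself.
#'
#' @param prob `n x 2` softmax matrix (column 2 = advanced stage) or a
#'   vector of advanced-stage probabilities.
#' @param labels true 0/1 labels.
#' @return a `metrics_record` with `auc` added.
#' @export
evaluate_predictions <- function(prob, labels) {
  p1 <- if (is.matrix(prob)) prob[, 2L] else prob
  m <- compute_metrics(confusion_counts(as.integer(p1 > 0.5), labels))
  m$auc <- auc(p1, labels)
  m
}

metrics_df <- function(m) {
  as.data.frame(m[c("acc", "pre", "sen", "spe", "f1", "auc")])
}

# ---- joint end-to-end training -------------------------------------------

prefix_params <- function(params, prefix) {
  stats::setNames(params, paste0(prefix, names(params)))
}

strip_prefix <- function(params, prefix) {
  sel <- startsWith(names(params), prefix)
  stats::setNames(params[sel], substring(names(params)[sel],
                                         nchar(prefix) + 1L))
}

#' Jointly train the PB, CT and fusion networks end to end
#'
#' Builds the three sub-models (graph topology, HU window and
#' standardization statistics from the training samples only), optionally
#' initializes the CT branch by image-only pretraining, then updates every
#' parameter jointly by minibatch Adam on the cross-entropy of the fused
#' head. If the loss turns non-finite the last completed epoch's
#' parameters are restored.
#'
#' @param dataset a [paired_dataset()] of *training* samples, already
#'   preprocessed (no missing PB values).
#' @param gnn,cnn,fusion branch configurations ([gnn_config()],
#'   [cnn_config()], [fusion_config()]); fusion's `lr`, `epochs` and
#'   `batch_size` drive the joint loop.
#' @param pretrain_ct pretrain the CT branch on the image-only task first.
#' @param ct_init optional already-pretrained [ct_model()] used to
#'   initialize the CT branch (overrides `pretrain_ct`).
#' @param pb_init optional already-trained [pb_model()] used to initialize
#'   the PB branch (its graph and standardization are reused), keeping the
#'   joint fine-tuning loop short.
#' @param graph optional pre-built feature graph.
#' @param hu_window optional fixed HU normalization window.
#' @param val_dataset optional [paired_dataset()] used for best-epoch
#'   parameter selection (checked after every joint epoch).
#' @param verbose print the joint loss each epoch.
#' @return an object of class `joint_model` with elements `pb`, `ct`,
#'   `fusion` and a loss `history`.
#' @export
train_joint <- function(dataset, gnn = gnn_config(), cnn = cnn_config(),
                        fusion = fusion_config(), pretrain_ct = TRUE,
                        ct_init = NULL, pb_init = NULL, graph = NULL,
                        hu_window = NULL, val_dataset = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(dataset, "paired_dataset"))
  if (gnn$out_dim != cnn$out_dim) {
    stop("PB and CT branches must share out_dim")
  }
  table <- dataset$table
  if (any(!is.finite(table$values))) stop("preprocess the PB table first")
  y <- dataset$labels + 1L

  if (!is.null(pb_init)) {
    pb <- pb_init
    gnn <- pb$config
  } else {
    if (is.null(graph)) graph <- build_feature_graph(table)
    center <- colMeans(table$values)
    scale <- apply(table$values, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    pb <- pb_model(graph, gnn, center, scale)
  }

  raw <- inherits(dataset$volumes[[1]], "ct_volume")
  if (is.null(hu_window)) {
    hu_window <- if (raw) hu_range_from_volumes(dataset$volumes) else c(0, 1)
  }
  if (!is.null(ct_init)) {
    ct <- ct_init
    hu_window <- ct$hu_window
    cnn <- ct$config
  } else if (pretrain_ct) {
    ct <- pretrain_cnn(dataset$volumes, dataset$labels, cnn,
                       hu_window = hu_window, verbose = verbose)
  } else {
    ct <- ct_model(cnn)
    ct$hu_window <- hu_window
  }
  fus <- fusion_model(fusion)

  prepped <- if (raw) {
    prepare_volumes(dataset$volumes, hu_window, cnn$input_shape)
  } else {
    lapply(dataset$volumes, crop_resize, target_shape = cnn$input_shape)
  }
  if (is.null(ct_init) && !pretrain_ct) {
    vx <- unlist(lapply(prepped, function(v) as.vector(v$voxels)))
    ct$input_center <- mean(vx)
    ct$input_scale <- max(stats::sd(vx), 1e-8)
  }
  Xs <- pb_standardize(pb, table$values)
  n <- length(y)

  params <- c(prefix_params(pb$params, "pb."),
              prefix_params(ct$params, "ct."),
              prefix_params(fus$params, "fus."))
  scale <- ifelse(startsWith(names(params), "fus."), 1,
                  fusion$branch_lr_scale)
  opt <- adam_init(params, lr = fusion$lr,
                   weight_decay = fusion$weight_decay,
                   lr_scale = as.list(stats::setNames(scale,
                                                      names(params))))
  losses <- numeric(fusion$epochs)
  best <- list(acc = -Inf, params = NULL)
  model_sync <- function(params) {
    pb$params <<- strip_prefix(params, "pb.")
    ct$params <<- strip_prefix(params, "ct.")
    fus$params <<- strip_prefix(params, "fus.")
  }
  with_seed(fusion$seed + 2L, {
    for (ep in seq_len(fusion$epochs)) {
      last_good <- params
      perm <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = fusion$batch_size)) {
        idx <- perm[start:min(start + fusion$batch_size - 1L, n)]
        batch_vols <- prepped[idx]
        if (cnn$augment) {
          batch_vols <- lapply(batch_vols, augment_rotate,
                               max_deg = cnn$max_rotate_deg, fill = 0)
        }
        x5 <- stack_volumes(batch_vols, cnn$input_shape)
        x5 <- (x5 - ct$input_center) / ct$input_scale
        tape <- ad_tape(training = TRUE)
        leaves <- ad_params(tape, params)
        pbout <- pb_forward_tape(tape, strip_prefix(leaves, "pb."), pb,
                                 Xs[idx, , drop = FALSE])
        ctout <- ct_forward_tape(tape, strip_prefix(leaves, "ct."), ct, x5)
        fout <- fusion_forward_tape(tape, strip_prefix(leaves, "fus."), fus,
                                    pbout$z_a, ctout$z_v, length(idx))
        loss <- ad_softmax_ce(fout$logits, y[idx])
        if (!is.finite(loss$value)) {
          warning("non-finite loss at epoch ", ep,
                  "; restoring last completed epoch")
          params <- last_good
          break
        }
        ad_backward(loss)
        params <- adam_step(opt, params, ad_grads(leaves))
        tot <- tot + loss$value * length(idx)
      }
      losses[ep] <- tot / n
      if (!is.null(val_dataset)) {
        model_sync(params)
        pv <- predict_joint(list(pb = pb, ct = ct, fusion = fus),
                            val_dataset$table, val_dataset$volumes)
        acc <- mean(pv$pred == val_dataset$labels)
        if (acc >= best$acc) best <- list(acc = acc, params = params)
      }
      if (verbose) message(sprintf("joint epoch %d loss %.4f", ep,
                                   losses[ep]))
    }
  })
  if (!is.null(best$params)) params <- best$params
  model_sync(params)
  structure(list(pb = pb, ct = ct, fusion = fus,
                 history = data.frame(epoch = seq_len(fusion$epochs),
                                      loss = losses)),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat("<joint_model> PB + CT + fusion; final joint loss ",
      round(utils::tail(x$history$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Predict with a jointly trained model
#'
#' @param model a [train_joint()] result.
#' @param table a [feature_table()] (preprocessed).
#' @param volumes matching list of volumes (raw HU or normalized).
#' @return list with `prob`, `pred`, `z_a`, `z_v`.
#' @export
predict_joint <- function(model, table, volumes) {
  X <- if (inherits(table, "feature_table")) table$values else
    as.matrix(table)
  pbout <- pb_forward(X, model$pb)
  raw <- inherits(volumes[[1]], "ct_volume")
  prepped <- if (raw) {
    prepare_volumes(volumes, model$ct$hu_window, model$ct$config$input_shape)
  } else {
    lapply(volumes, crop_resize,
           target_shape = model$ct$config$input_shape)
  }
  ctout <- cnn_forward(prepped, model$ct)
  fout <- fuse_forward(pbout$z_a, ctout$z_v, model$fusion)
  list(prob = fout$prob, pred = as.integer(fout$prob[, 2L] > 0.5),
       z_a = pbout$z_a, z_v = ctout$z_v)
}

#' Five-fold cross-validated evaluation
#'
#' Runs the full leak-free pipeline per fold: preprocessing statistics,
#' graph topology, standardization and the HU window are fit on the
#' training portion only; the model is trained on it and evaluated on the
#' held-out fold; metrics are averaged across folds.
#'
#' @param dataset a [paired_dataset()] (PB table may contain outliers /
#'   repeated records; each fold preprocesses with its own training
#'   statistics).
#' @param folds fold count.
#' @param seed split seed.
#' @param ... configuration arguments passed to [train_joint()].
#' @return list with `per_fold` (data frame of metrics) and `mean`
#'   (column means).
#' @export
cross_validate_joint <- function(dataset, folds = 5L, seed = 1L, ...) {
  fold_id <- make_splits(dataset$labels, "kfold", folds = folds, seed = seed)
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    prep <- preprocess_pb(dataset$table, fit_rows = tr)
    tr_ds <- paired_dataset(
      feature_table(prep$table$values[tr, , drop = FALSE],
                    dataset$labels[tr], dataset$table$feature_names),
      dataset$volumes[tr], dataset$labels[tr])
    model <- train_joint(tr_ds, ...)
    te_tab <- feature_table(prep$table$values[te, , drop = FALSE],
                            dataset$labels[te],
                            dataset$table$feature_names)
    pred <- predict_joint(model, te_tab, dataset$volumes[te])
    rows[[f]] <- metrics_df(evaluate_predictions(pred$prob,
                                                 dataset$labels[te]))
  }
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold, mean = colMeans(per_fold, na.rm = TRUE))
}

# ---- indicator ranking ----------------------------------------------------

#' Rank indicators by pooling score and ablation performance drop
#'
#' Reproduces the two-stage selection: the TopK pooling scores shortlist
#' the candidate indicators, then each candidate is removed in turn by
#' substituting its column with the training mean and the decrease in
#' accuracy on the evaluation set is recorded. Candidates are ranked by
#' accuracy drop (ties broken by the larger pooled score) and the top `q`
#' form the final shortlist.
#'
#' @param model a trained [pb_model()] or `joint_model`.
#' @param table evaluation [feature_table()].
#' @param volumes evaluation volumes (joint models only).
#' @param q shortlist size (default 4).
#' @param candidates optional candidate indices; defaults to the pooling
#'   selection from [pooling_scores()].
#' @return data frame of class `indicator_report`: `indicator`, `mean_z`,
#'   `acc_drop`, `rank`, `shortlisted`, ordered by rank.
#' @export
rank_indicators <- function(model, table, volumes = NULL, q = 4L,
                            candidates = NULL) {
  joint <- inherits(model, "joint_model")
  pbm <- if (joint) model$pb else model
  labels <- table$labels
  predict_fn <- function(tab) {
    if (joint) predict_joint(model, tab, volumes)$prob
    else predict_pb(pbm, tab)$prob
  }
  ps <- pooling_scores(pbm, table)
  ps <- ps[match(pbm$graph$feature_names, ps$indicator), ]
  if (is.null(candidates)) candidates <- which(ps$selected)
  base_prob <- predict_fn(table)
  base_acc <- mean(as.integer(base_prob[, 2L] > 0.5) == labels)
  drops <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    j <- candidates[ci]
    ablated <- table
    ablated$values[, j] <- pbm$center[j]   # training-mean substitution
    prob <- predict_fn(ablated)
    drops[ci] <- base_acc -
      mean(as.integer(prob[, 2L] > 0.5) == labels)
  }
  ord <- order(-drops, -ps$mean_z[candidates], candidates)
  report <- data.frame(indicator = pbm$graph$feature_names[candidates],
                       index = candidates,
                       mean_z = ps$mean_z[candidates],
                       acc_drop = drops)
  report <- report[ord, ]
  report$rank <- seq_len(nrow(report))
  report$shortlisted <- report$rank <= q
  class(report) <- c("indicator_report", "data.frame")
  attr(report, "base_acc") <- base_acc
  report
}

#' Two-group statistics for an indicator
#'
#' Values are z-score normalized over all samples, then compared between
#' the early (label 0) and advanced (label 1) groups with an independent
#' two-sample t-test (Student's pooled-variance by default, Welch by
#' flag). Reports the early-minus-advanced mean difference with its 95%
#' confidence interval. When both groups are constant the test is
#' undefined and reported as such.
#'
#' @param values numeric indicator values.
#' @param labels 0/1 group labels (>= 2 samples per group).
#' @param welch use the Welch (unequal-variance) test.
#' @return list with `difference`, `ci` (length 2), `t`, `p`, `df`,
#'   `undefined`.
#' @export
group_statistics <- function(values, labels, welch = FALSE) {
  stopifnot(length(values) == length(labels))
  g0 <- values[labels == 0]; g1 <- values[labels == 1]
  if (length(g0) < 2L || length(g1) < 2L) {
    stop("need >= 2 samples per group")
  }
  z <- (values - mean(values)) / stats::sd(values)
  z0 <- z[labels == 0]; z1 <- z[labels == 1]
  if (stats::var(z0) == 0 && stats::var(z1) == 0) {
    return(list(difference = mean(z0) - mean(z1), ci = c(NA_real_, NA_real_),
                t = NA_real_, p = NA_real_, df = NA_real_, undefined = TRUE))
  }
  tt <- stats::t.test(z0, z1, var.equal = !welch)
  list(difference = unname(mean(z0) - mean(z1)),
       ci = unname(tt$conf.int), t = unname(tt$statistic),
       p = tt$p.value, df = unname(tt$parameter), undefined = FALSE)
}

#' Write per-fold and aggregate metrics as JSON and CSV
#'
#' @param per_fold data frame of per-fold metrics.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_metrics <- function(per_fold, dir, prefix = "metrics") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  json <- file.path(dir, paste0(prefix, ".json"))
  utils::write.csv(per_fold, csv, row.names = FALSE)
  jsonlite::write_json(list(per_fold = per_fold,
                            mean = as.list(colMeans(per_fold, na.rm = TRUE))),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, json))
}
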