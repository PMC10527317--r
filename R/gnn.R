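# The PB branch: mean-aggregation GNN over the indicator correlation graph,
# TopK pooling, multi-scale mean/max readout, a 64-d feature head and a
# classification head.
#
# Node i of the graph carries, for one sample, the scalar value of indicator
# i, lifted to the hidden dimension by a learned linear embedding. Each GNN
# layer averages neighbor states (the node's own state enters through
# concatenation), applies a dense map with ReLU and dropout, and L2
# normalizes every nonzero state row. A single TopK pooling layer follows
# the last convolution; the readout concatenates mean- and max-pooled
# statistics of every layer's states (restricted to the surviving nodes)
# and sums them across layers.

#' GNN branch configuration
#'
#' @param n_layers number of message-passing layers (default 4).
#' @param hidden_dim hidden state width, constant across layers.
#' @param dropout dropout probability after each layer's ReLU.
#' @param input_dropout probability of zeroing an (already standardized)
#'   indicator value during training. Zeroing a standardized value is
#'   mean substitution, the same semantics the ablation ranking uses; the
#'   regularization spreads the model's reliance over all informative
#'   indicators instead of letting a redundant subset carry the fit.
#' @param pooling_ratio TopK keep ratio k in (0, 1).
#' @param out_dim modality feature dimension (default 64).
#' @param lr Adam learning rate.
#' @param epochs,batch_size training loop sizes.
#' @param weight_decay decoupled L2 coefficient.
#' @param seed RNG seed for initialization and batching.
#' @return a `gnn_config` list.
#' @export
gnn_config <- function(n_layers = 4L, hidden_dim = 16L, dropout = 0.1,
                       input_dropout = 0.15,
                       pooling_ratio = 0.5, out_dim = 64L, lr = 3e-3,
                       epochs = 200L, batch_size = 48L, weight_decay = 0,
                       seed = 1L) {
  if (pooling_ratio <= 0 || pooling_ratio >= 1) {
    stop("pooling_ratio must be in (0, 1)")
  }
  if (n_layers < 1L) stop("n_layers must be >= 1")
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim), dropout = dropout,
                 input_dropout = input_dropout,
                 pooling_ratio = pooling_ratio, out_dim = as.integer(out_dim),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "gnn_config")
}

#' Lift one sample's indicator values to initial node states
#'
#' Node i's initial hidden state is the scalar value of indicator i for this
#' sample mapped through a learned linear embedding,
#' `h_i = x_i * w + b (+ B_i)`, where the optional per-node term `B_i` is a
#' learned indicator-identity embedding (without it, nodes with identical
#' neighborhoods are interchangeable to the permutation-invariant readout).
#'
#' @param graph a [build_feature_graph()] result.
#' @param sample_row numeric vector, one value per node.
#' @param weight embedding weights, length `hidden_dim`.
#' @param bias embedding bias, length `hidden_dim` (default 0).
#' @param node_embedding optional `n_nodes x hidden_dim` per-node matrix.
#' @return `n_nodes x hidden_dim` state matrix.
#' @export
init_node_states <- function(graph, sample_row, weight, bias = 0,
                             node_embedding = NULL) {
  if (length(sample_row) != graph$n_nodes) {
    stop("sample_row length must equal n_nodes")
  }
  weight <- as.vector(weight)
  H <- sweep(outer(as.vector(sample_row), weight), 2L,
             rep_len(bias, length(weight)), "+")
  if (!is.null(node_embedding)) H <- H + node_embedding
  H
}

#' One GNN layer: neighbor mean, concat, dense + ReLU, L2 row normalization
#'
#' For each node the aggregation is the mean of its neighbors' states (a
#' zero vector for isolated nodes); the node's own state is concatenated
#' with the aggregate, mapped by `W` (shape `2*hidden x hidden`) plus bias,
#' passed through ReLU, and each nonzero row is L2 normalized.
#'
#' @param states `n_nodes x hidden` state matrix.
#' @param graph a [build_feature_graph()] result.
#' @param params list with `W` (`2*hidden x hidden`) and `b` (length hidden).
#' @param dropout dropout probability, applied only when `training = TRUE`.
#' @param training logical.
#' @return updated state matrix; every row of pre-normalization norm at
#'   least `1e-3` has exactly unit L2 norm, ReLU-killed rows stay near
#'   zero (clamped denominator, so the map is continuous through zero).
#' @export
gnn_layer <- function(states, graph, params, dropout = 0, training = FALSE) {
  states <- as.matrix(states)
  if (nrow(states) != graph$n_nodes) stop("states/graph dimension mismatch")
  if (nrow(params$W) != 2L * ncol(states) ||
      ncol(params$W) != ncol(states)) {
    stop("W must be (2*hidden) x hidden")
  }
  A <- graph_mean_operator(graph)
  agg <- as.matrix(A %*% states)
  H <- cbind(states, agg) %*% params$W
  H <- sweep(H, 2L, as.vector(params$b), "+")
  H <- pmax(H, 0)
  if (training && dropout > 0) {
    keep <- (stats::runif(length(H)) >= dropout) / (1 - dropout)
    H <- H * keep
  }
  nrm <- sqrt(rowSums(H^2))
  H / pmax(nrm, 1e-3)   # clamped denominator; see the tape op ad_rownorm
}

#' TopK graph pooling
#'
#' Scores every node by the normalized projection `z = X p / ||p||`, keeps
#' the `ceiling(k * N)` nodes with the largest score (ties prefer the lower
#' original index), and gates the kept rows by `sigmoid(z)` so the
#' projection vector receives gradient during training. The sigmoid (rather
#' than an odd gate such as tanh) makes usefulness monotone in z: a node
#' can only contribute to the readout by raising its score, which keeps the
#' top-z selection aligned with the nodes the model actually relies on.
#'
#' @param states `N x d` node state matrix.
#' @param p projection vector, length `d`, must be nonzero.
#' @param ratio keep ratio k in (0, 1].
#' @return list with `indices` (kept original node ids, ascending),
#'   `scores` (z for all N nodes), `projection` (p), and `pooled`
#'   (gated kept rows `X[i, ] * sigmoid(z_i)`).
#' @export
topk_pool <- function(states, p, ratio) {
  states <- as.matrix(states)
  p <- as.vector(p)
  nrm <- sqrt(sum(p^2))
  if (nrm == 0) stop("projection vector p must be nonzero")
  n_keep <- ceiling(ratio * nrow(states))
  if (n_keep < 1L) stop("ceiling(k * N) must be >= 1")
  z <- as.vector(states %*% p) / nrm
  ord <- order(-z, seq_along(z))          # ties -> lower original index
  idx <- sort(ord[seq_len(min(n_keep, length(z)))])
  list(indices = idx, scores = z, projection = p,
       pooled = states[idx, , drop = FALSE] * stats::plogis(z[idx]))
}

#' Multi-scale graph readout
#'
#' Per layer, concatenates the column-wise mean and maximum over the active
#' nodes (`S_l = mean || max`, length `2 * hidden`), then sums the per-layer
#' summaries into the graph vector `s`.
#'
#' @param per_layer_states list of `n_active x hidden` matrices sharing the
#'   same hidden width.
#' @return list with `per_layer` (list of `S_l`) and `s` (their sum).
#' @export
readout <- function(per_layer_states) {
  if (!length(per_layer_states)) stop("need at least one layer")
  per_layer <- lapply(per_layer_states, function(H) {
    H <- as.matrix(H)
    if (nrow(H) == 0L) stop("readout over an empty node set")
    c(colMeans(H), apply(H, 2L, max))
  })
  d <- unique(vapply(per_layer, length, integer(1)))
  if (length(d) != 1L) stop("layers must share hidden_dim")
  list(per_layer = per_layer, s = Reduce(`+`, per_layer))
}

# ---- model ---------------------------------------------------------------

pb_init_params <- function(config, n_nodes) {
  d <- config$hidden_dim
  # B_emb: learned per-node (indicator identity) embedding added to the
  # scalar lift; without it, nodes with identical neighborhoods are
  # interchangeable and the readout cannot attribute signal to specific
  # indicators
  params <- list(W_emb = xavier_init(c(1, d)), b_emb = numeric(d),
                 B_emb = xavier_init(c(n_nodes, d)))
  for (l in seq_len(config$n_layers)) {
    params[[paste0("W", l)]] <- xavier_init(c(2 * d, d))
    params[[paste0("b", l)]] <- numeric(d)
  }
  params$p_vec <- as.vector(xavier_init(c(d, 1)))
  params$W_feat <- xavier_init(c(2 * d, config$out_dim))
  params$b_feat <- numeric(config$out_dim)
  params$W_cls <- xavier_init(c(config$out_dim, 2))
  params$b_cls <- numeric(2)
  params
}

#' Create an (untrained) PB branch model
#'
#' Parameters are Xavier-initialized under `config$seed`.
#'
#' @param graph a [build_feature_graph()] result (training-set topology).
#' @param config a [gnn_config()].
#' @param center,scale per-indicator standardization applied to inputs.
#' @return an object of class `pb_model`.
#' @export
pb_model <- function(graph, config = gnn_config(),
                     center = rep(0, graph$n_nodes),
                     scale = rep(1, graph$n_nodes)) {
  params <- with_seed(config$seed, pb_init_params(config, graph$n_nodes))
  cache <- new.env(parent = emptyenv())
  structure(list(graph = graph, config = config, params = params,
                 center = center, scale = scale, cache = cache,
                 history = NULL),
            class = "pb_model")
}

#' @export
print.pb_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<pb_model> ", x$graph$n_nodes, " nodes, ", x$config$n_layers,
      " layers, hidden ", x$config$hidden_dim, ", ", np, " parameters\n",
      sep = "")
  invisible(x)
}

# Cached batch operators for batch size B: block adjacency and the
# selected-node group-mean matrix.
pb_batch_ops <- function(model, B) {
  key <- as.character(B)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  N <- model$graph$n_nodes
  ksel <- ceiling(model$config$pooling_ratio * N)
  A <- graph_mean_operator(model$graph)
  ops <- list(
    Ablock = Matrix::bdiag(rep(list(A), B)),
    Msel = Matrix::sparseMatrix(i = rep(seq_len(B), each = ksel),
                                j = seq_len(B * ksel), x = 1 / ksel,
                                dims = c(B, B * ksel)),
    ksel = ksel
  )
  model$cache[[key]] <- ops
  ops
}

# Tape forward over a batch. X: B x n_nodes (already standardized).
# Returns nodes: z_a (B x out_dim), logits (B x 2), plus selection info.
pb_forward_tape <- function(tape, leaves, model, X) {
  cfg <- model$config
  N <- model$graph$n_nodes
  B <- nrow(X)
  ops <- pb_batch_ops(model, B)
  xvec <- matrix(as.vector(t(X)), ncol = 1)                 # sample-major
  if (tape$training && cfg$input_dropout > 0) {
    # zeroing a standardized indicator = substituting its training mean
    xvec[stats::runif(length(xvec)) < cfg$input_dropout] <- 0
  }
  xcol <- ad_leaf(tape, xvec)
  H <- ad_add_tile(ad_linear(xcol, leaves$W_emb, leaves$b_emb),
                   leaves$B_emb, B)
  layer_states <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    Hagg <- ad_spmatmul(ops$Ablock, H)
    Hc <- ad_concat_cols(H, Hagg)
    H <- ad_relu(ad_linear(Hc, leaves[[paste0("W", l)]],
                           leaves[[paste0("b", l)]]))
    H <- ad_dropout(H, cfg$dropout)
    H <- ad_rownorm(H)
    layer_states[[l]] <- H
  }
  z <- ad_project(H, leaves$p_vec)
  zv <- as.vector(z$value)
  sel <- integer(B * ops$ksel)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    zb <- zv[rows]
    ord <- order(-zb, seq_len(N))
    keep <- sort(ord[seq_len(ops$ksel)])
    sel[((b - 1L) * ops$ksel + 1L):(b * ops$ksel)] <- rows[keep]
  }
  gate <- ad_sigmoid_op(z)
  Hgated <- ad_rowscale(H, gate)
  pooled_states <- c(layer_states[-cfg$n_layers], list(Hgated))
  s <- NULL
  for (l in seq_len(cfg$n_layers)) {
    Hsel <- ad_rows(pooled_states[[l]], sel)
    Sl <- ad_concat_cols(ad_spmatmul(ops$Msel, Hsel),
                         ad_group_max(Hsel, ops$ksel, B))
    s <- if (is.null(s)) Sl else ad_add(s, Sl)
  }
  z_a <- ad_linear(s, leaves$W_feat, leaves$b_feat)
  logits <- ad_linear(ad_relu(z_a), leaves$W_cls, leaves$b_cls)
  list(z_a = z_a, logits = logits, selected = sel, scores = zv, readout = s)
}

pb_standardize <- function(model, X) {
  sweep(sweep(as.matrix(X), 2L, model$center), 2L, model$scale, "/")
}

#' Forward pass of the PB branch
#'
#' Deterministic (eval-mode) forward pass for one sample or a matrix of
#' samples, producing the 64-d modality feature `z_a` and the class logits.
#'
#' @param sample_row numeric vector (one sample) or matrix (samples in
#'   rows) of raw indicator values.
#' @param model a [pb_model()].
#' @return list with `z_a`, `logits`, `prob` (softmax matrix), and the
#'   per-sample `selected` node indices and pooling `scores` matrix.
#' @export
pb_forward <- function(sample_row, model) {
  X <- if (is.null(dim(sample_row))) matrix(sample_row, nrow = 1) else
    as.matrix(sample_row)
  Xs <- pb_standardize(model, X)
  tape <- ad_tape(training = FALSE)
  leaves <- ad_params(tape, model$params)
  out <- pb_forward_tape(tape, leaves, model, Xs)
  N <- model$graph$n_nodes
  logits <- out$logits$value
  prob <- exp(logits - apply(logits, 1L, max))
  prob <- prob / rowSums(prob)
  list(z_a = out$z_a$value, logits = logits, prob = prob,
       selected = matrix((out$selected - 1L) %% N + 1L,
                         nrow = nrow(X), byrow = TRUE),
       scores = matrix(out$scores, nrow = nrow(X), byrow = TRUE))
}

#' Train the PB branch alone
#'
#' Minibatch Adam on softmax cross-entropy. The graph topology and the
#' standardization statistics are computed from the supplied (training)
#' table only.
#'
#' @param table a preprocessed [feature_table()] of training samples.
#' @param config a [gnn_config()].
#' @param graph optional pre-built graph; built from `table` when omitted.
#' @param val_table optional validation [feature_table()]; when given, the
#'   parameters with the best validation accuracy (checked every 10
#'   epochs) are kept instead of the last epoch's.
#' @param verbose print the loss every 10 epochs.
#' @return a trained [pb_model()] with a `history` data frame of epoch
#'   losses.
#' @export
train_pb <- function(table, config = gnn_config(), graph = NULL,
                     val_table = NULL, verbose = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(graph)) graph <- build_feature_graph(table)
  X <- table$values
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  model <- pb_model(graph, config, center, scale)
  y <- table$labels + 1L
  Xs <- pb_standardize(model, X)
  n <- nrow(Xs)
  opt <- adam_init(model$params, lr = config$lr,
                   weight_decay = config$weight_decay)
  losses <- numeric(config$epochs)
  best <- list(acc = -Inf, params = NULL)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        tape <- ad_tape(training = TRUE)
        leaves <- ad_params(tape, model$params)
        out <- pb_forward_tape(tape, leaves, model,
                               Xs[idx, , drop = FALSE])
        loss <- ad_softmax_ce(out$logits, y[idx])
        ad_backward(loss)
        model$params <- adam_step(opt, model$params, ad_grads(leaves))
        tot <- tot + loss$value * length(idx)
      }
      losses[ep] <- tot / n
      if (!is.null(val_table) &&
          (ep %% 10L == 0L || ep == config$epochs)) {
        pv <- predict_pb(model, val_table)
        acc <- mean(pv$pred == val_table$labels)
        if (acc >= best$acc) best <- list(acc = acc, params = model$params)
      }
      if (verbose && ep %% 10L == 0L) {
        message(sprintf("pb epoch %d loss %.4f", ep, losses[ep]))
      }
    }
  })
  if (!is.null(best$params)) model$params <- best$params
  model$history <- data.frame(epoch = seq_len(config$epochs), loss = losses)
  model
}

#' Predict stage probabilities with a trained PB model
#'
#' @param model a trained [pb_model()].
#' @param table a [feature_table()] or numeric matrix of indicator values.
#' @return list with `prob` (n x 2 softmax matrix), `pred` (0/1 labels at
#'   threshold 0.5 on the advanced-stage probability) and `z_a`.
#' @export
predict_pb <- function(model, table) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  out <- pb_forward(X, model)
  list(prob = out$prob, pred = as.integer(out$prob[, 2L] > 0.5),
       z_a = out$z_a)
}

#' Aggregate TopK pooling scores over a dataset
#'
#' Mean per-indicator pooling score `z` over the supplied samples and the
#' aggregate selected set (the `ceiling(k * N)` indicators with the largest
#' mean score), the pooling-stage shortlist used for indicator ranking.
#'
#' @param model a trained [pb_model()].
#' @param table a [feature_table()] or matrix.
#' @return data frame with `indicator`, `mean_z` and `selected`, ordered by
#'   decreasing `mean_z`.
#' @export
pooling_scores <- function(model, table) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  out <- pb_forward(X, model)
  mz <- colMeans(out$scores)
  ksel <- ceiling(model$config$pooling_ratio * model$graph$n_nodes)
  ord <- order(-mz, seq_along(mz))
  sel <- seq_along(mz) %in% ord[seq_len(ksel)]
  df <- data.frame(indicator = model$graph$feature_names, mean_z = mz,
                   selected = sel)
  df[order(-df$mean_z), ]
}
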