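# Low-rank multi-modal fusion (LMF), the full tensor-fusion oracle, and the
# cross-modal / self-attention transformer blocks of the fusion head.
#
# LMF computes the contraction of a rank-r CP-decomposed weight tensor with
# the outer product of the modality vectors without materializing either
# tensor: per output coordinate k, h_k = sum_i prod_m <w_{m,k}^(i), z_m>,
# i.e. the rank-wise elementwise products of the modality projections are
# summed over the rank index. (Summing within each modality before the
# product is not the same quantity for r > 1 and does not reproduce the
# full-tensor contraction.)

#' Construct LMF factors
#'
#' @param factors list over modalities; element m is a list of `rank`
#'   matrices, each `d_h x d_m` (row k holds the factor vector
#'   `w_{m,k}^{(i)}`).
#' @return an object of class `lmf_factors` with fields `rank`, `d_h`,
#'   `d_m` and `factors`.
#' @export
lmf_factors <- function(factors) {
  if (!length(factors)) stop("need at least one modality")
  rank <- unique(vapply(factors, length, integer(1)))
  if (length(rank) != 1L || rank < 1L) {
    stop("all modalities must have the same rank >= 1")
  }
  d_h <- unique(unlist(lapply(factors, function(f)
    vapply(f, nrow, integer(1)))))
  if (length(d_h) != 1L) stop("all factors must share the output dim d_h")
  d_m <- vapply(factors, function(f) ncol(f[[1]]), integer(1))
  for (m in seq_along(factors)) {
    if (any(vapply(factors[[m]], ncol, integer(1)) != d_m[m])) {
      stop("modality ", m, ": inconsistent factor widths")
    }
  }
  structure(list(rank = rank, d_h = d_h, d_m = d_m, factors = factors),
            class = "lmf_factors")
}

#' Random LMF factors (for testing and initialization)
#'
#' @param d_m integer vector of modality dims.
#' @param d_h output dim.
#' @param rank CP rank.
#' @return an [lmf_factors()] object with N(0, 1) entries.
#' @export
random_lmf_factors <- function(d_m, d_h, rank) {
  lmf_factors(lapply(d_m, function(dm) {
    lapply(seq_len(rank), function(i) {
      matrix(stats::rnorm(d_h * dm), d_h, dm)
    })
  }))
}

#' Low-rank multi-modal fusion
#'
#' Computes the fused vector `h` from per-modality low-rank factors without
#' materializing the full weight tensor:
#' `h = sum_i prod_m (w_m^{(i)} z_m)` (elementwise product over modalities,
#' summed over the rank index). Identical to contracting the reconstructed
#' weight tensor with the outer product of the modality vectors.
#'
#' @param z_list list of modality vectors (numeric, lengths `d_m`).
#' @param factors an [lmf_factors()] object.
#' @return fused numeric vector of length `d_h`.
#' @export
lmf_fuse <- function(z_list, factors) {
  stopifnot(inherits(factors, "lmf_factors"))
  if (length(z_list) != length(factors$factors)) {
    stop("number of modality vectors must match the factors")
  }
  for (m in seq_along(z_list)) {
    if (length(z_list[[m]]) != factors$d_m[m]) {
      stop("modality ", m, ": vector length ", length(z_list[[m]]),
           " != factor width ", factors$d_m[m])
    }
  }
  h <- numeric(factors$d_h)
  for (i in seq_len(factors$rank)) {
    term <- rep(1, factors$d_h)
    for (m in seq_along(z_list)) {
      term <- term * as.vector(factors$factors[[m]][[i]] %*% z_list[[m]])
    }
    h <- h + term
  }
  h
}

#' Reconstruct the full weight tensor from LMF factors
#'
#' Per output coordinate k, the M-way tensor
#' `W_k = sum_i w_{1,k}^{(i)} o ... o w_{M,k}^{(i)}` (outer products summed
#' over the rank), assembled into an array of dimension
#' `(d_1, ..., d_M, d_h)`.
#'
#' @param factors an [lmf_factors()] object.
#' @return numeric array of dimension `c(d_m, d_h)`.
#' @export
reconstruct_weight_tensor <- function(factors) {
  stopifnot(inherits(factors, "lmf_factors"))
  W <- array(0, c(factors$d_m, factors$d_h))
  Wm <- matrix(W, ncol = factors$d_h)
  for (k in seq_len(factors$d_h)) {
    Wk <- 0
    for (i in seq_len(factors$rank)) {
      Wk <- Wk + Reduce(`%o%`, lapply(seq_along(factors$factors), function(m) {
        factors$factors[[m]][[i]][k, ]
      }))
    }
    Wm[, k] <- as.vector(Wk)
  }
  array(Wm, c(factors$d_m, factors$d_h))
}

#' Full tensor-fusion contraction (verification oracle / TFN baseline)
#'
#' Contracts a dense weight tensor with the outer product of the modality
#' vectors: `h_k = sum over all index tuples of W[..., k] * prod_m z_m`.
#'
#' @param W numeric array of dimension `c(d_1, ..., d_M, d_h)`.
#' @param z_list list of modality vectors matching `d_1, ..., d_M`.
#' @return fused numeric vector of length `d_h`.
#' @export
tensor_fusion_oracle <- function(W, z_list) {
  dims <- dim(W)
  M <- length(z_list)
  stopifnot(length(dims) == M + 1L)
  for (m in seq_len(M)) {
    if (length(z_list[[m]]) != dims[m]) stop("modality ", m, " dim mismatch")
  }
  Z <- Reduce(`%o%`, z_list)
  Wm <- matrix(W, ncol = dims[M + 1L])
  as.vector(crossprod(Wm, as.vector(Z)))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`; each output row is a convex combination
#' of the rows of `V`.
#'
#' @param Q query matrix (`Tq x d_k`).
#' @param K key matrix (`Tk x d_k`).
#' @param V value matrix (`Tk x d_v`).
#' @return `Tq x d_v` matrix; the softmax weight matrix is attached as
#'   `attr(, "weights")`.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (nrow(K) != nrow(V)) stop("K and V must have equal row counts")
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension")
  d_k <- ncol(K)
  if (d_k == 0L) stop("key dimension must be positive")
  S <- Q %*% t(K) / sqrt(d_k)
  S <- S - apply(S, 1L, max)
  A <- exp(S)
  A <- A / rowSums(A)
  structure(A %*% V, weights = A)
}

# plain layer norm over rows with learned gain/shift
layernorm_plain <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  sweep(sweep(xc / sqrt(v + eps), 2L, g, "*"), 2L, b, "+")
}

mha_plain <- function(Q, K, V, heads) {
  d <- ncol(Q)
  dh <- d %/% heads
  out <- matrix(0, nrow(Q), d)
  for (h in seq_len(heads)) {
    cs <- ((h - 1L) * dh + 1L):(h * dh)
    out[, cs] <- scaled_dot_attention(Q[, cs, drop = FALSE],
                                      K[, cs, drop = FALSE],
                                      V[, cs, drop = FALSE])
  }
  out
}

#' Parameters for one transformer block
#'
#' Pre-norm residual block: layer norms for the query and key/value inputs,
#' Q/K/V/output projections, and a two-layer position-wise feed-forward.
#'
#' @param d_model token width.
#' @param d_ff feed-forward hidden width (default `2 * d_model`).
#' @return named list of parameter arrays (Xavier for projections, unit
#'   gain / zero shift for the layer norms).
#' @export
transformer_block_params <- function(d_model, d_ff = 2L * d_model) {
  list(lnq_g = rep(1, d_model), lnq_b = numeric(d_model),
       lnkv_g = rep(1, d_model), lnkv_b = numeric(d_model),
       Wq = xavier_init(c(d_model, d_model)),
       Wk = xavier_init(c(d_model, d_model)),
       Wv = xavier_init(c(d_model, d_model)),
       Wo = xavier_init(c(d_model, d_model)),
       ln2_g = rep(1, d_model), ln2_b = numeric(d_model),
       ff_W1 = xavier_init(c(d_model, d_ff)), ff_b1 = numeric(d_ff),
       ff_W2 = xavier_init(c(d_ff, d_model)), ff_b2 = numeric(d_model))
}

#' Cross-modal transformer block
#'
#' Pre-norm residual block in which the queries come from the target
#' modality and the keys/values from the source modality:
#' `target + MHA(LN(target) Wq, LN(source) Wk, LN(source) Wv) Wo`, followed
#' by a position-wise feed-forward with residual. With `source = target`
#' this is a standard self-attention block. The output always has the
#' target's token count.
#'
#' @param target `Tq x d_model` token matrix (modality m).
#' @param source `Tk x d_model` token matrix (modality n).
#' @param params a [transformer_block_params()] list.
#' @param heads attention head count; must divide `d_model`.
#' @return `Tq x d_model` token matrix.
#' @export
cross_modal_block <- function(target, source, params, heads = 4L) {
  target <- as.matrix(target); source <- as.matrix(source)
  if (ncol(target) != ncol(source)) stop("target/source must share d_model")
  q_in <- layernorm_plain(target, params$lnq_g, params$lnq_b)
  kv_in <- layernorm_plain(source, params$lnkv_g, params$lnkv_b)
  attn <- mha_plain(q_in %*% params$Wq, kv_in %*% params$Wk,
                    kv_in %*% params$Wv, heads)
  x <- target + attn %*% params$Wo
  h_in <- layernorm_plain(x, params$ln2_g, params$ln2_b)
  ff <- pmax(sweep(h_in %*% params$ff_W1, 2L, params$ff_b1, "+"), 0) %*%
    params$ff_W2
  x + sweep(ff, 2L, params$ff_b2, "+")
}

# ---- fusion model --------------------------------------------------------

#' Fusion head configuration
#'
#' The two 64-d modality vectors are fused by LMF into `h` (dim `d_h`);
#' each of `z_a`, `z_v` and `h` is reshaped into `tokens` tokens, linearly
#' embedded to `d_model` with learned positional embeddings; each modality
#' stream passes a cross-modal transformer block (queries from the
#' modality, keys/values from `h`; `swap_qkv` flips this) and one
#' self-attention block; token means are concatenated and classified by a
#' two-layer MLP.
#'
#' @param in_dim modality vector dimension (matches the branch `out_dim`).
#' @param d_h LMF fused-vector dimension.
#' @param rank LMF CP rank.
#' @param tokens tokens per vector; must divide `in_dim` and `d_h`.
#' @param d_model transformer width.
#' @param heads attention heads.
#' @param mlp_hidden classifier hidden width.
#' @param append_one append a constant-1 coordinate to each modality vector
#'   before LMF (off by default: the fusion equation here has no bias
#'   augmentation).
#' @param swap_qkv derive K/V from the modality and Q from `h`.
#' @param lr,epochs,batch_size,weight_decay joint-training hyperparameters.
#' @param branch_lr_scale multiplier on `lr` for the (pretrained) PB and CT
#'   branch parameters during joint fine-tuning; 1 trains everything at the
#'   same rate, smaller values protect the unimodal solutions while the
#'   fusion head trains.
#' @param seed RNG seed.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(in_dim = 64L, d_h = 64L, rank = 4L, tokens = 8L,
                          d_model = 32L, heads = 4L, mlp_hidden = 32L,
                          append_one = FALSE, swap_qkv = FALSE, lr = 1e-3,
                          epochs = 10L, batch_size = 10L, weight_decay = 0,
                          branch_lr_scale = 0.1, seed = 1L) {
  if (in_dim %% tokens != 0L || d_h %% tokens != 0L) {
    stop("tokens must divide in_dim and d_h")
  }
  if (d_model %% heads != 0L) stop("heads must divide d_model")
  if (rank < 1L) stop("rank must be >= 1")
  structure(list(in_dim = as.integer(in_dim), d_h = as.integer(d_h),
                 rank = as.integer(rank), tokens = as.integer(tokens),
                 d_model = as.integer(d_model), heads = as.integer(heads),
                 mlp_hidden = as.integer(mlp_hidden),
                 append_one = append_one, swap_qkv = swap_qkv, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 branch_lr_scale = branch_lr_scale,
                 seed = as.integer(seed)),
            class = "fusion_config")
}

fusion_init_params <- function(config) {
  d_in <- config$in_dim + as.integer(config$append_one)
  params <- list()
  for (m in c("a", "v")) {
    for (i in seq_len(config$rank)) {
      params[[sprintf("lmf_%s_%d", m, i)]] <-
        xavier_init(c(d_in, config$d_h)) / sqrt(config$rank)
    }
  }
  tok_a <- config$in_dim %/% config$tokens
  tok_h <- config$d_h %/% config$tokens
  for (m in c("a", "v")) {
    params[[paste0("tokemb_", m, "_W")]] <- xavier_init(c(tok_a,
                                                          config$d_model))
    params[[paste0("tokemb_", m, "_b")]] <- numeric(config$d_model)
    params[[paste0("pos_", m)]] <- xavier_init(c(config$tokens,
                                                 config$d_model))
  }
  params$tokemb_h_W <- xavier_init(c(tok_h, config$d_model))
  params$tokemb_h_b <- numeric(config$d_model)
  params$pos_h <- xavier_init(c(config$tokens, config$d_model))
  for (blk in c("cm_a", "cm_v", "sa_a", "sa_v")) {
    bp <- transformer_block_params(config$d_model)
    for (nm in names(bp)) params[[paste0(blk, "_", nm)]] <- bp[[nm]]
  }
  params$mlp_W1 <- xavier_init(c(2L * config$d_model, config$mlp_hidden))
  params$mlp_b1 <- numeric(config$mlp_hidden)
  params$mlp_W2 <- xavier_init(c(config$mlp_hidden, 2L))
  params$mlp_b2 <- numeric(2L)
  params
}

#' Create an (untrained) fusion head
#'
#' @param config a [fusion_config()]; parameters Xavier-initialized under
#'   `config$seed`.
#' @return an object of class `fusion_model`.
#' @export
fusion_model <- function(config = fusion_config()) {
  params <- with_seed(config$seed, fusion_init_params(config))
  cache <- new.env(parent = emptyenv())
  structure(list(config = config, params = params, cache = cache),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<fusion_model> rank ", x$config$rank, ", ", x$config$tokens,
      " tokens x d_model ", x$config$d_model, ", ", np, " parameters\n",
      sep = "")
  invisible(x)
}

# Gather index turning a B x d matrix into sample-major tokens
# ((B*tokens) x (d/tokens)); cached per (B, d, tokens).
token_gather_idx <- function(cache, B, d, tokens) {
  key <- sprintf("tok_%d_%d_%d", B, d, tokens)
  if (!is.null(cache[[key]])) return(cache[[key]])
  w <- d %/% tokens
  rows <- B * tokens
  idx <- integer(rows * w)
  pos <- 1L
  for (i in seq_len(w)) {          # output column
    for (b in seq_len(B)) for (t in seq_len(tokens)) {
      j <- (t - 1L) * w + i        # source column in the B x d matrix
      idx[pos] <- (j - 1L) * B + b
      pos <- pos + 1L
    }
  }
  # rows must be ordered (b-1)*tokens + t; fix ordering: we generated rows
  # in b-major, t-minor order which is exactly (b-1)*tokens + t
  cache[[key]] <- idx
  idx
}

ad_tokens <- function(z, cache, tokens, Wemb, bemb, pos, B) {
  d <- ncol(z$value)
  idx <- token_gather_idx(cache, B, d, tokens)
  tok <- ad_gather(z, idx, c(B * tokens, d %/% tokens))
  ad_add_tile(ad_linear(tok, Wemb, bemb), pos, B)
}

ad_transformer_block <- function(tape, x, src, L, prefix, heads, Tq, Tk) {
  g <- function(nm) L[[paste0(prefix, "_", nm)]]
  qn <- ad_layernorm(x, g("lnq_g"), g("lnq_b"))
  kn <- ad_layernorm(src, g("lnkv_g"), g("lnkv_b"))
  att <- ad_mha(ad_matmul(qn, g("Wq")), ad_matmul(kn, g("Wk")),
                ad_matmul(kn, g("Wv")), Tq, Tk, heads)
  x1 <- ad_add(x, ad_matmul(att, g("Wo")))
  hn <- ad_layernorm(x1, g("ln2_g"), g("ln2_b"))
  ff <- ad_matmul(ad_relu(ad_linear(hn, g("ff_W1"), g("ff_b1"))), g("ff_W2"))
  ad_add(x1, ad_add_bias(ff, g("ff_b2")))
}

# Tape forward of the fusion head. z_a, z_v: ad nodes (B x in_dim).
fusion_forward_tape <- function(tape, leaves, model, z_a, z_v, B) {
  cfg <- model$config
  if (cfg$append_one) {
    ones <- ad_leaf(tape, matrix(1, B, 1L))
    z_a <- ad_concat_cols(z_a, ones)
    z_v <- ad_concat_cols(z_v, ones)
  }
  # LMF: rank-wise modality projections, elementwise product, sum over rank
  h <- NULL
  for (i in seq_len(cfg$rank)) {
    term <- ad_mul(ad_matmul(z_a, leaves[[sprintf("lmf_a_%d", i)]]),
                   ad_matmul(z_v, leaves[[sprintf("lmf_v_%d", i)]]))
    h <- if (is.null(h)) term else ad_add(h, term)
  }
  zr_a <- if (cfg$append_one) ad_gather(z_a,
    as.vector(outer(seq_len(B), (seq_len(cfg$in_dim) - 1L) * B, `+`)),
    c(B, cfg$in_dim)) else z_a
  zr_v <- if (cfg$append_one) ad_gather(z_v,
    as.vector(outer(seq_len(B), (seq_len(cfg$in_dim) - 1L) * B, `+`)),
    c(B, cfg$in_dim)) else z_v
  tok_a <- ad_tokens(zr_a, model$cache, cfg$tokens, leaves$tokemb_a_W,
                     leaves$tokemb_a_b, leaves$pos_a, B)
  tok_v <- ad_tokens(zr_v, model$cache, cfg$tokens, leaves$tokemb_v_W,
                     leaves$tokemb_v_b, leaves$pos_v, B)
  tok_h <- ad_tokens(h, model$cache, cfg$tokens, leaves$tokemb_h_W,
                     leaves$tokemb_h_b, leaves$pos_h, B)
  Tn <- cfg$tokens
  if (cfg$swap_qkv) {
    u_a <- ad_transformer_block(tape, tok_h, tok_a, leaves, "cm_a",
                                cfg$heads, Tn, Tn)
    u_v <- ad_transformer_block(tape, tok_h, tok_v, leaves, "cm_v",
                                cfg$heads, Tn, Tn)
  } else {
    u_a <- ad_transformer_block(tape, tok_a, tok_h, leaves, "cm_a",
                                cfg$heads, Tn, Tn)
    u_v <- ad_transformer_block(tape, tok_v, tok_h, leaves, "cm_v",
                                cfg$heads, Tn, Tn)
  }
  u_a <- ad_transformer_block(tape, u_a, u_a, leaves, "sa_a", cfg$heads,
                              Tn, Tn)
  u_v <- ad_transformer_block(tape, u_v, u_v, leaves, "sa_v", cfg$heads,
                              Tn, Tn)
  Mpool <- Matrix::sparseMatrix(i = rep(seq_len(B), each = Tn),
                                j = seq_len(B * Tn), x = 1 / Tn,
                                dims = c(B, B * Tn))
  pooled <- ad_concat_cols(ad_spmatmul(Mpool, u_a), ad_spmatmul(Mpool, u_v))
  hid <- ad_relu(ad_linear(pooled, leaves$mlp_W1, leaves$mlp_b1))
  logits <- ad_linear(hid, leaves$mlp_W2, leaves$mlp_b2)
  list(h = h, final_vector = pooled, logits = logits)
}

#' Forward pass of the fusion head
#'
#' Deterministic (eval-mode) forward: LMF fusion of the two modality
#' vectors, cross-modal and self-attention transformer blocks, token mean
#' pooling, concatenation and the MLP classifier.
#'
#' @param z_a,z_v modality vectors (length `in_dim`) or matrices (samples
#'   in rows).
#' @param model a [fusion_model()].
#' @return list with `h` (LMF fused vectors), `final_vector`
#'   (`n x 2*d_model` concatenated stream summaries), `logits` and `prob`.
#' @export
fuse_forward <- function(z_a, z_v, model) {
  if (is.null(dim(z_a))) z_a <- matrix(z_a, nrow = 1)
  if (is.null(dim(z_v))) z_v <- matrix(z_v, nrow = 1)
  B <- nrow(z_a)
  tape <- ad_tape(training = FALSE)
  leaves <- ad_params(tape, model$params)
  na <- ad_leaf(tape, as.matrix(z_a))
  nv <- ad_leaf(tape, as.matrix(z_v))
  out <- fusion_forward_tape(tape, leaves, model, na, nv, B)
  logits <- out$logits$value
  prob <- exp(logits - apply(logits, 1L, max))
  prob <- prob / rowSums(prob)
  list(h = out$h$value, final_vector = out$final_vector$value,
       logits = logits, prob = prob)
}
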