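# Low-rank fusion, the full-tensor oracle, attention and the transformer
# blocks of the fusion head.

ns <- asNamespace("copdfuse")

test_that("lmf_fuse closed forms hold", {
  # two modalities, rank 1, d_h = 1, all-ones factors: product of sums
  f <- lmf_factors(list(list(matrix(1, 1, 3)), list(matrix(1, 1, 4))))
  za <- c(1, 2, 3); zv <- c(4, 5, 6, 7)
  expect_equal(lmf_fuse(list(za, zv), f), sum(za) * sum(zv))

  # any zero modality vector annihilates the product
  set.seed(1)
  f2 <- random_lmf_factors(c(3, 4), d_h = 2, rank = 2)
  expect_equal(lmf_fuse(list(c(0, 0, 0), rnorm(4)), f2), c(0, 0))

  expect_error(lmf_fuse(list(rnorm(2), rnorm(4)), f2), "length")
})

test_that("the reconstructed weight tensor has the declared CP structure", {
  set.seed(2)
  # rank 1, two modalities: each W_k is an outer product, matrix rank 1
  f1 <- random_lmf_factors(c(3, 4), d_h = 2, rank = 1)
  W1 <- reconstruct_weight_tensor(f1)
  expect_identical(dim(W1), c(3L, 4L, 2L))
  expect_identical(qr(W1[, , 1])$rank, 1L)
  expect_equal(W1[, , 2], outer(f1$factors[[1]][[1]][2, ],
                                f1$factors[[2]][[1]][2, ]))

  # rank 2: matrix rank of each slice at most 2
  f2 <- random_lmf_factors(c(4, 5), d_h = 3, rank = 2)
  W2 <- reconstruct_weight_tensor(f2)
  expect_lte(qr(W2[, , 1])$rank, 2L)

  # all-zero factors reconstruct the zero tensor
  z <- lmf_factors(list(list(matrix(0, 2, 3)), list(matrix(0, 2, 2))))
  expect_true(all(reconstruct_weight_tensor(z) == 0))
})

test_that("the full-tensor contraction unfolds outer products", {
  # identity-like W with d_h = d_a * d_v reproduces vec(z_a o z_v)
  d_a <- 2; d_v <- 3
  W <- array(0, c(d_a, d_v, d_a * d_v))
  for (k in seq_len(d_a * d_v)) W[, , k][k] <- 1
  za <- c(2, -1); zv <- c(1, 3, 5)
  expect_equal(tensor_fusion_oracle(W, list(za, zv)),
               as.vector(outer(za, zv)))
  expect_true(all(tensor_fusion_oracle(0 * W, list(za, zv)) == 0))
})

test_that("scaled dot-product attention satisfies its closed forms", {
  set.seed(3)
  # a single key/value row is returned unchanged for any query
  V1 <- matrix(c(3, -2), 1, 2)
  out <- scaled_dot_attention(matrix(rnorm(6), 3, 2),
                              matrix(rnorm(2), 1, 2), V1)
  expect_equal(out, matrix(rep(V1, each = 3), 3, 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical keys give uniform weights: the column mean of V
  K <- matrix(1, 4, 2); V <- matrix(rnorm(8), 4, 2)
  out2 <- scaled_dot_attention(matrix(rnorm(2), 1, 2), K, V)
  expect_equal(as.vector(out2), colMeans(V), tolerance = 1e-12,
               ignore_attr = TRUE)

  # 2x2 hand example: Q = K = I, weights softmax(c(1, 0)/sqrt(2)) per row
  V3 <- matrix(c(1, 2, 3, 4), 2, 2)
  out3 <- scaled_dot_attention(diag(2), diag(2), V3)
  w <- exp(c(1, 0) / sqrt(2)); w <- w / sum(w)
  expect_equal(out3[1, ], w[1] * V3[1, ] + w[2] * V3[2, ],
               tolerance = 1e-9)
  expect_equal(out3[2, ], w[2] * V3[1, ] + w[1] * V3[2, ],
               tolerance = 1e-9)
  expect_error(scaled_dot_attention(matrix(0, 1, 0), matrix(0, 1, 0),
                                    matrix(1, 1, 1)), "positive")
  expect_error(scaled_dot_attention(diag(2), diag(3), diag(3)), "share")
})

test_that("cross_modal_block reduces to identity with zeroed projections", {
  set.seed(4)
  p <- transformer_block_params(4)
  p$Wo[] <- 0; p$ff_W2[] <- 0; p$ff_b2[] <- 0
  target <- matrix(rnorm(12), 3, 4)
  source <- matrix(rnorm(20), 5, 4)
  expect_equal(cross_modal_block(target, source, p, heads = 2), target)
})

test_that("cross_modal_block with a single source token projects it everywhere", {
  set.seed(5)
  p <- transformer_block_params(4)
  p$ff_W2[] <- 0; p$ff_b2[] <- 0
  target <- matrix(rnorm(8), 2, 4)
  source <- matrix(rnorm(4), 1, 4)
  out <- cross_modal_block(target, source, p, heads = 2)
  # attention over one key is that key's value row for every query
  kv <- copdfuse:::layernorm_plain(source, p$lnkv_g, p$lnkv_b)
  vrow <- as.vector(kv %*% p$Wv)
  expected <- target + matrix(vrow, 2, 4, byrow = TRUE) %*% p$Wo
  expect_equal(out, expected, tolerance = 1e-9)
})

test_that("cross_modal_block matches a layer-by-layer hand composition", {
  set.seed(6)
  p <- transformer_block_params(2, d_ff = 3)
  target <- matrix(rnorm(4), 2, 2)
  source <- matrix(rnorm(4), 2, 2)
  ln <- function(X, g, b) {
    t(apply(X, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) * g + b
    }))
  }
  q <- ln(target, p$lnq_g, p$lnq_b) %*% p$Wq
  k <- ln(source, p$lnkv_g, p$lnkv_b) %*% p$Wk
  v <- ln(source, p$lnkv_g, p$lnkv_b) %*% p$Wv
  S <- q %*% t(k) / sqrt(2)
  A <- exp(S); A <- A / rowSums(A)
  x1 <- target + (A %*% v) %*% p$Wo
  hn <- ln(x1, p$ln2_g, p$ln2_b)
  ff <- pmax(sweep(hn %*% p$ff_W1, 2, p$ff_b1, "+"), 0) %*% p$ff_W2
  expected <- x1 + sweep(ff, 2, p$ff_b2, "+")
  expect_equal(cross_modal_block(target, source, p, heads = 1), expected,
               tolerance = 1e-9)
})

test_that("fuse_forward is deterministic with the declared dimensions", {
  model <- fusion_model(fusion_config(seed = 9))
  set.seed(10)
  za <- matrix(rnorm(3 * 64), 3, 64)
  zv <- matrix(rnorm(3 * 64), 3, 64)
  o1 <- fuse_forward(za, zv, model)
  o2 <- fuse_forward(za, zv, model)
  expect_identical(o1$logits, o2$logits)
  expect_identical(dim(o1$final_vector), c(3L, 64L))  # 2 * d_model
  expect_identical(dim(o1$logits), c(3L, 2L))
  expect_identical(dim(o1$h), c(3L, 64L))
})

test_that("the model's internal LMF agrees with lmf_fuse", {
  cfg <- fusion_config(in_dim = 4L, d_h = 4L, rank = 3L, tokens = 2L,
                       d_model = 4L, heads = 2L, mlp_hidden = 3L, seed = 2)
  model <- fusion_model(cfg)
  set.seed(11)
  za <- rnorm(4); zv <- rnorm(4)
  out <- fuse_forward(za, zv, model)
  f <- lmf_factors(list(
    lapply(1:3, function(i) t(model$params[[sprintf("lmf_a_%d", i)]])),
    lapply(1:3, function(i) t(model$params[[sprintf("lmf_v_%d", i)]]))))
  expect_equal(as.vector(out$h), lmf_fuse(list(za, zv), f),
               tolerance = 1e-9)
})

test_that("fuse_forward matches the composition of its exported pieces", {
  cfg <- fusion_config(in_dim = 4L, d_h = 4L, rank = 2L, tokens = 2L,
                       d_model = 4L, heads = 2L, mlp_hidden = 3L, seed = 7)
  model <- fusion_model(cfg)
  P <- model$params
  set.seed(12)
  za <- rnorm(4); zv <- rnorm(4)
  out <- fuse_forward(za, zv, model)

  f <- lmf_factors(list(
    lapply(1:2, function(i) t(P[[sprintf("lmf_a_%d", i)]])),
    lapply(1:2, function(i) t(P[[sprintf("lmf_v_%d", i)]]))))
  h <- lmf_fuse(list(za, zv), f)
  tokens <- function(z, Wk, bk, pos) {
    t(vapply(1:2, function(tk) {
      as.vector(z[(tk - 1) * 2 + 1:2] %*% Wk) + bk + pos[tk, ]
    }, numeric(4)))
  }
  block <- function(prefix) {
    nm <- names(transformer_block_params(4))
    stats::setNames(lapply(nm, function(x) P[[paste0(prefix, "_", x)]]), nm)
  }
  tok_a <- tokens(za, P$tokemb_a_W, P$tokemb_a_b, P$pos_a)
  tok_v <- tokens(zv, P$tokemb_v_W, P$tokemb_v_b, P$pos_v)
  tok_h <- tokens(h, P$tokemb_h_W, P$tokemb_h_b, P$pos_h)
  u_a <- cross_modal_block(tok_a, tok_h, block("cm_a"), heads = 2)
  u_v <- cross_modal_block(tok_v, tok_h, block("cm_v"), heads = 2)
  u_a <- cross_modal_block(u_a, u_a, block("sa_a"), heads = 2)
  u_v <- cross_modal_block(u_v, u_v, block("sa_v"), heads = 2)
  pooled <- c(colMeans(u_a), colMeans(u_v))
  hid <- pmax(as.vector(pooled %*% P$mlp_W1) + P$mlp_b1, 0)
  logits <- as.vector(hid %*% P$mlp_W2) + P$mlp_b2
  expect_equal(as.vector(out$final_vector), pooled, tolerance = 1e-9)
  expect_equal(as.vector(out$logits), logits, tolerance = 1e-9)
})

test_that("gradient reaches every fusion parameter group", {
  cfg <- fusion_config(in_dim = 8L, d_h = 8L, rank = 2L, tokens = 2L,
                       d_model = 8L, heads = 2L, mlp_hidden = 4L, seed = 3)
  model <- fusion_model(cfg)
  set.seed(13)
  za <- matrix(rnorm(4 * 8), 4, 8)
  zv <- matrix(rnorm(4 * 8), 4, 8)
  tape <- ns$ad_tape(training = TRUE)
  leaves <- ns$ad_params(tape, model$params)
  out <- ns$fusion_forward_tape(tape, leaves, model,
                                ns$ad_leaf(tape, za), ns$ad_leaf(tape, zv),
                                4L)
  loss <- ns$ad_softmax_ce(out$logits, c(1, 2, 1, 2))
  ns$ad_backward(loss)
  grads <- ns$ad_grads(leaves)
  for (nm in names(model$params)) {
    expect_false(is.null(grads[[nm]]), info = nm)
    expect_true(all(is.finite(grads[[nm]])), info = nm)
    expect_gt(max(abs(grads[[nm]])), 0)
  }
})

test_that("three-modality LMF follows the same contraction", {
  set.seed(14)
  f <- random_lmf_factors(c(2, 3, 2), d_h = 2, rank = 2)
  z <- list(rnorm(2), rnorm(3), rnorm(2))
  W <- reconstruct_weight_tensor(f)
  expect_identical(dim(W), c(2L, 3L, 2L, 2L))
  expect_equal(lmf_fuse(z, f), tensor_fusion_oracle(W, z),
               tolerance = 1e-9)
})
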