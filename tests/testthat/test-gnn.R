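# Feature graph construction and the GNN branch operations.

ns <- asNamespace("copdfuse")

graph_from_values <- function(X, threshold = 0.3) {
  build_feature_graph(feature_table(X, rep_len(c(0, 1), nrow(X)),
                                    paste0("f", seq_len(ncol(X)))),
                      threshold = threshold)
}

test_that("edges follow |pearson r| > threshold", {
  set.seed(2)
  x <- rnorm(20)
  # duplicated column (r = 1) and negated column (r = -1) both give edges
  X <- cbind(x, x, -x, rnorm(20))
  g <- graph_from_values(X)
  pairs <- apply(g$edges, 1, paste, collapse = "-")
  expect_true("1-2" %in% pairs)
  expect_true("1-3" %in% pairs)
  r13 <- g$correlation[pairs == "1-3"]
  expect_equal(r13, -1, tolerance = 1e-12)

  # orthogonal-by-construction columns: r computed by the hand formula is 0
  a <- c(1, 1, -1, -1); b <- c(1, -1, 1, -1)
  expect_equal(pearson_oracle(a, b), 0)
  g2 <- graph_from_values(cbind(a, b))
  expect_identical(nrow(g2$edges), 0L)
})

test_that("graph construction validates inputs", {
  expect_error(graph_from_values(matrix(rnorm(8), 4, 2), threshold = 1),
               "threshold")
  expect_error(graph_from_values(matrix(rnorm(4), 2, 2)), "3 training")
  X <- matrix(rnorm(20), 10, 2); X[1, 1] <- NA
  expect_error(graph_from_values(X), "missing")
  # constant columns produce no edges
  g <- graph_from_values(cbind(rep(1, 10), rnorm(10), rnorm(10)))
  expect_false(any(g$edges == 1L))
})

test_that("initial node states are the embedded scalar values", {
  g <- graph_from_values(matrix(rnorm(30), 10, 3))
  # identity-like embedding: hidden_dim 1, weight 1, bias 0
  row <- c(2, -1, 0.5)
  expect_equal(as.vector(init_node_states(g, row, weight = 1)), row)
  # zero row with zero bias gives all-zero states
  expect_true(all(init_node_states(g, c(0, 0, 0), weight = rnorm(4)) == 0))
  # consistent permutation of indicators permutes states
  w <- rnorm(4); B <- matrix(rnorm(12), 3, 4)
  perm <- c(3, 1, 2)
  s1 <- init_node_states(g, row, w, node_embedding = B)
  s2 <- init_node_states(g, row[perm], w, node_embedding = B[perm, ])
  expect_equal(s2, s1[perm, ])
})

test_that("gnn_layer aggregates neighbor means and normalizes rows", {
  # two connected nodes with identical states: aggregate equals own state
  X <- cbind(c(1, 1, -1, -1), c(1, 1, 1, -1))   # r(f1,f2) > 0.3 -> edge
  g <- graph_from_values(X)
  expect_identical(nrow(g$edges), 1L)
  # all-positive weights keep the ReLU row alive, so the normalized row
  # is exactly unit
  W <- matrix(0.5, 4, 2); b <- c(0.1, 0.2)
  h <- rbind(c(0.3, 0.4), c(0.3, 0.4))
  out <- gnn_layer(h, g, list(W = W, b = b))
  expect_equal(out[1, ], out[2, ])
  expect_equal(sum(out[1, ]^2), 1, tolerance = 1e-9)

  # isolated node: aggregation term is the zero vector
  X3 <- cbind(c(1, 1, -1, -1), c(1, 1, 1, -1), c(1, -1, 0, 0))
  g3 <- graph_from_values(X3)
  expect_false(3L %in% as.vector(g3$edges))
  W3 <- diag(1, 6, 3)  # picks out the own-state block
  h3 <- matrix(rnorm(9), 3, 3)
  out3 <- gnn_layer(h3, g3, list(W = W3, b = rep(0, 3)))
  # for the isolated node the pre-activation is relu(own state)
  expected <- pmax(h3[3, ], 0)
  nrm <- sqrt(sum(expected^2))
  expect_equal(out3[3, ], expected / max(nrm, 1e-3), tolerance = 1e-9)
})

test_that("gnn_layer matches an explicit hand computation on a 2-node path", {
  X <- cbind(c(1, 1, -1, -1), c(1, 1, 1, -1))
  g <- graph_from_values(X)
  W <- matrix(c(0.5, -0.2, 0.1, 0.4,
                0.3, 0.7, -0.5, 0.2), nrow = 4)
  b <- c(0.05, -0.05)
  h <- rbind(c(1, 0), c(0, 1))
  # hand arithmetic: agg(1) = h2, agg(2) = h1
  pre1 <- c(sum(c(1, 0, 0, 1) * W[, 1]), sum(c(1, 0, 0, 1) * W[, 2])) + b
  pre2 <- c(sum(c(0, 1, 1, 0) * W[, 1]), sum(c(0, 1, 1, 0) * W[, 2])) + b
  r1 <- pmax(pre1, 0); r2 <- pmax(pre2, 0)
  expected <- rbind(r1 / max(sqrt(sum(r1^2)), 1e-3),
                    r2 / max(sqrt(sum(r2^2)), 1e-3))
  out <- gnn_layer(h, g, list(W = W, b = b))
  expect_equal(out, expected, tolerance = 1e-9)
})

test_that("state rows stay unit-norm (or dead) across random layers", {
  set.seed(8)
  for (rep in 1:20) {
    p <- sample(3:8, 1)
    X <- matrix(rnorm(30 * p), 30, p)
    g <- graph_from_values(X)
    d <- sample(2:6, 1)
    h <- matrix(rnorm(p * d), p, d)
    for (l in 1:3) {
      h <- gnn_layer(h, g, list(W = matrix(rnorm(2 * d * d), 2 * d, d),
                                b = rnorm(d)))
      nrm <- sqrt(rowSums(h^2))
      expect_true(all(abs(nrm - 1) < 1e-9 | nrm < 1))
    }
  }
})

test_that("topk_pool follows the projection score definition", {
  X <- rbind(c(1, 0), c(0, 2), c(3, 3), c(-1, 1))
  p <- c(1, 1) / sqrt(2)
  res <- topk_pool(X, p, ratio = 0.5)
  expect_equal(res$scores, c(1, 2, 6, 0) / sqrt(2), tolerance = 1e-12)
  expect_identical(res$indices, c(2L, 3L))
  expect_equal(res$pooled, X[c(2, 3), ] * plogis(res$scores[c(2, 3)]))

  # p = first basis vector: z is the first column of X
  res2 <- topk_pool(X, c(1, 0), ratio = 0.5)
  expect_equal(res2$scores, X[, 1])

  # scale invariance of the normalized projection
  res5 <- topk_pool(X, 5 * p, ratio = 0.5)
  expect_equal(res5$scores, res$scores)
  expect_identical(res5$indices, res$indices)

  expect_error(topk_pool(X, c(0, 0), 0.5), "nonzero")
})

test_that("readout concatenates mean and max and sums layers", {
  # all states equal c: mean = max = c
  H <- matrix(rep(c(0.2, -1, 3), each = 4), 4, 3)
  r <- readout(list(H))
  expect_equal(r$s, c(c(0.2, -1, 3), c(0.2, -1, 3)))

  # two identical layers double the summary
  r2 <- readout(list(H, H))
  expect_equal(r2$s, 2 * r$s)

  # random states match direct column statistics
  set.seed(4)
  G <- matrix(rnorm(6), 3, 2)
  r3 <- readout(list(G))
  expect_equal(r3$s, c(colMeans(G), apply(G, 2, max)))
  expect_error(readout(list(G[0, , drop = FALSE])), "empty")
})

test_that("pb_forward is deterministic and matches the composed operations", {
  set.seed(12)
  spec <- synthetic_spec(n_samples = 60, modality_signal = "pb_only",
                         seed = 12)
  tab <- generate_pb_table(spec)
  g <- build_feature_graph(tab)
  cfg <- gnn_config(hidden_dim = 4, out_dim = 8, dropout = 0, seed = 3)
  model <- pb_model(g, cfg, colMeans(tab$values),
                    apply(tab$values, 2, sd))
  out1 <- pb_forward(tab$values[1:3, ], model)
  out2 <- pb_forward(tab$values[1:3, ], model)
  expect_identical(out1$z_a, out2$z_a)
  expect_identical(dim(out1$z_a), c(3L, 8L))
  expect_identical(dim(out1$logits), c(3L, 2L))

  # single-sample composition from the exported ops
  x <- (tab$values[1, ] - model$center) / model$scale
  P <- model$params
  h <- init_node_states(g, x, P$W_emb, P$b_emb, node_embedding = P$B_emb)
  layers <- list()
  for (l in 1:4) {
    h <- gnn_layer(h, g, list(W = P[[paste0("W", l)]],
                              b = P[[paste0("b", l)]]))
    layers[[l]] <- h
  }
  pool <- topk_pool(h, P$p_vec, cfg$pooling_ratio)
  states <- c(lapply(layers[1:3], function(H)
    H[pool$indices, , drop = FALSE]), list(pool$pooled))
  s <- readout(states)$s
  z_a <- as.vector(s %*% P$W_feat) + P$b_feat
  logits <- as.vector(pmax(z_a, 0) %*% P$W_cls) + P$b_cls
  expect_equal(as.vector(out1$z_a[1, ]), z_a, tolerance = 1e-9)
  expect_equal(as.vector(out1$logits[1, ]), logits, tolerance = 1e-9)
})

test_that("short PB training decreases the loss and beats chance", {
  spec <- synthetic_spec(n_samples = 120, modality_signal = "pb_only",
                         seed = 19)
  tab <- generate_pb_table(spec)
  model <- train_pb(tab, gnn_config(seed = 1, epochs = 30))
  expect_lt(tail(model$history$loss, 1), model$history$loss[1])
  pred <- predict_pb(model, tab)
  expect_gt(mean(pred$pred == tab$labels), 0.7)   # training accuracy
  ps <- pooling_scores(model, tab)
  expect_identical(sum(ps$selected), 12L)         # ceiling(0.5 * 24)
})
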