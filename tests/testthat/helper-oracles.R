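# Independent oracles used across the suite. These re-derive expected
# values from first principles and never call the code paths they check.

# Direct-summation 3D convolution (channels-last volume, no batching).
naive_conv3d <- function(x, w, b, stride, pad) {
  dx <- dim(x)
  kd <- dim(w)[1]; kh <- dim(w)[2]; kw <- dim(w)[3]
  cin <- dim(w)[4]; cout <- dim(w)[5]
  od <- (dx[1] + 2 * pad[1] - kd) %/% stride[1] + 1
  oh <- (dx[2] + 2 * pad[2] - kh) %/% stride[2] + 1
  ow <- (dx[3] + 2 * pad[3] - kw) %/% stride[3] + 1
  y <- array(0, c(od, oh, ow, cout))
  for (co in seq_len(cout)) for (zo in seq_len(od)) for (yo in seq_len(oh)) {
    for (xo in seq_len(ow)) {
      acc <- b[co]
      for (ci in seq_len(cin)) for (dz in seq_len(kd)) for (dy in seq_len(kh)) {
        for (dxk in seq_len(kw)) {
          zi <- (zo - 1) * stride[1] - pad[1] + dz
          yi <- (yo - 1) * stride[2] - pad[2] + dy
          xi <- (xo - 1) * stride[3] - pad[3] + dxk
          if (zi >= 1 && zi <= dx[1] && yi >= 1 && yi <= dx[2] &&
              xi >= 1 && xi <= dx[3]) {
            acc <- acc + x[zi, yi, xi, ci] * w[dz, dy, dxk, ci, co]
          }
        }
      }
      y[zo, yo, xo, co] <- acc
    }
  }
  y
}

# Hand Pearson correlation from the definition.
pearson_oracle <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Exhaustive pairwise AUC (ties counted one half).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Confusion metrics straight from the definitions.
metrics_oracle <- function(TP, FP, FN, TN) {
  pre <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  sen <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  list(acc = (TP + TN) / (TP + TN + FP + FN),
       pre = pre, sen = sen,
       spe = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       f1 = if (!is.na(pre) && !is.na(sen) && pre + sen > 0) {
         2 * pre * sen / (pre + sen)
       } else NA_real_)
}

# Brute-force TopK pooling: full sort with explicit tie handling.
topk_oracle <- function(X, p, ratio) {
  z <- as.vector(X %*% p) / sqrt(sum(p^2))
  k <- ceiling(ratio * nrow(X))
  ord <- order(-z, seq_along(z))
  sort(ord[seq_len(k)])
}

# Finite-difference gradient check through an arbitrary tape program.
# fn(tape, leaves) must return the scalar loss node.
fd_gradient_check <- function(fn, params, eps = 1e-6, nprobe = 5,
                              training = FALSE) {
  ns <- asNamespace("copdfuse")
  tape <- ns$ad_tape(training = training)
  leaves <- ns$ad_params(tape, params)
  loss <- fn(tape, leaves)
  ns$ad_backward(loss)
  grads <- ns$ad_grads(leaves)
  worst <- 0
  for (nm in names(params)) {
    p <- params[[nm]]
    probe <- unique(round(seq(1, length(p),
                              length.out = min(length(p), nprobe))))
    for (ix in probe) {
      pp <- params; pp[[nm]][ix] <- pp[[nm]][ix] + eps
      t2 <- ns$ad_tape(training = training)
      f2 <- fn(t2, ns$ad_params(t2, pp))$value
      pm <- params; pm[[nm]][ix] <- pm[[nm]][ix] - eps
      t3 <- ns$ad_tape(training = training)
      f3 <- fn(t3, ns$ad_params(t3, pm))$value
      num <- (f2 - f3) / (2 * eps)
      an <- if (is.null(grads[[nm]])) 0 else grads[[nm]][ix]
      worst <- max(worst, abs(num - an) / max(1e-4, abs(num), abs(an)))
    }
  }
  worst
}

tiny_feature_table <- function(n = 30, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  feature_table(X, rep_len(c(0, 1), n), paste0("f", seq_len(p)))
}
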