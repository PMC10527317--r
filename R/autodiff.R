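# Reverse-mode automatic differentiation on a linear tape.
#
# Every differentiable quantity is an `ad_node` environment holding a numeric
# array (`value`), an accumulated gradient (`grad`), and a backward closure
# that pushes the node's gradient into its parents. Nodes are appended to the
# tape in creation order, which is a topological order of the computation
# graph, so backpropagation is a single reverse sweep. A fresh tape is built
# per forward pass; model parameters live outside the tape as plain arrays
# and are attached as leaves each pass.

#' Create an empty autodiff tape
#'
#' @param training logical; when `FALSE`, stochastic layers (dropout) are
#'   identity maps, making the forward pass deterministic.
#' @return an `ad_tape` environment.
#' @keywords internal
#' @export
ad_tape <- function(training = TRUE) {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape$training <- isTRUE(training)
  class(tape) <- "ad_tape"
  tape
}

ad_node <- function(tape, value, backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backward <- backward
  node$tape <- tape
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

#' Attach a value to a tape as a differentiable leaf
#'
#' @param tape an [ad_tape()].
#' @param value numeric vector, matrix or array.
#' @param stop_grad when `TRUE`, ops may skip propagating a gradient into
#'   this leaf (used for network inputs, which are never trained).
#' @keywords internal
#' @export
ad_leaf <- function(tape, value, stop_grad = FALSE) {
  node <- ad_node(tape, value)
  if (stop_grad) node$stop_grad <- TRUE
  node
}

is_ad <- function(x) is.environment(x) && !is.null(x$value) || inherits(x, "ad_node")

ad_accumulate <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run the reverse sweep from a scalar loss node
#'
#' @param loss the `ad_node` to differentiate; seeded with gradient 1.
#' @keywords internal
#' @export
ad_backward <- function(loss) {
  tape <- loss$tape
  g <- loss$value
  g[] <- 0
  loss$grad <- g + 1
  for (i in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node$grad)
  }
  invisible(NULL)
}

# ---- elementary ops -------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(a$tape, av %*% bv, backward = function(g) {
    ad_accumulate(a, tcrossprod(g, bv))
    ad_accumulate(b, crossprod(av, g))
  })
}

# S: constant sparse (or dense) matrix applied on the left.
ad_spmatmul <- function(S, x) {
  xv <- x$value
  ad_node(x$tape, as.matrix(S %*% xv), backward = function(g) {
    ad_accumulate(x, as.matrix(Matrix::crossprod(S, g)))
  })
}

ad_add <- function(a, b) {
  ad_node(a$tape, a$value + b$value, backward = function(g) {
    ad_accumulate(a, g)
    ad_accumulate(b, g)
  })
}

# Add a length-ncol bias vector to every row.
ad_add_bias <- function(x, b) {
  ad_node(x$tape, sweep(x$value, 2L, as.vector(b$value), "+"), backward = function(g) {
    ad_accumulate(x, g)
    ad_accumulate(b, colSums(g))
  })
}

# x is (times*T) x d with rows grouped sample-major; p is T x d added to each tile.
ad_add_tile <- function(x, p, times) {
  pv <- p$value
  Tn <- nrow(pv)
  tile <- pv[rep.int(seq_len(Tn), times), , drop = FALSE]
  ad_node(x$tape, x$value + tile, backward = function(g) {
    ad_accumulate(x, g)
    gp <- pv; gp[] <- 0
    grp <- rep.int(seq_len(Tn), times)
    for (j in seq_len(ncol(gp))) gp[, j] <- rowsum(g[, j], grp)[, 1L]
    ad_accumulate(p, gp)
  })
}

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(a$tape, av * bv, backward = function(g) {
    ad_accumulate(a, g * bv)
    ad_accumulate(b, g * av)
  })
}

# Scale row i of x by v[i] (v an ad_node vector of length nrow(x)).
ad_rowscale <- function(x, v) {
  xv <- x$value; vv <- as.vector(v$value)
  ad_node(x$tape, xv * vv, backward = function(g) {
    ad_accumulate(x, g * vv)
    ad_accumulate(v, rowSums(g * xv))
  })
}

ad_scale <- function(x, s) {
  ad_node(x$tape, x$value * s, backward = function(g) ad_accumulate(x, g * s))
}

ad_relu <- function(x) {
  keep <- x$value > 0
  ad_node(x$tape, x$value * keep, backward = function(g) ad_accumulate(x, g * keep))
}

ad_tanh_op <- function(x) {
  y <- tanh(x$value)
  ad_node(x$tape, y, backward = function(g) ad_accumulate(x, g * (1 - y^2)))
}

ad_sigmoid_op <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  ad_node(x$tape, y, backward = function(g) ad_accumulate(x, g * y * (1 - y)))
}

ad_dropout <- function(x, p) {
  if (!x$tape$training || p <= 0) return(x)
  keep <- (stats::runif(length(x$value)) >= p) / (1 - p)
  dim(keep) <- dim(x$value)
  ad_node(x$tape, x$value * keep, backward = function(g) ad_accumulate(x, g * keep))
}

# Row-wise L2 normalization with a clamped denominator: y = x / max(||x||,
# eps). Rows with norm >= eps land exactly on the unit sphere; smaller
# (ReLU-killed) rows are scaled by 1/eps, which keeps the map continuous
# through zero -- the exact x/||x|| jumps from 0 to the unit sphere there
# and turns dead rows into optimization cliffs.
ad_rownorm <- function(x, eps = 1e-3) {
  xv <- x$value
  nrm <- sqrt(rowSums(xv^2))
  live <- nrm >= eps
  safe <- pmax(nrm, eps)
  y <- xv / safe
  ad_node(x$tape, y, backward = function(g) {
    gx <- g / safe
    dot <- rowSums(g * xv)
    corr <- xv * (dot / safe^3)
    gx[live, ] <- gx[live, , drop = FALSE] - corr[live, , drop = FALSE]
    ad_accumulate(x, gx)
  })
}

ad_rows <- function(x, idx) {
  xv <- x$value
  ad_node(x$tape, xv[idx, , drop = FALSE], backward = function(g) {
    gx <- xv; gx[] <- 0
    acc <- rowsum(g, idx)
    gx[as.integer(rownames(acc)), ] <- acc
    ad_accumulate(x, gx)
  })
}

# Gather arbitrary elements of x into an array of dimension out_dim.
# idx indexes x$value as a flat vector, length prod(out_dim).
ad_gather <- function(x, idx, out_dim) {
  xv <- x$value
  y <- xv[idx]
  dim(y) <- out_dim
  ad_node(x$tape, y, backward = function(g) {
    gx <- as.vector(xv); gx[] <- 0
    gacc <- rowsum(as.vector(g), idx)
    gx[as.integer(rownames(gacc))] <- gacc[, 1L]
    dim(gx) <- dim(xv)
    ad_accumulate(x, gx)
  })
}

ad_concat_cols <- function(a, b) {
  na <- ncol(a$value)
  ad_node(a$tape, cbind(a$value, b$value), backward = function(g) {
    ad_accumulate(a, g[, seq_len(na), drop = FALSE])
    ad_accumulate(b, g[, -seq_len(na), drop = FALSE])
  })
}

ad_vstack <- function(nodes) {
  sizes <- vapply(nodes, function(n) nrow(n$value), integer(1))
  offs <- cumsum(c(0L, sizes))
  ad_node(nodes[[1]]$tape, do.call(rbind, lapply(nodes, function(n) n$value)),
    backward = function(g) {
      for (i in seq_along(nodes)) {
        ad_accumulate(nodes[[i]], g[(offs[i] + 1L):offs[i + 1L], , drop = FALSE])
      }
    })
}

# Column-wise max over contiguous groups of `gsize` rows (ngroups groups).
ad_group_max <- function(x, gsize, ngroups) {
  xv <- x$value
  d <- ncol(xv)
  # columns of `cols` are the gsize values of one (group, feature) pair
  cols <- matrix(xv, nrow = gsize)                  # gsize x (ngroups*d)
  which_idx <- max.col(t(cols), ties.method = "first")
  y <- matrix(cols[cbind(which_idx, seq_along(which_idx))], ngroups, d)
  ad_node(x$tape, y, backward = function(g) {
    gx <- matrix(0, gsize, ngroups * d)
    gx[cbind(which_idx, seq_along(which_idx))] <- as.vector(g)
    dim(gx) <- dim(xv)
    ad_accumulate(x, gx)
  })
}

# Row-wise layer normalization with learned gain/shift vectors.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  y <- sweep(xhat, 2L, gv, "*")
  y <- sweep(y, 2L, bv, "+")
  ad_node(x$tape, y, backward = function(g) {
    ad_accumulate(gamma, colSums(g * xhat))
    ad_accumulate(beta, colSums(g))
    gh <- sweep(g, 2L, gv, "*")
    # d xhat -> d x for row-wise normalization
    gx <- inv * (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat))
    ad_accumulate(x, gx)
  })
}

ad_linear <- function(x, W, b) ad_add_bias(ad_matmul(x, W), b)

# Mean softmax cross-entropy over rows of logits; y integer labels in 1..ncol.
ad_softmax_ce <- function(logits, y) {
  lv <- logits$value
  m <- apply(lv, 1L, max)
  ex <- exp(lv - m)
  p <- ex / rowSums(ex)
  n <- nrow(lv)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y)] + eps))
  ad_node(logits$tape, loss, backward = function(g) {
    gl <- p
    gl[cbind(seq_len(n), y)] <- gl[cbind(seq_len(n), y)] - 1
    ad_accumulate(logits, gl * (as.numeric(g) / n))
  })
}

# Multi-head scaled dot-product attention over contiguous per-sample token
# blocks. q: (B*Tq) x d, k/v: (B*Tk) x d, d divisible by heads.
ad_mha <- function(q, k, v, Tq, Tk, heads) {
  qv <- q$value; kv <- k$value; vv <- v$value
  d <- ncol(qv)
  stopifnot(d %% heads == 0L)
  dh <- d %/% heads
  B <- nrow(qv) %/% Tq
  out <- matrix(0, nrow(qv), d)
  att <- vector("list", B * heads)   # cached softmax weights for backward
  for (b in seq_len(B)) {
    rq <- ((b - 1L) * Tq + 1L):(b * Tq)
    rk <- ((b - 1L) * Tk + 1L):(b * Tk)
    for (h in seq_len(heads)) {
      cs <- ((h - 1L) * dh + 1L):(h * dh)
      S <- (qv[rq, cs, drop = FALSE] %*% t(kv[rk, cs, drop = FALSE])) / sqrt(dh)
      S <- S - apply(S, 1L, max)
      A <- exp(S); A <- A / rowSums(A)
      att[[(b - 1L) * heads + h]] <- A
      out[rq, cs] <- A %*% vv[rk, cs, drop = FALSE]
    }
  }
  ad_node(q$tape, out, backward = function(g) {
    gq <- qv; gq[] <- 0; gk <- kv; gk[] <- 0; gv_ <- vv; gv_[] <- 0
    for (b in seq_len(B)) {
      rq <- ((b - 1L) * Tq + 1L):(b * Tq)
      rk <- ((b - 1L) * Tk + 1L):(b * Tk)
      for (h in seq_len(heads)) {
        cs <- ((h - 1L) * dh + 1L):(h * dh)
        A <- att[[(b - 1L) * heads + h]]
        go <- g[rq, cs, drop = FALSE]
        gv_[rk, cs] <- gv_[rk, cs] + t(A) %*% go
        gA <- go %*% t(vv[rk, cs, drop = FALSE])
        gS <- A * (gA - rowSums(gA * A))
        gS <- gS / sqrt(dh)
        gq[rq, cs] <- gq[rq, cs] + gS %*% kv[rk, cs, drop = FALSE]
        gk[rk, cs] <- gk[rk, cs] + t(gS) %*% qv[rq, cs, drop = FALSE]
      }
    }
    ad_accumulate(q, gq); ad_accumulate(k, gk); ad_accumulate(v, gv_)
  })
}

# Normalized projection z = X p / ||p||, the TopK pooling score.
ad_project <- function(x, p) {
  xv <- x$value
  pv <- as.vector(p$value)
  nrm <- sqrt(sum(pv^2))
  if (nrm == 0) stop("projection vector must be nonzero")
  z <- (xv %*% pv) / nrm
  ad_node(x$tape, z, backward = function(g) {
    g <- as.vector(g)
    ad_accumulate(x, outer(g, pv / nrm))
    gp <- as.vector(t(xv) %*% g) / nrm - pv * (sum(g * z) / nrm^2)
    ad_accumulate(p, gp)
  })
}

# ---- 3D convolution ops (Rcpp im2col/col2im kernels) ----------------------

# x: array (D,H,W,C,N); w: array (kd,kh,kw,Cin,Cout); b: vector length Cout.
# stride/pad: length-3 integer vectors (depth, height, width).
ad_conv3d <- function(x, w, b, stride = c(1L, 1L, 1L), pad = c(1L, 1L, 1L)) {
  xv <- x$value; wv <- w$value; bv <- as.vector(b$value)
  dx <- dim(xv)
  stopifnot(length(dx) == 5L)
  kd <- dim(wv)[1]; kh <- dim(wv)[2]; kw <- dim(wv)[3]
  cin <- dim(wv)[4]; cout <- dim(wv)[5]
  stopifnot(dx[4] == cin)
  N <- dx[5]
  od <- (dx[1] + 2L * pad[1] - kd) %/% stride[1] + 1L
  oh <- (dx[2] + 2L * pad[2] - kh) %/% stride[2] + 1L
  ow <- (dx[3] + 2L * pad[3] - kw) %/% stride[3] + 1L
  Wmat <- matrix(wv, nrow = kd * kh * kw * cin, ncol = cout)
  ks <- as.integer(c(kd, kh, kw))
  stride <- as.integer(stride); pad <- as.integer(pad)
  # patch rows grouped sample-major: one GEMM per conv per minibatch
  colb <- im2col3d_batch(xv, dim(xv), ks, stride, pad)
  yb <- sweep(colb %*% Wmat, 2L, bv, "+")       # (N*osp) x cout
  y <- aperm(array(yb, c(od, oh, ow, N, cout)), c(1, 2, 3, 5, 4))
  ad_node(x$tape, y, backward = function(g) {
    gyb <- matrix(aperm(g, c(1, 2, 3, 5, 4)), nrow = od * oh * ow * N)
    gW <- crossprod(colb, gyb)
    dim(gW) <- dim(wv)
    ad_accumulate(w, gW)
    ad_accumulate(b, colSums(gyb))
    if (is.null(x$stop_grad)) {
      gx <- col2im3d_batch(tcrossprod(gyb, Wmat), dim(xv), ks, stride, pad)
      ad_accumulate(x, gx)
    }
  })
}

# Per-channel batch normalization over a (D,H,W,C,N) tensor. gamma/beta are
# length-C parameter nodes; `state` is an environment holding running mean
# and variance (updated in training mode, used in eval mode).
ad_bn3d <- function(x, gamma, beta, state, momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  dx <- dim(xv)
  C <- dx[4]; N <- dx[5]
  nsp <- dx[1] * dx[2] * dx[3]
  training <- x$tape$training
  # columns of m are (channel, sample) pairs with channel fastest, so no
  # transposition is needed: per-channel statistics aggregate every C-th
  # column
  m <- matrix(xv, nrow = nsp)
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  ch <- rep.int(seq_len(C), N)                # channel id per column
  if (training || is.null(state$mean)) {
    cm <- colMeans(m)
    cm2 <- colMeans(m^2)
    mu <- rowMeans(matrix(cm, C, N))
    v <- rowMeans(matrix(cm2, C, N)) - mu^2
    if (training) {
      if (is.null(state$mean)) {
        state$mean <- mu; state$var <- v
      } else {
        state$mean <- (1 - momentum) * state$mean + momentum * mu
        state$var <- (1 - momentum) * state$var + momentum * v
      }
    }
  } else {
    mu <- state$mean; v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(m, 2L, mu[ch]), 2L, inv[ch], "*")
  ym <- sweep(sweep(xhat, 2L, gv[ch], "*"), 2L, bv[ch], "+")
  dim(ym) <- dx
  n_per_ch <- nsp * N
  ad_node(x$tape, ym, backward = function(g) {
    gm <- matrix(g, nrow = nsp)
    ad_accumulate(gamma, rowSums(matrix(colSums(gm * xhat), C, N)))
    ad_accumulate(beta, rowSums(matrix(colSums(gm), C, N)))
    gh <- sweep(gm, 2L, gv[ch], "*")
    if (training) {
      mean_gh <- rowSums(matrix(colSums(gh), C, N)) / n_per_ch
      mean_ghx <- rowSums(matrix(colSums(gh * xhat), C, N)) / n_per_ch
      gx <- sweep(gh, 2L, mean_gh[ch]) -
        sweep(xhat, 2L, mean_ghx[ch], "*")
      gx <- sweep(gx, 2L, inv[ch], "*")
    } else {
      gx <- sweep(gh, 2L, inv[ch], "*")
    }
    dim(gx) <- dx
    ad_accumulate(x, gx)
  })
}

# Global average pooling over the three spatial dims: (D,H,W,C,N) -> N x C.
ad_gap3d <- function(x) {
  xv <- x$value
  dx <- dim(xv)
  nsp <- dx[1] * dx[2] * dx[3]
  m <- matrix(xv, nrow = nsp)           # nsp x (C*N)
  y <- t(matrix(colMeans(m), nrow = dx[4]))   # N x C
  ad_node(x$tape, y, backward = function(g) {
    gflat <- rep(as.vector(t(g)) / nsp, each = nsp)
    dim(gflat) <- dx
    ad_accumulate(x, gflat)
  })
}

# ---- parameter initialization and optimizer -------------------------------

#' Xavier/Glorot uniform initialization
#'
#' @param dims integer vector of array dimensions.
#' @param fan_in,fan_out receptive-field fan counts; derived from `dims` when
#'   omitted (last dim = fan_out, product of the rest = fan_in).
#' @keywords internal
#' @export
xavier_init <- function(dims, fan_in = NULL, fan_out = NULL) {
  nd <- length(dims)
  if (is.null(fan_out)) fan_out <- dims[nd]
  if (is.null(fan_in)) fan_in <- prod(dims[-nd])
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Create an Adam optimizer state
#'
#' @param params named list of numeric arrays.
#' @param lr learning rate.
#' @param betas length-2 exponential decay rates for the moment estimates.
#' @param eps numerical stabilizer.
#' @param weight_decay decoupled L2 penalty coefficient.
#' @keywords internal
#' @export
adam_init <- function(params, lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8,
                      weight_decay = 0, lr_scale = NULL) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) { p[] <- 0; p })
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr; st$betas <- betas; st$eps <- eps; st$wd <- weight_decay
  st$lr_scale <- lr_scale   # optional named per-parameter multipliers
  st
}

#' One Adam update
#'
#' @param opt state from [adam_init()].
#' @param params named list of arrays.
#' @param grads matching named list of gradients (`NULL` entries are skipped).
#' @return the updated parameter list.
#' @keywords internal
#' @export
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$betas[1]; b2 <- opt$betas[2]
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (opt$wd > 0) g <- g + opt$wd * params[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    lr <- opt$lr
    if (!is.null(opt$lr_scale) && !is.null(opt$lr_scale[[nm]])) {
      lr <- lr * opt$lr_scale[[nm]]
    }
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  params
}

# Attach every parameter array to a tape; returns named list of leaves.
ad_params <- function(tape, params) lapply(params, function(p) ad_leaf(tape, p))

# Collect gradients from a list of leaves (NULL where a parameter was unused).
ad_grads <- function(leaves) lapply(leaves, function(l) l$grad)
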