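# 3D residual CNN branch producing the CT modality vector z_v.
#
# Two backbones share one interface: `resnet50_3d` keeps the standard
# bottleneck layout (stem + stages of 3/4/6/3 bottleneck blocks, expansion
# 4), while `resnet_lite_3d` is a three-stage basic-block network of a few
# hundred thousand parameters for desk-scale work. A fully connected layer
# maps the pooled features to the shared modality dimension (default 64)
# and a final linear head performs classification during (pre)training.

#' CT branch configuration
#'
#' Defaults follow the backbone: `resnet50_3d` uses the full-scale training
#' profile (input 30 x 224 x 224, Adam lr 2e-5, betas (0.9, 0.999),
#' eps 1e-8, weight decay 1e-3, lr x0.1 every 10 epochs, batch size 10);
#' `resnet_lite_3d` defaults to 16 x 32 x 32 inputs and lr 1e-3.
#'
#' @param backbone `"resnet_lite_3d"` or `"resnet50_3d"`.
#' @param input_shape `(depth, height, width)` network input.
#' @param out_dim modality feature dimension, matching the PB branch.
#' @param lr,betas,eps,weight_decay Adam hyperparameters.
#' @param lr_step list `(every, factor)`: multiply lr by `factor` every
#'   `every` epochs; defaults to every 10 epochs for the full backbone and
#'   every 20 for the lite profile.
#' @param batch_size,epochs training loop sizes.
#' @param augment apply random in-plane rotation during training.
#' @param max_rotate_deg augmentation rotation limit in degrees.
#' @param seed RNG seed.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(backbone = c("resnet_lite_3d", "resnet50_3d"),
                       input_shape = NULL, out_dim = 64L, lr = NULL,
                       betas = c(0.9, 0.999), eps = 1e-8,
                       weight_decay = 1e-3,
                       lr_step = NULL,
                       batch_size = 10L, epochs = 15L, augment = TRUE,
                       max_rotate_deg = 15, seed = 1L) {
  backbone <- match.arg(backbone)
  if (is.null(input_shape)) {
    input_shape <- if (backbone == "resnet50_3d") c(30L, 224L, 224L)
      else c(16L, 32L, 32L)
  }
  if (is.null(lr)) lr <- if (backbone == "resnet50_3d") 2e-5 else 1e-3
  if (is.null(lr_step)) {
    lr_step <- if (backbone == "resnet50_3d") {
      list(every = 10L, factor = 0.1)
    } else {
      list(every = 20L, factor = 0.1)
    }
  }
  structure(list(backbone = backbone, input_shape = as.integer(input_shape),
                 out_dim = as.integer(out_dim), lr = lr, betas = betas,
                 eps = eps, weight_decay = weight_decay, lr_step = lr_step,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augment = augment,
                 max_rotate_deg = max_rotate_deg, seed = as.integer(seed)),
            class = "cnn_config")
}

# Architecture description: list of layer specs consumed by the builders.
cnn_arch <- function(backbone) {
  if (backbone == "resnet_lite_3d") {
    list(
      list(type = "conv", name = "stem", k = 3L, stride = c(2L, 2L, 2L),
           pad = 1L, cin = 1L, cout = 4L),
      list(type = "basic", name = "s1", cin = 4L, cout = 4L, stride = 1L),
      list(type = "basic", name = "s2", cin = 4L, cout = 8L, stride = 2L),
      list(type = "basic", name = "s3", cin = 8L, cout = 16L, stride = 2L)
    )
  } else {
    arch <- list(list(type = "conv", name = "stem", k = 7L,
                      stride = c(1L, 2L, 2L), pad = 3L, cin = 1L, cout = 64L))
    stages <- list(c(64L, 3L, 1L), c(128L, 4L, 2L), c(256L, 6L, 2L),
                   c(512L, 3L, 2L))
    cin <- 64L
    for (si in seq_along(stages)) {
      width <- stages[[si]][1]; nblocks <- stages[[si]][2]
      stride <- stages[[si]][3]
      for (b in seq_len(nblocks)) {
        arch[[length(arch) + 1L]] <-
          list(type = "bottleneck", name = sprintf("s%d_b%d", si, b),
               cin = cin, width = width, cout = 4L * width,
               stride = if (b == 1L) stride else 1L)
        cin <- 4L * width
      }
    }
    arch
  }
}

arch_out_channels <- function(arch) {
  last <- arch[[length(arch)]]
  if (last$type == "conv") last$cout else last$cout
}

cnn_init_params <- function(config) {
  arch <- cnn_arch(config$backbone)
  params <- list()
  conv_w <- function(k, cin, cout) {
    xavier_init(c(k, k, k, cin, cout), fan_in = k^3 * cin,
                fan_out = k^3 * cout)
  }
  add_conv <- function(nm, k, cin, cout) {
    params[[paste0(nm, "_W")]] <<- conv_w(k, cin, cout)
    params[[paste0(nm, "_b")]] <<- numeric(cout)
    params[[paste0(nm, "_bng")]] <<- rep(1, cout)   # batch-norm gain
    params[[paste0(nm, "_bnb")]] <<- numeric(cout)  # batch-norm shift
  }
  for (lay in arch) {
    if (lay$type == "conv") {
      add_conv(lay$name, lay$k, lay$cin, lay$cout)
    } else if (lay$type == "basic") {
      add_conv(paste0(lay$name, "_c1"), 3L, lay$cin, lay$cout)
      add_conv(paste0(lay$name, "_c2"), 3L, lay$cout, lay$cout)
      if (lay$cin != lay$cout || lay$stride != 1L) {
        add_conv(paste0(lay$name, "_skip"), 1L, lay$cin, lay$cout)
      }
    } else { # bottleneck
      add_conv(paste0(lay$name, "_c1"), 1L, lay$cin, lay$width)
      add_conv(paste0(lay$name, "_c2"), 3L, lay$width, lay$width)
      add_conv(paste0(lay$name, "_c3"), 1L, lay$width, lay$cout)
      if (lay$cin != lay$cout || lay$stride != 1L) {
        add_conv(paste0(lay$name, "_skip"), 1L, lay$cin, lay$cout)
      }
    }
  }
  cpool <- arch_out_channels(arch)
  params$fc_feat_W <- xavier_init(c(cpool, config$out_dim))
  params$fc_feat_b <- numeric(config$out_dim)
  params$fc_cls_W <- xavier_init(c(config$out_dim, 2L))
  params$fc_cls_b <- numeric(2L)
  params
}

#' Create an (untrained) CT branch model
#'
#' @param config a [cnn_config()]; parameters are Xavier-initialized under
#'   `config$seed`.
#' @return an object of class `ct_model`.
#' @export
ct_model <- function(config = cnn_config()) {
  params <- with_seed(config$seed, cnn_init_params(config))
  structure(list(config = config, arch = cnn_arch(config$backbone),
                 params = params, hu_window = NULL,
                 input_center = 0, input_scale = 1,
                 buffers = new.env(parent = emptyenv()), history = NULL),
            class = "ct_model")
}

#' @export
print.ct_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<ct_model> ", x$config$backbone, ", input ",
      paste(x$config$input_shape, collapse = "x"), ", ", np,
      " parameters\n", sep = "")
  invisible(x)
}

s3 <- function(s) if (length(s) == 1L) rep(as.integer(s), 3L) else as.integer(s)

# Tape forward. x5: array (D, H, W, C=1, N) of normalized voxels.
ct_forward_tape <- function(tape, leaves, model, x5) {
  bn_state <- function(nm) {
    if (is.null(model$buffers[[nm]])) {
      model$buffers[[nm]] <- new.env(parent = emptyenv())
    }
    model$buffers[[nm]]
  }
  conv_bn <- function(h, nm, stride, pad, relu = TRUE) {
    o <- ad_conv3d(h, leaves[[paste0(nm, "_W")]], leaves[[paste0(nm, "_b")]],
                   stride = s3(stride), pad = s3(pad))
    o <- ad_bn3d(o, leaves[[paste0(nm, "_bng")]],
                 leaves[[paste0(nm, "_bnb")]], bn_state(nm))
    if (relu) ad_relu(o) else o
  }
  h <- ad_leaf(tape, x5, stop_grad = TRUE)   # inputs are never trained
  for (lay in model$arch) {
    if (lay$type == "conv") {
      h <- conv_bn(h, lay$name, lay$stride, lay$pad)
    } else if (lay$type == "basic") {
      skip <- h
      o <- conv_bn(h, paste0(lay$name, "_c1"), lay$stride, 1L)
      o <- conv_bn(o, paste0(lay$name, "_c2"), 1L, 1L, relu = FALSE)
      if (!is.null(leaves[[paste0(lay$name, "_skip_W")]])) {
        skip <- conv_bn(skip, paste0(lay$name, "_skip"), lay$stride, 0L,
                        relu = FALSE)
      }
      h <- ad_relu(ad_add(o, skip))
    } else { # bottleneck
      skip <- h
      o <- conv_bn(h, paste0(lay$name, "_c1"), 1L, 0L)
      o <- conv_bn(o, paste0(lay$name, "_c2"), lay$stride, 1L)
      o <- conv_bn(o, paste0(lay$name, "_c3"), 1L, 0L, relu = FALSE)
      if (!is.null(leaves[[paste0(lay$name, "_skip_W")]])) {
        skip <- conv_bn(skip, paste0(lay$name, "_skip"), lay$stride, 0L,
                        relu = FALSE)
      }
      h <- ad_relu(ad_add(o, skip))
    }
  }
  pooled <- ad_gap3d(h)
  z_v <- ad_linear(pooled, leaves$fc_feat_W, leaves$fc_feat_b)
  logits <- ad_linear(ad_relu(z_v), leaves$fc_cls_W, leaves$fc_cls_b)
  list(z_v = z_v, logits = logits)
}

# Stack normalized volumes (or arrays) into the (D,H,W,1,N) input tensor.
stack_volumes <- function(volumes, input_shape) {
  n <- length(volumes)
  x5 <- array(0, c(input_shape, 1L, n))
  for (i in seq_len(n)) {
    vox <- if (is.list(volumes[[i]])) volumes[[i]]$voxels else
      as.array(volumes[[i]])
    if (!all(dim(vox) == input_shape)) {
      stop("volume ", i, " has shape ", paste(dim(vox), collapse = "x"),
           ", expected ", paste(input_shape, collapse = "x"),
           " (crop_resize first)")
    }
    x5[, , , 1L, i] <- vox
  }
  x5
}

#' Forward pass of the CT branch
#'
#' Deterministic (eval-mode) forward pass for a list of normalized volumes,
#' producing the modality feature matrix `z_v` and class logits, one row
#' per volume in input order.
#'
#' @param volumes a single volume or list of `normalized_volume` / arrays
#'   matching `config$input_shape`, voxels in `[0, 1]`.
#' @param model a [ct_model()].
#' @return list with `z_v` (n x out_dim), `logits` (n x 2), `prob`.
#' @export
cnn_forward <- function(volumes, model) {
  if (!is.list(volumes) || !is.null(volumes$voxels)) volumes <- list(volumes)
  x5 <- stack_volumes(volumes, model$config$input_shape)
  x5 <- (x5 - model$input_center) / model$input_scale
  tape <- ad_tape(training = FALSE)
  leaves <- ad_params(tape, model$params)
  out <- ct_forward_tape(tape, leaves, model, x5)
  logits <- out$logits$value
  prob <- exp(logits - apply(logits, 1L, max))
  prob <- prob / rowSums(prob)
  list(z_v = out$z_v$value, logits = logits, prob = prob)
}

# Prepare raw HU volumes for the network: optional mask hook, HU
# normalization with the model window, crop/resize to the input shape.
prepare_volumes <- function(volumes, hu_window, input_shape,
                            crop_fraction = 1, mask_fn = NULL) {
  lapply(volumes, function(v) {
    if (!is.null(mask_fn)) v <- apply_lung_mask(v, mask_fn)
    nv <- hu_normalize(v, hu_window[1], hu_window[2])
    crop_resize(nv, input_shape, crop_fraction)
  })
}

#' Pre-train the CT branch on image data alone
#'
#' Minibatch Adam on softmax cross-entropy over the image-only
#' classification task, with optional random rotation augmentation; the
#' resulting parameters initialize the joint fusion training.
#'
#' @param volumes list of [ct_volume()] (raw HU) or pre-normalized volumes.
#' @param labels binary stage labels.
#' @param config a [cnn_config()].
#' @param hu_window `c(hu_min, hu_max)`; computed from `volumes` when `NULL`
#'   (pass a training-folds window in CV settings).
#' @param val optional `list(volumes =, labels =)` validation set for
#'   best-epoch parameter selection.
#' @param verbose print the loss each epoch.
#' @return a trained [ct_model()] with `hu_window`, the training-set input
#'   standardization and a loss `history`.
#' @export
pretrain_cnn <- function(volumes, labels, config = cnn_config(),
                         hu_window = NULL, val = NULL, verbose = FALSE) {
  if (length(unique(labels)) < 2L) {
    stop("pretraining needs both classes present")
  }
  raw <- inherits(volumes[[1]], "ct_volume")
  if (raw && is.null(hu_window)) hu_window <- hu_range_from_volumes(volumes)
  if (!raw) hu_window <- c(0, 1)
  model <- ct_model(config)
  model$hu_window <- hu_window
  prepped <- if (raw) {
    prepare_volumes(volumes, hu_window, config$input_shape)
  } else {
    lapply(volumes, crop_resize, target_shape = config$input_shape)
  }
  # whiten the network input with training-set statistics: the normalized
  # lung window occupies a narrow sub-interval of [0, 1], and an O(1)
  # input scale keeps the Xavier-initialized gradients healthy
  vx <- unlist(lapply(prepped, function(v) as.vector(v$voxels)))
  model$input_center <- mean(vx)
  model$input_scale <- max(stats::sd(vx), 1e-8)
  if (!is.null(val)) {
    vraw <- inherits(val$volumes[[1]], "ct_volume")
    vv <- if (vraw) prepare_volumes(val$volumes, hu_window,
                                    config$input_shape)
      else lapply(val$volumes, crop_resize,
                  target_shape = config$input_shape)
    val <- list(volumes = vv, labels = val$labels)
  }
  train_ct_epochs(model, prepped, labels, val = val, verbose = verbose)
}

# Shared training loop over prepared (normalized, resized) volumes.
# val: optional list(volumes = prepared volumes, labels) for best-epoch
# parameter selection.
train_ct_epochs <- function(model, prepped, labels, val = NULL,
                            verbose = FALSE) {
  config <- model$config
  y <- as.integer(labels) + 1L
  n <- length(prepped)
  opt <- adam_init(model$params, lr = config$lr, betas = config$betas,
                   eps = config$eps, weight_decay = config$weight_decay)
  losses <- numeric(config$epochs)
  best <- list(acc = -Inf, params = NULL)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      if (ep > 1L && (ep - 1L) %% config$lr_step$every == 0L) {
        opt$lr <- opt$lr * config$lr_step$factor
      }
      perm <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        batch <- prepped[idx]
        if (config$augment) {
          batch <- lapply(batch, augment_rotate,
                          max_deg = config$max_rotate_deg, fill = 0)
        }
        x5 <- stack_volumes(batch, config$input_shape)
        x5 <- (x5 - model$input_center) / model$input_scale
        tape <- ad_tape(training = TRUE)
        leaves <- ad_params(tape, model$params)
        out <- ct_forward_tape(tape, leaves, model, x5)
        loss <- ad_softmax_ce(out$logits, y[idx])
        if (config$lr > 0) {
          ad_backward(loss)
          model$params <- adam_step(opt, model$params, ad_grads(leaves))
        }
        tot <- tot + loss$value * length(idx)
      }
      losses[ep] <- tot / n
      if (!is.null(val) && (ep %% 2L == 0L || ep == config$epochs)) {
        pv <- cnn_forward(val$volumes, model)
        acc <- mean(as.integer(pv$prob[, 2L] > 0.5) == val$labels)
        if (acc >= best$acc) best <- list(acc = acc, params = model$params)
      }
      if (verbose) message(sprintf("ct epoch %d loss %.4f", ep, losses[ep]))
    }
  })
  if (!is.null(best$params)) model$params <- best$params
  model$history <- data.frame(epoch = seq_len(config$epochs), loss = losses)
  model
}

#' Predict stage probabilities with a trained CT model
#'
#' @param model a trained [ct_model()] with an `hu_window`.
#' @param volumes list of [ct_volume()] (raw HU) or normalized volumes.
#' @return list with `prob`, `pred` (threshold 0.5) and `z_v`.
#' @export
predict_ct <- function(model, volumes) {
  raw <- inherits(volumes[[1]], "ct_volume")
  prepped <- if (raw) {
    prepare_volumes(volumes, model$hu_window, model$config$input_shape)
  } else {
    lapply(volumes, crop_resize, target_shape = model$config$input_shape)
  }
  out <- cnn_forward(prepped, model)
  list(prob = out$prob, pred = as.integer(out$prob[, 2L] > 0.5),
       z_v = out$z_v)
}
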