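# CT preprocessing: HU normalization, in-plane rotation augmentation, and
# center-crop + trilinear resize to the network input shape.

#' Normalize Hounsfield units to [0, 1]
#'
#' `I = (H - hu_min) / (hu_max - hu_min)`, clipped to `[0, 1]`. The study
#' convention takes `hu_min`/`hu_max` as the dataset minimum and maximum;
#' compute them on training folds (see [hu_range_from_volumes()]) or pass a
#' fixed window such as `c(-1000, 400)`.
#'
#' @param volume a [ct_volume()] or numeric array of HU values.
#' @param hu_min,hu_max normalization window; `hu_max` must exceed `hu_min`.
#' @return an object of class `normalized_volume`: voxels in `[0, 1]` plus
#'   the window used, kept as provenance.
#' @export
hu_normalize <- function(volume, hu_min, hu_max) {
  if (hu_max <= hu_min) stop("hu_max must be greater than hu_min")
  vox <- if (inherits(volume, "ct_volume")) volume$voxels else as.array(volume)
  out <- (vox - hu_min) / (hu_max - hu_min)
  out[out < 0] <- 0
  out[out > 1] <- 1
  structure(list(voxels = out, hu_min = hu_min, hu_max = hu_max,
                 sample_id = if (inherits(volume, "ct_volume"))
                   volume$sample_id else NA_character_),
            class = "normalized_volume")
}

#' Dataset HU window from a set of volumes
#'
#' @param volumes list of [ct_volume()] objects (training folds only, to
#'   avoid leaking the held-out intensity range).
#' @return `c(hu_min, hu_max)`.
#' @export
hu_range_from_volumes <- function(volumes) {
  rng <- range(vapply(volumes, function(v) range(v$voxels),
                      numeric(2)))
  c(rng[1], rng[2])
}

# In-plane rotation index map for an H x W slice grid: returns source linear
# indices (NA outside the frame) for a rotation by theta degrees.
rotation_map <- function(H, W, theta_deg, interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  th <- theta_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- rep(seq_len(H), times = W) - cy
  gx <- rep(seq_len(W), each = H) - cx
  # inverse mapping: source = R(-theta) target
  sy <- cos(th) * gy + sin(th) * gx + cy
  sx <- -sin(th) * gy + cos(th) * gx + cx
  if (interp == "nearest") {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 1 & ry <= H & rx >= 1 & rx <= W
    idx <- ifelse(ok, (rx - 1) * H + ry, NA_integer_)
    list(mode = "nearest", idx = idx)
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    ok <- function(y, x) y >= 1 & y <= H & x >= 1 & x <= W
    mk <- function(y, x) ifelse(ok(y, x), (x - 1) * H + y, NA_integer_)
    list(mode = "bilinear",
         idx = cbind(mk(y0, x0), mk(y0 + 1, x0), mk(y0, x0 + 1),
                     mk(y0 + 1, x0 + 1)),
         w = cbind((1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx,
                   fy * fx))
  }
}

apply_slice_map <- function(slice, map, fill) {
  v <- as.vector(slice)
  if (map$mode == "nearest") {
    out <- v[map$idx]
    out[is.na(out)] <- fill
  } else {
    out <- numeric(length(v))
    for (c4 in 1:4) {
      val <- v[map$idx[, c4]]
      w <- map$w[, c4]
      val[is.na(val)] <- fill
      out <- out + w * val
    }
  }
  matrix(out, nrow = nrow(slice))
}

#' Random in-plane rotation augmentation
#'
#' Rotates every axial slice of the volume by the same angle, drawn
#' uniformly from `[-max_deg, max_deg]` (training-time augmentation around
#' the Z axis). Out-of-frame voxels are filled with `fill`. The angle is
#' drawn from the current RNG stream, so a fixed seed gives a fixed angle
#' sequence.
#'
#' @param volume a [ct_volume()], `normalized_volume` or 3D array
#'   (depth, height, width).
#' @param max_deg maximum absolute rotation angle in degrees (default 15).
#' @param fill background fill value (0 for normalized volumes,
#'   `hu_min` for raw HU).
#' @param theta optional fixed angle (degrees), overriding the random draw.
#' @param interp `"nearest"` or `"bilinear"` in-plane interpolation.
#' @return object of the same kind as the input with rotated voxels.
#' @export
augment_rotate <- function(volume, max_deg = 15, fill = 0, theta = NULL,
                           interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  vox <- if (is.list(volume)) volume$voxels else as.array(volume)
  if (is.null(theta)) theta <- stats::runif(1, -max_deg, max_deg)
  if (theta == 0) return(volume)
  d <- dim(vox)
  map <- rotation_map(d[2], d[3], theta, interp)
  out <- vox
  for (z in seq_len(d[1])) {
    out[z, , ] <- apply_slice_map(vox[z, , ], map, fill)
  }
  if (is.list(volume)) { volume$voxels <- out; volume } else out
}

# Sparse-free 1D linear interpolation matrix mapping S source samples to T
# targets with half-pixel alignment (the block-average-preserving
# convention for integer downscaling).
resize_matrix <- function(S, Tn) {
  if (S == Tn) return(diag(S))
  M <- matrix(0, Tn, S)
  for (t in seq_len(Tn)) {
    src <- (t - 0.5) * S / Tn + 0.5
    lo <- floor(src); f <- src - lo
    lo <- max(1L, min(S, lo)); hi <- min(S, lo + 1L)
    M[t, lo] <- M[t, lo] + (1 - f)
    M[t, hi] <- M[t, hi] + f
  }
  M
}

#' Center-crop and trilinear resize to a target shape
#'
#' Center-crops the volume to `crop_fraction` of each in-plane dimension,
#' then resamples to `target_shape` by separable (trilinear) linear
#' interpolation; the depth axis is resampled the same way, which
#' standardizes heterogeneous slice counts to the target depth.
#'
#' @param volume a [ct_volume()], `normalized_volume` or 3D array.
#' @param target_shape `(depth, height, width)` of the output.
#' @param crop_fraction fraction of height/width retained before resizing
#'   (1 = no crop).
#' @return object of the same kind as the input with resampled voxels.
#' @export
crop_resize <- function(volume, target_shape = c(30L, 224L, 224L),
                        crop_fraction = 1) {
  vox <- if (is.list(volume)) volume$voxels else as.array(volume)
  if (!length(vox)) stop("empty volume")
  d <- dim(vox)
  if (crop_fraction < 1) {
    ch <- max(1L, round(d[2] * crop_fraction))
    cw <- max(1L, round(d[3] * crop_fraction))
    oy <- (d[2] - ch) %/% 2L
    ox <- (d[3] - cw) %/% 2L
    vox <- vox[, (oy + 1L):(oy + ch), (ox + 1L):(ox + cw), drop = FALSE]
    d <- dim(vox)
  }
  tgt <- as.integer(target_shape)
  if (!all(d == tgt)) {
    Md <- resize_matrix(d[1], tgt[1])
    Mh <- resize_matrix(d[2], tgt[2])
    Mw <- resize_matrix(d[3], tgt[3])
    # contract axis by axis: depth, then height, then width
    x <- matrix(vox, nrow = d[1])                 # D x (H*W)
    x <- Md %*% x                                 # Td x (H*W)
    x <- array(x, c(tgt[1], d[2], d[3]))
    x <- aperm(x, c(2, 1, 3))                     # H x Td x W
    x <- matrix(x, nrow = d[2])
    x <- Mh %*% x
    x <- array(x, c(tgt[2], tgt[1], d[3]))
    x <- aperm(x, c(3, 2, 1))                     # W x Td x Th
    x <- matrix(x, nrow = d[3])
    x <- Mw %*% x
    x <- array(x, c(tgt[3], tgt[1], tgt[2]))
    vox <- aperm(x, c(2, 3, 1))                   # Td x Th x Tw
  }
  if (is.list(volume)) { volume$voxels <- vox; volume } else vox
}

#' Apply an injectable lung mask hook
#'
#' Lung parenchyma segmentation is external to this package; a masking
#' function can be injected anywhere volumes are ingested. The default is
#' the identity.
#'
#' @param volume a [ct_volume()].
#' @param mask_fn function taking and returning a voxel array.
#' @return the masked volume.
#' @export
apply_lung_mask <- function(volume, mask_fn = identity) {
  volume$voxels <- mask_fn(volume$voxels)
  volume
}
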