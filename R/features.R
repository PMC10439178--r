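# Image descriptors: global magnitude-weighted HOG, CIELAB channel
# statistics, the 38-dim detection vector, per-pixel ITA, the masked tone
# feature vector, and a PCA projection for QA plots.

#' Construct and validate an image patch
#'
#' An image patch is an H x W x 3 numeric array of 8-bit sRGB values in
#' \[0, 255\]. Inputs in \[0, 1\] (as returned by PNG/JPEG readers) are
#' rescaled; greyscale matrices are replicated to 3 channels.
#'
#' @param pixels Numeric array (H x W x 3 or H x W).
#' @return Validated H x W x 3 array of values in \[0, 255\].
#' @export
image_patch <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  }
  d <- dim(pixels)
  if (length(d) == 3 && d[3] == 4) {
    pixels <- pixels[, , 1:3, drop = FALSE]  # drop alpha
    d <- dim(pixels)
  }
  if (length(d) != 3 || d[3] != 3) {
    stop("pixels must be an H x W x 3 array")
  }
  if (d[1] < 1 || d[2] < 1) {
    stop("pixels must be non-empty")
  }
  if (anyNA(pixels)) {
    stop("pixels contain NA")
  }
  if (max(pixels) <= 1 && min(pixels) >= 0) {
    pixels <- pixels * 255
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255] (or [0, 1])")
  }
  storage.mode(pixels) <- "double"
  pixels
}

# Scalar intensity channel used for gradients: BT.601 luma. A constant added
# to all three sRGB channels shifts the luma by the same constant, which
# keeps the gradient field (and hence the HOG) photometric-shift invariant.
.intensity <- function(patch) {
  0.299 * patch[, , 1] + 0.587 * patch[, , 2] + 0.114 * patch[, , 3]
}

#' Central-difference image gradients
#'
#' Horizontal and vertical gradients of the scalar intensity channel:
#' Gx(r, c) = I(r, c + 1) - I(r, c - 1) and
#' Gy(r, c) = I(r + 1, c) - I(r - 1, c). Border pixels, where the central
#' difference is undefined, are excluded.
#'
#' @param patch Image patch (see [image_patch()]); at least 3 x 3.
#' @return List with `gx` and `gy`, each (H - 2) x (W - 2).
#' @export
image_gradients <- function(patch) {
  patch <- image_patch(patch)
  h <- dim(patch)[1]; w <- dim(patch)[2]
  if (h < 3 || w < 3) {
    stop("image must be at least 3 x 3 for central differences")
  }
  I <- .intensity(patch)
  ri <- 2:(h - 1)
  ci <- 2:(w - 1)
  list(
    gx = I[ri, ci + 1, drop = FALSE] - I[ri, ci - 1, drop = FALSE],
    gy = I[ri + 1, ci, drop = FALSE] - I[ri - 1, ci, drop = FALSE]
  )
}

#' Global magnitude-weighted histogram of gradient orientations
#'
#' Per interior pixel, the orientation theta = arctan(Gy / Gx) in
#' (-pi/2, pi/2\] and magnitude M = sqrt(Gx^2 + Gy^2) are computed; each
#' pixel adds M to the nearest of `bins` equal-width bin centers spanning
#' (-pi/2, pi/2\] (boundary ties to the lower-index bin). The histogram is
#' L1-normalized when the total magnitude is positive, and all-zero
#' otherwise.
#'
#' @param patch Image patch, at least 3 x 3.
#' @param bins Number of orientation bins (>= 2); default 32.
#' @return Numeric vector of length `bins`, non-negative, summing to 1 (or 0).
#' @export
hog_descriptor <- function(patch, bins = 32) {
  if (!is.numeric(bins) || bins < 2) {
    stop("bins must be an integer >= 2")
  }
  bins <- as.integer(bins)
  g <- image_gradients(patch)
  gx <- as.vector(g$gx)
  gy <- as.vector(g$gy)
  m <- sqrt(gx^2 + gy^2)
  theta <- atan(gy / gx)
  theta[gx == 0 & gy != 0] <- pi / 2
  theta[gx == 0 & gy == 0] <- 0  # M = 0 there; contributes nothing
  # bin centers at -pi/2 + w * (i - 1/2); nearest-center assignment with
  # ties to the lower index reduces to a ceiling on the rescaled angle
  w <- pi / bins
  u <- (theta + pi / 2) / w
  idx <- as.integer(ceiling(u))
  idx[idx < 1L] <- 1L
  idx[idx > bins] <- bins
  h <- numeric(bins)
  acc <- rowsum(m, idx)
  h[as.integer(rownames(acc))] <- acc[, 1]
  tot <- sum(h)
  if (tot > 0) h <- h / tot
  h
}

#' CIELAB channel statistics
#'
#' Mean and population standard deviation of the L*, a*, b* channels over
#' all pixels of the patch.
#'
#' @param patch Image patch.
#' @return Named numeric vector `c(muL, mua, mub, sdL, sda, sdb)`.
#' @export
lab_stats <- function(patch) {
  patch <- image_patch(patch)
  lab <- srgb_to_lab(matrix(patch, ncol = 3))
  mu <- colMeans(lab)
  sd_pop <- sqrt(colMeans(sweep(lab, 2, mu)^2))
  stats::setNames(c(mu, sd_pop), c("muL", "mua", "mub", "sdL", "sda", "sdb"))
}

#' 38-dimensional skin-image detection descriptor
#'
#' Concatenation of the 32-bin global HOG ([hog_descriptor()]) and the six
#' CIELAB channel statistics ([lab_stats()]).
#'
#' @param patch Image patch, at least 3 x 3.
#' @return Named numeric vector of length 38 (`h01`..`h32`, then the CIELAB
#'   statistics).
#' @export
detection_features <- function(patch) {
  h <- hog_descriptor(patch, bins = 32)
  names(h) <- sprintf("h%02d", seq_along(h))
  c(h, lab_stats(patch))
}

#' Per-pixel individual typology angle over a skin mask
#'
#' @param patch Image patch.
#' @param mask Logical H x W matrix aligned to `patch`; must select at least
#'   one pixel.
#' @return Numeric vector of ITA values (degrees) for the masked pixels.
#' @export
ita_map <- function(patch, mask) {
  patch <- image_patch(patch)
  mask <- as_mask(mask, dim(patch)[1:2])
  if (!any(mask)) {
    stop("no skin pixels: mask is empty")
  }
  rgb <- cbind(patch[, , 1][mask], patch[, , 2][mask], patch[, , 3][mask])
  lab <- srgb_to_lab(rgb)
  ita_angle(lab[, 1], lab[, 3])
}

#' Masked skin-tone feature vector
#'
#' Concatenation of (i) the 32-bin HOG computed over the bounding box of the
#' mask with non-mask pixels zeroed, (ii) mean and population standard
#' deviation of the CIELAB L* and b* channels over masked pixels, and (iii)
#' mean and population standard deviation of the per-pixel ITA. With the
#' default `ita_stats` the vector has length 38.
#'
#' @param patch Image patch.
#' @param mask Logical skin mask aligned to `patch`; non-empty.
#' @param ita_stats Either `"mean_sd"` (default, 2 ITA entries) or `"mean"`
#'   (1 entry, giving a 37-dim vector).
#' @return Named numeric feature vector.
#' @export
tone_features <- function(patch, mask, ita_stats = c("mean_sd", "mean")) {
  ita_stats <- match.arg(ita_stats)
  patch <- image_patch(patch)
  mask <- as_mask(mask, dim(patch)[1:2])
  if (!any(mask)) {
    stop("no skin pixels: mask is empty")
  }
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  sub <- patch[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  msub <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  sub <- sub * as.numeric(rep(msub, 3))
  # hog_descriptor needs >= 3 x 3; pad trivially small crops with zeros
  if (nrow(msub) < 3 || ncol(msub) < 3) {
    padded <- array(0, dim = c(max(3, nrow(msub)), max(3, ncol(msub)), 3))
    padded[seq_len(nrow(msub)), seq_len(ncol(msub)), ] <- sub
    sub <- padded
  }
  h <- hog_descriptor(sub, bins = 32)
  names(h) <- sprintf("h%02d", seq_along(h))
  rgb <- cbind(patch[, , 1][mask], patch[, , 2][mask], patch[, , 3][mask])
  lab <- srgb_to_lab(rgb)
  mu <- colMeans(lab)
  sd_pop <- sqrt(colMeans(sweep(lab, 2, mu)^2))
  ita <- ita_angle(lab[, 1], lab[, 3])
  istat <- c(mu_ita = mean(ita))
  if (ita_stats == "mean_sd") {
    istat <- c(istat, sd_ita = sqrt(mean((ita - mean(ita))^2)))
  }
  c(h,
    muL = unname(mu[1]), sdL = unname(sd_pop[1]),
    mub = unname(mu[3]), sdb = unname(sd_pop[3]),
    istat)
}

#' Project feature vectors onto their top principal components
#'
#' Centered PCA projection used for visual QA of the skin / non-skin
#' feature clouds. Component signs are fixed so the largest-magnitude
#' loading of each axis is positive.
#'
#' @param vectors n x p numeric matrix (rows = images), n >= k + 1.
#' @param k Number of components (default 2).
#' @return n x k matrix of scores.
#' @export
pca_project <- function(vectors, k = 2) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < k + 1) {
    stop("need at least k + 1 vectors for a k-component projection")
  }
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- pc$x[, seq_len(k), drop = FALSE] %*% diag(flip, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Coerce and validate a logical skin mask
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param dims Expected `c(H, W)`, or NULL to skip the shape check.
#' @return Logical matrix.
#' @export
as_mask <- function(mask, dims = NULL) {
  if (!is.matrix(mask)) {
    stop("mask must be a matrix")
  }
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) {
      stop("mask must be logical or 0/1")
    }
    mask <- array(mask != 0, dim = dim(mask))
  }
  if (!is.null(dims) && !identical(dim(mask), as.integer(dims))) {
    stop("mask shape does not match image shape")
  }
  mask
}

#' Fraction of mask pixels flagged as skin
#'
#' @param mask Logical matrix.
#' @return `sum(mask) / length(mask)`.
#' @export
skin_fraction <- function(mask) {
  mask <- as_mask(mask)
  mean(mask)
}
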