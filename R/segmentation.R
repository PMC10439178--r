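# Skin-pixel segmentation: HSV/YCbCr color rules refined by morphology,
# connected-component area filtering, CIELAB region growing and watershed
# splitting; plus pixel-fraction evaluation against ground-truth masks.

#' Default HSV / YCbCr skin rule ranges
#'
#' Published skin color loci: hue in \[-20, 50\] degrees (hue is treated
#' circularly, so this is the arc from 340 through 0 to 50 degrees),
#' saturation in \[0.15, 0.70\], value >= 0.25, Cb in \[77, 127\] and Cr in
#' \[133, 173\] (8-bit, BT.601 full range). A pixel is a skin candidate
#' only if it satisfies both the HSV and the YCbCr rule. Every interval is
#' a config key and can be overridden.
#'
#' @param h,s Length-2 numeric ranges for hue (degrees, circular: values
#'   above 180 are folded to negative) and saturation.
#' @param v_min Minimum value (brightness) in \[0, 1\].
#' @param cb,cr Length-2 numeric ranges for Cb and Cr (8-bit).
#' @return Named list of ranges.
#' @export
skin_rule_ranges <- function(h = c(-20, 50), s = c(0.15, 0.70), v_min = 0.25,
                             cb = c(77, 127), cr = c(133, 173)) {
  rng <- list(h = h, s = s, v_min = v_min, cb = cb, cr = cr)
  for (nm in c("h", "s", "cb", "cr")) {
    r <- rng[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop(sprintf("invalid range for '%s': lo must not exceed hi", nm))
    }
  }
  rng
}

#' Default mask-refinement parameters
#'
#' @param r_open,r_close Disk radii (pixels) for morphological opening and
#'   closing. The default opening radius is 1 (despeckle only): color-rule
#'   candidates are speckled wherever pixel noise crosses a rule boundary,
#'   and a larger opening can erase a valid but porous candidate region
#'   before region growing has a chance to consolidate it.
#' @param min_area Minimum connected-component area; either an absolute
#'   pixel count or, when < 1, a fraction of the image pixels (default
#'   0.005 = 0.5\%).
#' @param grow_tol Region-growing admission tolerance as CIELAB Delta-E
#'   (CIE76) from the candidate-region mean color.
#' @param max_grow_iter Cap on region-growing sweeps.
#' @return Named list of parameters.
#' @export
segment_params <- function(r_open = 1, r_close = 3, min_area = 0.005,
                           grow_tol = 12, max_grow_iter = 100) {
  list(r_open = r_open, r_close = r_close, min_area = min_area,
       grow_tol = grow_tol, max_grow_iter = max_grow_iter)
}

#' Rule-based skin candidate mask
#'
#' Flags each pixel as candidate skin iff it satisfies both the HSV rule
#' and the YCbCr rule.
#'
#' @param patch Image patch.
#' @param ranges Rule ranges from [skin_rule_ranges()].
#' @return Logical H x W mask.
#' @export
pixel_rule_mask <- function(patch, ranges = skin_rule_ranges()) {
  ranges <- do.call(skin_rule_ranges, ranges)
  patch <- image_patch(patch)
  d <- dim(patch)
  rgb <- matrix(patch, ncol = 3)
  hsv <- srgb_to_hsv(rgb)
  ycc <- srgb_to_ycbcr(rgb)
  hue <- hsv[, 1]
  hue[hue > 180] <- hue[hue > 180] - 360  # circular hue, signed around red
  ok <- hue >= ranges$h[1] & hue <= ranges$h[2] &
    hsv[, 2] >= ranges$s[1] & hsv[, 2] <= ranges$s[2] &
    hsv[, 3] >= ranges$v_min &
    ycc[, 2] >= ranges$cb[1] & ycc[, 2] <= ranges$cb[2] &
    ycc[, 3] >= ranges$cr[1] & ycc[, 3] <= ranges$cr[2]
  matrix(ok, nrow = d[1], ncol = d[2])
}

.disc <- function(r) {
  EBImage::makeBrush(2 * r + 1, shape = "disc")
}

.drop_small <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  out <- matrix(lab %in% keep & lab > 0, nrow = nrow(mask))
  out
}

.delta_e_map <- function(lab_img, ref) {
  sqrt((lab_img[, , 1] - ref[1])^2 +
         (lab_img[, , 2] - ref[2])^2 +
         (lab_img[, , 3] - ref[3])^2)
}

#' Refine a candidate skin mask
#'
#' (i) morphological opening then closing with disk structuring elements;
#' (ii) removal of connected components below the minimum area;
#' (iii) region growing: neighbors of the surviving components are admitted
#' while their CIELAB Delta-E from the surviving-region mean color is within
#' tolerance; (iv) watershed on the distance map splits merged regions, and
#' fragments below the minimum area are dropped again.
#'
#' @param patch Image patch the mask belongs to.
#' @param candidate Logical candidate mask aligned to `patch`.
#' @param params Parameters from [segment_params()].
#' @return Refined logical mask with no component smaller than `min_area`.
#' @export
refine_mask <- function(patch, candidate, params = segment_params()) {
  params <- do.call(segment_params, params)
  patch <- image_patch(patch)
  mask <- as_mask(candidate, dim(patch)[1:2])
  npix <- length(mask)
  min_px <- if (params$min_area < 1) {
    max(1, round(params$min_area * npix))
  } else {
    params$min_area
  }
  if (!any(mask)) return(mask)

  m <- mask * 1
  if (params$r_open > 0) m <- EBImage::opening(m, .disc(params$r_open))
  if (params$r_close > 0) m <- EBImage::closing(m, .disc(params$r_close))
  mask <- matrix(as.numeric(m) > 0.5, nrow = nrow(mask))
  mask <- .drop_small(mask, min_px)
  if (!any(mask)) return(mask)

  # region growing against the mean color of the surviving region
  lab_img <- srgb_to_lab(patch)
  ref <- c(mean(lab_img[, , 1][mask]),
           mean(lab_img[, , 2][mask]),
           mean(lab_img[, , 3][mask]))
  admissible <- .delta_e_map(lab_img, ref) <= params$grow_tol
  kern <- .disc(1)
  for (i in seq_len(params$max_grow_iter)) {
    dil <- matrix(as.numeric(EBImage::dilate(mask * 1, kern)) > 0.5,
                  nrow = nrow(mask))
    newpix <- dil & !mask & admissible
    if (!any(newpix)) break
    mask <- mask | newpix
  }

  # watershed on the distance map separates touching blobs so undersized
  # fragments can be culled individually
  dm <- EBImage::distmap(mask * 1)
  ws <- EBImage::watershed(dm)
  ws <- matrix(as.integer(ws), nrow = nrow(mask))
  sizes <- tabulate(ws[ws > 0])
  keep <- which(sizes >= min_px)
  mask <- matrix(ws %in% keep & ws > 0, nrow = nrow(mask))
  mask
}

#' Segment skin pixels in an image
#'
#' Applies the HSV/YCbCr color rules ([pixel_rule_mask()]) and refines the
#' candidate mask ([refine_mask()]). Deterministic for a fixed config.
#'
#' @param patch Image patch.
#' @param config Optional list with elements `ranges` and `params`.
#' @return Logical skin mask.
#' @export
segment_skin <- function(patch, config = list()) {
  ranges <- config$ranges %||% skin_rule_ranges()
  params <- config$params %||% segment_params()
  refine_mask(patch, pixel_rule_mask(patch, ranges), params)
}

#' Pixel-fraction segmentation metrics
#'
#' True/false positive/negative rates expressed as fractions of all pixels
#' (skin is the positive class), so the four fractions sum to 1 and
#' accuracy = tp_frac + tn_frac; plus the Jaccard index of the two masks.
#'
#' @param pred Predicted logical mask.
#' @param truth Ground-truth logical mask of the same shape.
#' @return Named list: `tp_frac`, `tn_frac`, `fp_frac`, `fn_frac`,
#'   `jaccard`, `accuracy`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  pred <- as_mask(pred)
  truth <- as_mask(truth, dim(pred))
  n <- length(pred)
  tp <- sum(pred & truth) / n
  tn <- sum(!pred & !truth) / n
  fp <- sum(pred & !truth) / n
  fn <- sum(!pred & truth) / n
  denom <- tp + fp + fn
  list(
    tp_frac = tp, tn_frac = tn, fp_frac = fp, fn_frac = fn,
    jaccard = if (denom > 0) tp / denom else 1,
    accuracy = tp + tn
  )
}

#' Batch segmentation evaluation
#'
#' Evaluates a list of predicted masks against ground truth and returns
#' per-image metrics, their arithmetic mean, and pooled (all pixels
#' concatenated) metrics — the paper-style per-image average and the pooled
#' variant are both reported because the averaging convention is a known
#' ambiguity.
#'
#' @param preds,truths Lists of logical masks (same length and shapes).
#' @param ids Optional image identifiers.
#' @return List with `per_image` (data.frame), `mean` (named list), and
#'   `pooled` (named list).
#' @export
evaluate_segmentation_batch <- function(preds, truths, ids = NULL) {
  if (length(preds) != length(truths)) {
    stop("preds and truths must have the same length")
  }
  ids <- ids %||% sprintf("img%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    m <- evaluate_segmentation(preds[[i]], truths[[i]])
    data.frame(image_id = ids[i], as.data.frame(m))
  })
  per_image <- do.call(rbind, rows)
  mean_row <- as.list(colMeans(per_image[, -1]))
  tp <- sum(vapply(seq_along(preds), function(i) {
    sum(as_mask(preds[[i]]) & as_mask(truths[[i]]))
  }, numeric(1)))
  fp <- sum(vapply(seq_along(preds), function(i) {
    sum(as_mask(preds[[i]]) & !as_mask(truths[[i]]))
  }, numeric(1)))
  fn <- sum(vapply(seq_along(preds), function(i) {
    sum(!as_mask(preds[[i]]) & as_mask(truths[[i]]))
  }, numeric(1)))
  npix <- sum(vapply(preds, length, numeric(1)))
  tn <- npix - tp - fp - fn
  pooled <- list(
    tp_frac = tp / npix, tn_frac = tn / npix,
    fp_frac = fp / npix, fn_frac = fn / npix,
    jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1,
    accuracy = (tp + tn) / npix
  )
  list(per_image = per_image, mean = mean_row, pooled = pooled)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
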