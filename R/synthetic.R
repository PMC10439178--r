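# Synthetic fixtures with known ground truth: skin patches whose CIELAB
# distribution follows the light (FST I-IV) / dark (FST V-VI) split,
# non-skin figures (charts, text blocks, histology-like textures), pixel
# masks, labeled datasets, and multi-image PDF documents with provenance.

#' Specification of a synthetic dataset
#'
#' The color model draws light-class skin from L* ~ U(60, 78), b* ~ U(12, 22)
#' and dark-class skin from L* ~ U(28, 45), b* ~ U(4, 14) (a* ~ U(6, 18)
#' for both), rejection-resampled until the ITA of the color is > 10 degrees
#' (light) or <= -30 degrees (dark), so the two classes are ITA-separable by
#' construction.
#'
#' @param seed Base RNG seed.
#' @param n_images Number of images in a generated dataset.
#' @param tone_mix Proportion of dark (FST V-VI) images among skin images.
#' @param skin_prop Proportion of skin images in the dataset.
#' @param noise_sd Per-pixel CIELAB jitter standard deviation.
#' @param img_size `c(H, W)` of generated images.
#' @param clothing_prob Probability a skin image includes a clothing
#'   rectangle (non-skin foreground).
#' @param lesion_prob Probability a skin image includes a darker lesion blob
#'   inside the skin region (lesion pixels stay part of the true mask).
#' @param axis_frac Range of ellipse semi-axes as a fraction of image dims.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1, n_images = 100, tone_mix = 0.2,
                           skin_prop = 0.5, noise_sd = 4,
                           img_size = c(128, 128), clothing_prob = 0.3,
                           lesion_prob = 0.3, axis_frac = c(0.25, 0.42)) {
  if (tone_mix < 0 || tone_mix > 1) stop("tone_mix must lie in [0, 1]")
  if (skin_prop < 0 || skin_prop > 1) stop("skin_prop must lie in [0, 1]")
  structure(list(
    seed = seed, n_images = n_images, tone_mix = tone_mix,
    skin_prop = skin_prop, noise_sd = noise_sd, img_size = img_size,
    clothing_prob = clothing_prob, lesion_prob = lesion_prob,
    axis_frac = axis_frac,
    color_model = list(
      light = list(L = c(60, 78), a = c(6, 18), b = c(12, 22), ita_min = 10),
      dark = list(L = c(28, 45), a = c(6, 18), b = c(4, 14), ita_max = -30)
    ),
    background = list(
      c(235, 235, 235), c(210, 225, 240), c(120, 150, 200), c(140, 190, 150)
    ),
    clothing = list(c(40, 60, 160), c(150, 60, 160), c(40, 130, 90))
  ), class = "synthetic_spec")
}

#' Sample a skin color for a tone class
#'
#' Draws a CIELAB triple from the class ranges of the spec's color model,
#' rejection-resampled until the ITA constraint of the class holds (> 10
#' degrees for light, <= -30 for dark) and the color is inside the sRGB
#' gamut. Uses the current RNG state.
#'
#' @param tone_class `"light"` or `"dark"`.
#' @param spec A [synthetic_spec()].
#' @return Named CIELAB triple `c(L, a, b)`.
#' @export
sample_skin_color <- function(tone_class = c("light", "dark"),
                              spec = synthetic_spec()) {
  tone_class <- match.arg(tone_class)
  cm <- spec$color_model[[tone_class]]
  repeat {
    lab <- c(
      L = stats::runif(1, cm$L[1], cm$L[2]),
      a = stats::runif(1, cm$a[1], cm$a[2]),
      b = stats::runif(1, cm$b[1], cm$b[2])
    )
    ita <- ita_angle(lab[1], lab[3])
    ok <- if (tone_class == "light") ita > cm$ita_min else ita <= cm$ita_max
    if (!ok) next
    rgb <- lab_to_srgb(matrix(lab, 1))
    back <- srgb_to_lab(rgb)
    if (max(abs(back - lab)) < 0.5) {
      return(lab)
    }
  }
}

.ellipse_mask <- function(h, w, cy, cx, ry, rx, theta = 0) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- yy - cy
  dx <- xx - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Generate a synthetic skin image with ground truth
#'
#' A skin-colored ellipse with per-pixel CIELAB jitter on a non-skin
#' background, optionally with a clothing rectangle (outside the skin
#' region) and a darker lesion blob inside it. The true mask is the ellipse;
#' lesion pixels are included, mirroring segmentation that does not exclude
#' lesions.
#'
#' @param spec A [synthetic_spec()].
#' @param tone_class `"light"` or `"dark"`.
#' @param seed RNG seed for this image.
#' @return List with `pixels` (H x W x 3 in \[0, 255\]), `mask` (logical),
#'   `tone` (the class), and `base_lab` (the sampled skin color).
#' @export
gen_skin_image <- function(spec, tone_class = c("light", "dark"), seed = 1) {
  tone_class <- match.arg(tone_class)
  set.seed(seed)
  h <- spec$img_size[1]; w <- spec$img_size[2]
  base <- sample_skin_color(tone_class, spec)

  bg <- spec$background[[sample.int(length(spec$background), 1)]]
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- bg[ch] + stats::rnorm(h * w, 0, 2)

  # clothing rectangle along one edge, drawn before the skin ellipse so
  # skin is never occluded and the truth mask stays exactly the ellipse
  if (stats::runif(1) < spec$clothing_prob) {
    col <- spec$clothing[[sample.int(length(spec$clothing), 1)]]
    side <- sample.int(4, 1)
    t <- round(stats::runif(1, 0.15, 0.3) * c(h, w, h, w)[side])
    idx <- switch(side,
      list(1:t, 1:w), list(1:h, 1:t),
      list((h - t + 1):h, 1:w), list(1:h, (w - t + 1):w)
    )
    for (ch in 1:3) {
      px[idx[[1]], idx[[2]], ch] <- col[ch] +
        stats::rnorm(length(idx[[1]]) * length(idx[[2]]), 0, 2)
    }
  }

  ry <- stats::runif(1, spec$axis_frac[1], spec$axis_frac[2]) * h
  rx <- stats::runif(1, spec$axis_frac[1], spec$axis_frac[2]) * w
  cy <- h / 2 + stats::runif(1, -0.06, 0.06) * h
  cx <- w / 2 + stats::runif(1, -0.06, 0.06) * w
  theta <- stats::runif(1, 0, pi)
  mask <- .ellipse_mask(h, w, cy, cx, ry, rx, theta)

  nskin <- sum(mask)
  jit <- cbind(
    stats::rnorm(nskin, 0, spec$noise_sd),
    stats::rnorm(nskin, 0, spec$noise_sd / 2),
    stats::rnorm(nskin, 0, spec$noise_sd)
  )
  lab_px <- matrix(base, nskin, 3, byrow = TRUE) + jit

  # lesion: a darker blob fully inside the skin ellipse
  if (stats::runif(1) < spec$lesion_prob && nskin > 50) {
    lry <- ry * stats::runif(1, 0.15, 0.3)
    lrx <- rx * stats::runif(1, 0.15, 0.3)
    lmask <- .ellipse_mask(h, w, cy, cx, lry, lrx, theta) & mask
    sel <- lmask[mask]
    lab_px[sel, 1] <- lab_px[sel, 1] - 12
  }

  rgb_px <- lab_to_srgb(lab_px)
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[mask] <- rgb_px[, ch]
    px[, , ch] <- plane
  }
  px <- round(pmin(pmax(px, 0), 255))
  list(pixels = px, mask = mask, tone = tone_class, base_lab = base)
}

#' Generate a synthetic non-skin figure
#'
#' `chart`: colored polylines and axes on white; `textblock`: rows of dark
#' glyph-like noise on white; `histology`: pink/magenta blob texture.
#'
#' @param kind One of `"chart"`, `"textblock"`, `"histology"`.
#' @param seed RNG seed.
#' @param size `c(H, W)`.
#' @return H x W x 3 pixel array in \[0, 255\].
#' @export
gen_nonskin_image <- function(kind = c("chart", "textblock", "histology"),
                              seed = 1, size = c(128, 128)) {
  kind <- match.arg(kind)
  set.seed(seed)
  h <- size[1]; w <- size[2]
  px <- array(255, dim = c(h, w, 3))
  if (kind == "chart") {
    # axes
    px[h - 10, 10:(w - 5), ] <- 30
    px[5:(h - 10), 10, ] <- 30
    pal <- list(c(31, 119, 180), c(44, 160, 44), c(214, 39, 40),
                c(148, 103, 189))
    for (s in 1:3) {
      col <- pal[[sample.int(length(pal), 1)]]
      y <- round(stats::runif(1, 20, h - 20))
      xs <- 11:(w - 6)
      ys <- round(y + cumsum(stats::rnorm(length(xs), 0, 1.5)))
      ys <- pmin(pmax(ys, 3), h - 12)
      for (k in seq_along(xs)) {
        rr <- max(1, ys[k] - 1):min(h, ys[k] + 1)
        for (ch in 1:3) px[rr, xs[k], ch] <- col[ch]
      }
    }
  } else if (kind == "textblock") {
    nlines <- floor((h - 10) / 8)
    for (ln in seq_len(nlines)) {
      r0 <- 5 + (ln - 1) * 8
      len <- round(stats::runif(1, 0.5, 0.95) * (w - 10))
      on <- stats::runif(len * 4) < 0.45
      vals <- rep(255, len * 4)
      vals[on] <- stats::runif(sum(on), 0, 60)
      block <- matrix(vals, nrow = 4)
      for (ch in 1:3) px[r0:(r0 + 3), 6:(5 + len), ch] <- block
    }
  } else {
    # histology-like: overlapping magenta/pink blobs on a pale pink field
    base <- c(244, 220, 232)
    for (ch in 1:3) px[, , ch] <- base[ch] + stats::rnorm(h * w, 0, 3)
    pal <- list(c(190, 60, 140), c(220, 120, 180), c(150, 40, 110))
    for (bidx in 1:40) {
      col <- pal[[sample.int(length(pal), 1)]]
      m <- .ellipse_mask(h, w, stats::runif(1, 1, h), stats::runif(1, 1, w),
                         stats::runif(1, 3, 10), stats::runif(1, 3, 10),
                         stats::runif(1, 0, pi))
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[m] <- col[ch] + stats::rnorm(sum(m), 0, 4)
        px[, , ch] <- plane
      }
    }
  }
  round(pmin(pmax(px, 0), 255))
}

#' Generate a labeled synthetic dataset
#'
#' Deterministic class counts: `round(n * skin_prop)` skin images of which
#' `round(n_skin * tone_mix)` are dark; the remainder are non-skin figures
#' cycling through the three kinds. Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()] with `n_images >= 2`.
#' @return List with `images` (list of pixel arrays), `is_skin` (logical),
#'   `masks` (list; NULL for non-skin), `tone` (factor `I-IV` / `V-VI`,
#'   NA for non-skin), and `ids`.
#' @export
gen_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  if (spec$n_images < 2) stop("n_images must be >= 2")
  n <- spec$n_images
  n_skin <- round(n * spec$skin_prop)
  n_dark <- round(n_skin * spec$tone_mix)
  tones <- c(rep("dark", n_dark), rep("light", n_skin - n_dark))
  kinds <- rep(c("chart", "textblock", "histology"), length.out = n - n_skin)

  set.seed(spec$seed)
  ord <- sample.int(n)  # interleave skin and non-skin deterministically
  seeds <- sample.int(2^30, n)

  images <- vector("list", n)
  masks <- vector("list", n)
  is_skin <- logical(n)
  tone <- rep(NA_character_, n)
  slots <- ord[seq_len(n_skin)]
  for (i in seq_len(n_skin)) {
    g <- gen_skin_image(spec, tones[i], seed = seeds[slots[i]])
    images[[slots[i]]] <- g$pixels
    masks[[slots[i]]] <- g$mask
    is_skin[slots[i]] <- TRUE
    tone[slots[i]] <- if (tones[i] == "dark") "V-VI" else "I-IV"
  }
  if (n > n_skin) {
    nonslots <- ord[(n_skin + 1):n]
    for (i in seq_along(nonslots)) {
      images[[nonslots[i]]] <- gen_nonskin_image(kinds[i],
                                                 seed = seeds[nonslots[i]],
                                                 size = spec$img_size)
    }
  }
  list(
    images = images,
    is_skin = is_skin,
    masks = masks,
    tone = factor(tone, levels = c("I-IV", "V-VI")),
    ids = sprintf("syn%04d", seq_len(n))
  )
}

#' Generate a synthetic multi-image PDF document with truth manifest
#'
#' Embeds a generated dataset into a PDF (three images per page) and writes
#' a truth manifest recording page, bounding box (top-left origin, PDF
#' points), detection label and tone label per image.
#'
#' @param spec A [synthetic_spec()].
#' @param path Output PDF path.
#' @param extra_sizes Optional list of `c(H, W)` overriding individual image
#'   sizes (e.g. to plant an undersized image); recycled entries of NULL
#'   keep `spec$img_size`.
#' @return Invisibly, a list with `pdf` (path), `truth` (data.frame with
#'   page, bbox, is_skin, tone, md5) and `dataset` (the generated data).
#' @export
gen_document <- function(spec, path, extra_sizes = NULL) {
  ds <- gen_dataset(spec)
  n <- length(ds$images)
  if (!is.null(extra_sizes)) {
    for (i in seq_len(min(n, length(extra_sizes)))) {
      if (!is.null(extra_sizes[[i]])) {
        sz <- extra_sizes[[i]]
        img <- ds$images[[i]]
        ds$images[[i]] <- img[seq_len(min(sz[1], nrow(img))),
                              seq_len(min(sz[2], ncol(img))), , drop = FALSE]
        if (!is.null(ds$masks[[i]])) {
          ds$masks[[i]] <- ds$masks[[i]][seq_len(dim(ds$images[[i]])[1]),
                                         seq_len(dim(ds$images[[i]])[2]),
                                         drop = FALSE]
        }
      }
    }
  }
  per_page <- 3
  page_w <- 612; page_h <- 792
  placements <- lapply(seq_len(n), function(i) {
    page <- (i - 1) %/% per_page + 1
    slot <- (i - 1) %% per_page
    d <- dim(ds$images[[i]])
    x0 <- 60
    y0 <- 40 + slot * 250
    list(page = page, bbox = c(x0, y0, x0 + d[2], y0 + d[1]))
  })
  pdf_write_images(ds$images, placements, path)
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- placements[[i]]
    data.frame(
      id = ds$ids[i], page = p$page,
      x0 = p$bbox[1], y0 = p$bbox[2], x1 = p$bbox[3], y1 = p$bbox[4],
      is_skin = ds$is_skin[i], tone = as.character(ds$tone[i]),
      md5 = pixels_md5(ds$images[[i]]),
      stringsAsFactors = FALSE
    )
  }))
  manifest_path <- paste0(tools::file_path_sans_ext(path), "_truth.json")
  jsonlite::write_json(truth, manifest_path, dataframe = "rows", na = "null",
                       digits = NA, pretty = TRUE)
  invisible(list(pdf = path, truth = truth, truth_path = manifest_path,
                 dataset = ds))
}

#' MD5 checksum of a pixel array
#'
#' Content fingerprint used to align extracted images with truth manifests.
#'
#' @param pixels H x W x 3 array in \[0, 255\].
#' @return Character MD5 hex digest of the rounded pixel bytes.
#' @export
pixels_md5 <- function(pixels) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  writeBin(as.raw(round(as.vector(pixels))), tmp)
  unname(tools::md5sum(tmp))
}
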