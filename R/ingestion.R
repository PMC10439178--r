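# Document ingestion: extract embedded figures from a PDF (or a directory
# of page images) into image records with page/coordinate provenance, and
# serialize record sets to a JSON manifest with sibling PNG files.

#' Construct an image record
#'
#' An extracted figure with document provenance: 1-based page number,
#' bounding box `c(x0, y0, x1, y1)` in page points with top-left origin,
#' and 8-bit sRGB pixels.
#'
#' @param doc_id Document identifier.
#' @param page Positive integer page number.
#' @param bbox Numeric length-4 bounding box with x0 < x1 and y0 < y1.
#' @param pixels H x W x 3 pixel array (see [image_patch()]).
#' @param source_path Path the record was extracted from.
#' @return An object of class `image_record`.
#' @export
image_record <- function(doc_id, page, bbox, pixels, source_path = "") {
  if (!is.numeric(page) || page < 1) stop("page must be a positive integer")
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[1] >= bbox[3] || bbox[2] >= bbox[4]) {
    stop("bbox must satisfy x0 < x1 and y0 < y1")
  }
  pixels <- image_patch(pixels)
  structure(
    list(doc_id = doc_id, page = as.integer(page), bbox = bbox,
         pixels = pixels, source_path = source_path),
    class = "image_record"
  )
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_record> %s p.%d [%.1f, %.1f, %.1f, %.1f] %dx%d px\n",
              x$doc_id, x$page, x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4],
              d[1], d[2]))
  invisible(x)
}

.read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported raster format: '%s'", path))
  )
  image_patch(img)
}

#' Extract embedded figures from a document
#'
#' For a PDF, every embedded raster image is returned with its page number
#' and placement rectangle (top-left origin, page points); vector graphics
#' are ignored. For a directory of PNG/JPEG files, each file becomes one
#' record with `page` equal to its (name-sorted) index. Images smaller than
#' `min_dim` in either dimension are dropped. Records are ordered by page,
#' then reading order (top-to-bottom, left-to-right).
#'
#' @param document Path to a PDF file or a directory of raster images.
#' @param min_dim Minimum allowed image dimension in pixels (default 100).
#' @return List of [image_record()] objects.
#' @export
extract_images <- function(document, min_dim = 100) {
  doc_id <- basename(tools::file_path_sans_ext(document))
  if (dir.exists(document)) {
    files <- list.files(document, pattern = "\\.(png|jpe?g)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
    records <- lapply(seq_along(files), function(i) {
      px <- .read_raster(files[i])
      d <- dim(px)
      image_record(doc_id, i, c(0, 0, d[2], d[1]), px, files[i])
    })
  } else {
    if (!file.exists(document)) {
      stop(sprintf("ingestion error: cannot read '%s'", document))
    }
    raw_recs <- pdf_extract_rasters(document)
    records <- lapply(raw_recs, function(r) {
      image_record(doc_id, r$page, r$bbox, r$pixels, document)
    })
  }
  keep <- vapply(records, function(r) {
    min(dim(r$pixels)[1:2]) >= min_dim
  }, logical(1))
  records <- records[keep]
  if (length(records) > 1) {
    ord <- order(
      vapply(records, `[[`, integer(1), "page"),
      vapply(records, function(r) r$bbox[2], numeric(1)),
      vapply(records, function(r) r$bbox[1], numeric(1))
    )
    records <- records[ord]
  }
  records
}

#' Write an image-record manifest
#'
#' Writes `manifest.json` plus one PNG per record under `dir/images/`. The
#' manifest schema is `{doc_id, entries: [{page, bbox, image_path, md5}]}`
#' with image paths relative to the manifest.
#'
#' @param records List of [image_record()] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(records, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    rel <- file.path("images", sprintf("img_%04d.png", i))
    png::writePNG(r$pixels / 255, file.path(dir, rel))
    list(page = r$page, bbox = r$bbox, image_path = rel,
         md5 = pixels_md5(r$pixels))
  })
  doc_id <- if (length(records)) records[[1]]$doc_id else ""
  manifest <- list(doc_id = doc_id, entries = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an image-record manifest
#'
#' Inverse of [write_manifest()]: reproduces doc_id, page and bbox exactly
#' and pixels bit-identically.
#'
#' @param path Path to `manifest.json`.
#' @return List of [image_record()] objects.
#' @export
read_manifest <- function(path) {
  manifest <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) {
      stop(sprintf("manifest parse error in '%s': %s", path,
                   conditionMessage(e)))
    }
  )
  if (is.null(manifest$entries) || is.null(manifest$doc_id)) {
    stop(sprintf("manifest parse error in '%s': missing doc_id or entries",
                 path))
  }
  base <- dirname(path)
  lapply(manifest$entries, function(e) {
    img_path <- file.path(base, e$image_path)
    if (!file.exists(img_path)) {
      stop(sprintf("manifest references missing image file: '%s'", img_path))
    }
    px <- round(png::readPNG(img_path) * 255)
    image_record(manifest$doc_id, e$page, unlist(e$bbox), px, img_path)
  })
}
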