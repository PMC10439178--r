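# Minimal self-contained PDF image codec. The writer emits standards-valid
# PDFs whose figures are Flate-encoded DeviceRGB image XObjects; the reader
# recovers embedded raster XObjects together with their page number and
# placement rectangle. Scope: 8-bit DeviceRGB/DeviceGray images with no
# filter, FlateDecode (zlib) or DCTDecode (JPEG); vector graphics are
# ignored by construction. R's memCompress(type = "gzip") produces zlib
# streams, which is exactly the FlateDecode payload format.

.pdf_obj <- function(id, body) {
  c(charToRaw(sprintf("%d 0 obj\n", id)), body, charToRaw("\nendobj\n"))
}

#' Write images into a PDF document
#'
#' @param images List of H x W x 3 pixel arrays in \[0, 255\].
#' @param placements List (same length) of `list(page, bbox)` where `bbox`
#'   is `c(x0, y0, x1, y1)` in page points with a top-left origin.
#' @param path Output file path.
#' @param page_size `c(width, height)` of every page in points.
#' @return Invisibly, `path`.
#' @export
pdf_write_images <- function(images, placements, path,
                             page_size = c(612, 792)) {
  stopifnot(length(images) == length(placements))
  n <- length(images)
  pages <- vapply(placements, function(p) as.integer(p$page), integer(1))
  n_pages <- if (n == 0) 1L else max(pages)
  pw <- page_size[1]; ph <- page_size[2]

  # object ids: 1 catalog, 2 pages, 2+i page i, 2+P+i content i, 2+2P+k image k
  page_id <- function(i) 2L + i
  content_id <- function(i) 2L + n_pages + i
  image_id <- function(k) 2L + 2L * n_pages + k

  chunks <- list(charToRaw("%PDF-1.4\n%\xe2\xe3\xcf\xd3\n"))
  offsets <- integer(2 + 2 * n_pages + n)
  pos <- length(chunks[[1]])
  add_obj <- function(id, body) {
    obj <- .pdf_obj(id, body)
    offsets[id] <<- pos
    chunks[[length(chunks) + 1]] <<- obj
    pos <<- pos + length(obj)
  }

  kids <- paste(sprintf("%d 0 R", page_id(seq_len(n_pages))), collapse = " ")
  add_obj(1L, charToRaw("<< /Type /Catalog /Pages 2 0 R >>"))
  add_obj(2L, charToRaw(sprintf(
    "<< /Type /Pages /Kids [%s] /Count %d >>", kids, n_pages)))

  for (p in seq_len(n_pages)) {
    on_page <- which(pages == p)
    xoents <- paste(sprintf("/Im%d %d 0 R", on_page, image_id(on_page)),
                    collapse = " ")
    add_obj(page_id(p), charToRaw(sprintf(
      paste0("<< /Type /Page /Parent 2 0 R /MediaBox [0 0 %g %g] ",
             "/Resources << /XObject << %s >> >> /Contents %d 0 R >>"),
      pw, ph, xoents, content_id(p))))
  }
  for (p in seq_len(n_pages)) {
    on_page <- which(pages == p)
    ops <- vapply(on_page, function(k) {
      b <- placements[[k]]$bbox
      wd <- b[3] - b[1]; ht <- b[4] - b[2]
      # convert top-left origin to PDF's bottom-left origin
      sprintf("q %g 0 0 %g %g %g cm /Im%d Do Q", wd, ht, b[1], ph - b[4], k)
    }, character(1))
    stream <- charToRaw(paste(ops, collapse = "\n"))
    add_obj(content_id(p), c(
      charToRaw(sprintf("<< /Length %d >>\nstream\n", length(stream))),
      stream, charToRaw("\nendstream")))
  }
  for (k in seq_len(n)) {
    px <- round(images[[k]])
    d <- dim(px)
    bytes <- as.raw(as.vector(aperm(px, c(3, 2, 1))))  # row-major RGB
    comp <- memCompress(bytes, "gzip")
    add_obj(image_id(k), c(
      charToRaw(sprintf(
        paste0("<< /Type /XObject /Subtype /Image /Width %d /Height %d ",
               "/ColorSpace /DeviceRGB /BitsPerComponent 8 ",
               "/Filter /FlateDecode /Length %d >>\nstream\n"),
        d[2], d[1], length(comp))),
      comp, charToRaw("\nendstream")))
  }

  n_obj <- length(offsets)
  xref_pos <- pos
  xref <- paste0(
    sprintf("xref\n0 %d\n", n_obj + 1),
    "0000000000 65535 f \n",
    paste(sprintf("%010d 00000 n \n", offsets), collapse = ""))
  trailer <- sprintf(
    "trailer\n<< /Size %d /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF\n",
    n_obj + 1, xref_pos)
  chunks[[length(chunks) + 1]] <- charToRaw(paste0(xref, trailer))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(do.call(c, chunks), con)
  invisible(path)
}

# ---- reader ----------------------------------------------------------------

.pdf_searchable <- function(bytes) {
  b <- bytes
  b[b == as.raw(0)] <- as.raw(32)
  txt <- rawToChar(b)
  Encoding(txt) <- "latin1"
  txt
}

.re1 <- function(pattern, x) {
  m <- regmatches(x, regexec(pattern, x, perl = TRUE, useBytes = TRUE))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

.pdf_parse_objects <- function(bytes, txt, path) {
  locs <- gregexpr("(\\d+)\\s+\\d+\\s+obj\\b", txt, perl = TRUE,
                   useBytes = TRUE)[[1]]
  if (locs[1] == -1) {
    stop(sprintf("ingestion error: no PDF objects found in '%s'", path))
  }
  starts <- as.integer(locs)
  lens <- attr(locs, "match.length")
  objs <- list()
  for (i in seq_along(starts)) {
    header <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    id <- as.integer(sub("^(\\d+).*", "\\1", header))
    body_start <- starts[i] + lens[i]
    endo <- regexpr("endobj", substr(txt, body_start, nchar(txt)),
                    useBytes = TRUE)
    body_end <- if (endo == -1) nchar(txt) else body_start + endo - 2
    body <- substr(txt, body_start, body_end)
    dict <- body
    stream_data <- NULL
    sm <- regexpr("stream(\r\n|\n|\r)", body, perl = TRUE, useBytes = TRUE)
    if (sm != -1) {
      dict <- substr(body, 1, sm - 1)
      len_s <- .re1("/Length\\s+(\\d+)", dict)
      data_start <- body_start + sm - 1 + attr(sm, "match.length")
      if (!is.na(len_s)) {
        len <- as.integer(len_s)
      } else {
        # fall back to scanning for endstream
        es <- regexpr("endstream", substr(txt, data_start, nchar(txt)),
                      useBytes = TRUE)
        len <- if (es == -1) 0L else es - 2L
      }
      stream_data <- bytes[seq.int(data_start, length.out = len)]
    }
    objs[[as.character(id)]] <- list(dict = dict, stream = stream_data)
  }
  objs
}

.pdf_decode_stream <- function(obj) {
  data <- obj$stream
  if (grepl("/FlateDecode", obj$dict, useBytes = TRUE)) {
    data <- memDecompress(data, "gzip")
  }
  data
}

.pdf_decode_image <- function(obj) {
  w <- as.integer(.re1("/Width\\s+(\\d+)", obj$dict))
  h <- as.integer(.re1("/Height\\s+(\\d+)", obj$dict))
  bpc <- .re1("/BitsPerComponent\\s+(\\d+)", obj$dict)
  if (is.na(w) || is.na(h)) return(NULL)
  if (!is.na(bpc) && bpc != "8") return(NULL)
  if (grepl("/DCTDecode", obj$dict, useBytes = TRUE)) {
    img <- jpeg::readJPEG(obj$stream)
    px <- image_patch(img)
    return(px)
  }
  if (grepl("/Predictor", obj$dict, useBytes = TRUE)) return(NULL)
  data <- tryCatch(.pdf_decode_stream(obj), error = function(e) NULL)
  if (is.null(data)) return(NULL)
  gray <- grepl("/DeviceGray", obj$dict, useBytes = TRUE)
  nch <- if (gray) 1L else 3L
  if (length(data) < w * h * nch) return(NULL)
  v <- as.integer(data[seq_len(w * h * nch)])
  if (gray) {
    px <- t(matrix(v, nrow = w))
    array(rep(px, 3), dim = c(h, w, 3))
  } else {
    aperm(array(v, dim = c(3, w, h)), c(3, 2, 1))
  }
}

.pdf_collect_pages <- function(objs, id) {
  obj <- objs[[as.character(id)]]
  if (is.null(obj)) return(integer(0))
  if (grepl("/Type\\s*/Pages", obj$dict, perl = TRUE, useBytes = TRUE)) {
    kids_s <- .re1("/Kids\\s*\\[([^\\]]*)\\]", obj$dict)
    kid_ids <- as.integer(
      regmatches(kids_s, gregexpr("(\\d+)(?=\\s+\\d+\\s+R)", kids_s,
                                  perl = TRUE))[[1]])
    unlist(lapply(kid_ids, .pdf_collect_pages, objs = objs))
  } else {
    as.integer(id)
  }
}

#' Extract embedded raster images from a PDF
#'
#' Parses the page tree and, per page, decodes each placed image XObject
#' together with its placement rectangle. Coordinates are reported in page
#' points with a top-left origin; page numbers are 1-based. Vector graphics
#' are ignored; unsupported image encodings are skipped with a warning.
#'
#' @param path PDF file path.
#' @return List of records `list(page, bbox, pixels)`, in page then
#'   placement order.
#' @export
pdf_extract_rasters <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("ingestion error: cannot read '%s'", path))
  }
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 5 ||
      !identical(bytes[1:5], charToRaw("%PDF-"))) {
    stop(sprintf("ingestion error: '%s' is not a PDF file", path))
  }
  txt <- .pdf_searchable(bytes)
  if (grepl("/Encrypt", txt, useBytes = TRUE)) {
    stop(sprintf("ingestion error: '%s' is encrypted", path))
  }
  objs <- .pdf_parse_objects(bytes, txt, path)

  cat_id <- NULL
  for (id in names(objs)) {
    if (grepl("/Type\\s*/Catalog", objs[[id]]$dict, perl = TRUE,
              useBytes = TRUE)) {
      cat_id <- id
      break
    }
  }
  if (is.null(cat_id)) {
    stop(sprintf("ingestion error: no document catalog in '%s'", path))
  }
  root <- .re1("/Pages\\s+(\\d+)\\s+\\d+\\s+R", objs[[cat_id]]$dict)
  page_ids <- .pdf_collect_pages(objs, as.integer(root))

  records <- list()
  for (pnum in seq_along(page_ids)) {
    pobj <- objs[[as.character(page_ids[pnum])]]
    mb <- .re1("/MediaBox\\s*\\[([^\\]]*)\\]", pobj$dict)
    if (is.na(mb)) {
      mb <- .re1("/MediaBox\\s*\\[([^\\]]*)\\]", objs[[root]]$dict)
    }
    media <- if (is.na(mb)) c(0, 0, 612, 792) else scan(text = mb, quiet = TRUE)
    ph <- media[4] - media[2]

    # XObject name -> object id map
    res <- pobj$dict
    res_ref <- .re1("/Resources\\s+(\\d+)\\s+\\d+\\s+R", res)
    if (!is.na(res_ref)) res <- objs[[res_ref]]$dict
    xo_s <- .re1("/XObject\\s*<<([^>]*)>>", res)
    xmap <- list()
    if (!is.na(xo_s)) {
      mm <- regmatches(xo_s, gregexpr("/(\\w+)\\s+(\\d+)\\s+\\d+\\s+R", xo_s,
                                      perl = TRUE))[[1]]
      for (ent in mm) {
        nm <- sub("^/(\\w+)\\s.*", "\\1", ent)
        oid <- sub("^/\\w+\\s+(\\d+).*", "\\1", ent)
        xmap[[nm]] <- oid
      }
    }

    content_ref <- .re1("/Contents\\s+(\\d+)\\s+\\d+\\s+R", pobj$dict)
    if (is.na(content_ref)) next
    content <- tryCatch(
      rawToChar(.pdf_decode_stream(objs[[content_ref]])),
      error = function(e) "")
    num <- "([0-9eE.+-]+)"
    pat <- paste0(num, "\\s+", num, "\\s+", num, "\\s+", num, "\\s+",
                  num, "\\s+", num, "\\s+cm\\s+/(\\w+)\\s+Do")
    mm <- regmatches(content, gregexpr(pat, content, perl = TRUE))[[1]]
    for (ent in mm) {
      parts <- regmatches(ent, regexec(pat, ent, perl = TRUE))[[1]][-1]
      a <- as.numeric(parts[1]); d <- as.numeric(parts[4])
      e <- as.numeric(parts[5]); f <- as.numeric(parts[6])
      nm <- parts[7]
      oid <- xmap[[nm]]
      if (is.null(oid)) next
      px <- .pdf_decode_image(objs[[oid]])
      if (is.null(px)) {
        warning(sprintf("skipping unsupported image XObject /%s on page %d",
                        nm, pnum))
        next
      }
      records[[length(records) + 1]] <- list(
        page = pnum,
        bbox = c(e, ph - f - d, e + a, ph - f),
        pixels = px
      )
    }
  }
  records
}
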