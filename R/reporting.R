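# End-to-end document audit: ingest -> detect skin images -> segment skin
# pixels -> classify tone -> aggregate a representation report, with every
# counted image traceable to its (page, bbox) provenance.

#' Audit a document for skin tone representation
#'
#' Runs the full pipeline on a document: figure extraction, skin-image
#' detection, skin-pixel segmentation, and tone classification, then
#' aggregates counts and the proportion of dark (FST V-VI) skin images.
#' Images whose segmentation mask comes back empty cannot be tone-classified
#' and are counted separately as excluded.
#'
#' @param document Path to a PDF or a directory of raster images.
#' @param detector A fitted [train_detector()] model, or a function
#'   `f(patch) -> P(skin)`.
#' @param tone_model A tone model ([train_tone_ensemble()] /
#'   [finetune_cnn()]), the string `"ita"`, or a function
#'   `f(patch, mask) -> P(V-VI)`.
#' @param config Optional list: `min_dim` (ingestion filter, default 100),
#'   `seg` (segmentation config, see [segment_skin()]), `ita_table`,
#'   `detect_threshold` (default 0.5).
#' @return A `representation_report`.
#' @export
audit_document <- function(document, detector, tone_model = "ita",
                           config = list()) {
  if (missing(detector) || is.null(detector)) {
    stop("config error: a fitted detector (or detector function) is required")
  }
  if (is.null(tone_model)) {
    stop("config error: a tone model, 'ita', or a tone function is required")
  }
  min_dim <- config$min_dim %||% 100
  seg_cfg <- config$seg %||% list()
  table <- config$ita_table %||% ita_fst_table()
  thr <- config$detect_threshold %||% 0.5

  records <- extract_images(document, min_dim = min_dim)
  doc_id <- if (length(records)) records[[1]]$doc_id else
    basename(tools::file_path_sans_ext(document))

  rows <- lapply(records, function(r) {
    p_skin <- if (is.function(detector)) {
      detector(r$pixels)
    } else {
      predict_detector(detector, matrix(detection_features(r$pixels), 1))$prob
    }
    row <- data.frame(
      doc_id = r$doc_id, page = r$page,
      x0 = r$bbox[1], y0 = r$bbox[2], x1 = r$bbox[3], y1 = r$bbox[4],
      p_skin = as.numeric(p_skin), is_skin = as.numeric(p_skin) >= thr,
      n_skin_pixels = NA_integer_, mean_ita = NA_real_,
      p_dark = NA_real_, tone_class = NA_character_,
      stringsAsFactors = FALSE
    )
    if (!row$is_skin) return(row)
    mask <- segment_skin(r$pixels, seg_cfg)
    row$n_skin_pixels <- sum(mask)
    if (!any(mask)) {
      row$tone_class <- "excluded"
      return(row)
    }
    row$mean_ita <- mean(ita_map(r$pixels, mask))
    lab <- predict_tone(tone_model, r$pixels, mask, table)
    row$p_dark <- lab$score
    row$tone_class <- lab$fst_class
    row
  })
  per_image <- if (length(rows)) do.call(rbind, rows) else
    data.frame(doc_id = character(0))

  n_total <- length(records)
  n_skin <- sum(per_image$is_skin %||% logical(0))
  n_dark <- sum(per_image$tone_class == "V-VI", na.rm = TRUE)
  n_light <- sum(per_image$tone_class == "I-IV", na.rm = TRUE)
  n_excluded <- sum(per_image$tone_class == "excluded", na.rm = TRUE)
  structure(
    list(
      doc_id = doc_id,
      n_images_total = n_total,
      n_skin = n_skin,
      n_nonskin = n_total - n_skin,
      n_dark = n_dark,
      n_light = n_light,
      n_excluded = n_excluded,
      prop_dark = if (n_dark + n_light > 0) n_dark / (n_dark + n_light)
                  else NA_real_,
      per_image = per_image
    ),
    class = "representation_report"
  )
}

#' @export
print.representation_report <- function(x, ...) {
  cat(sprintf("<representation_report> %s\n", x$doc_id))
  cat(sprintf("  images: %d (%d skin, %d non-skin)\n",
              x$n_images_total, x$n_skin, x$n_nonskin))
  if (x$n_skin == 0) {
    cat("  no skin images detected\n")
  } else {
    cat(sprintf("  tone: %d dark (FST V-VI), %d light (FST I-IV), %d excluded\n",
                x$n_dark, x$n_light, x$n_excluded))
    cat(sprintf("  proportion dark: %s\n",
                if (is.na(x$prop_dark)) "undefined"
                else sprintf("%.1f%%", 100 * x$prop_dark)))
  }
  invisible(x)
}

#' Render a representation report to a file
#'
#' JSON renders the complete report (lossless round trip via
#' [read_report()]); Markdown is a human summary; CSV holds the per-image
#' records.
#'
#' @param report A `representation_report`.
#' @param path Output file path.
#' @param format `"json"`, `"md"`, or `"csv"`.
#' @return Invisibly, `path`.
#' @export
render_report <- function(report, path, format = c("json", "md", "csv")) {
  if (!inherits(report, "representation_report")) {
    stop("report must be a representation_report")
  }
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null", dataframe = "rows",
                         pretty = TRUE)
  } else if (format == "csv") {
    utils::write.csv(report$per_image, path, row.names = FALSE)
  } else {
    lines <- c(
      sprintf("# Skin tone representation report: %s", report$doc_id),
      "",
      sprintf("- Images extracted: %d", report$n_images_total),
      sprintf("- Skin images: %d; non-skin images: %d",
              report$n_skin, report$n_nonskin)
    )
    if (report$n_skin == 0) {
      lines <- c(lines, "", "No skin images detected.")
    } else {
      lines <- c(lines,
        sprintf("- Dark (FST V-VI): %d; light (FST I-IV): %d; excluded (no skin pixels): %d",
                report$n_dark, report$n_light, report$n_excluded),
        sprintf("- Proportion dark among classified skin images: %s",
                if (is.na(report$prop_dark)) "undefined"
                else sprintf("%.1f%%", 100 * report$prop_dark)))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a JSON representation report back
#'
#' @param path Path written by [render_report()] with `format = "json"`.
#' @return A `representation_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_image <- as.data.frame(x$per_image)
  structure(x, class = "representation_report")
}

#' Oracle detector and tone models from a truth manifest
#'
#' Builds lookup-based models from a [gen_document()] truth table: each
#' image is matched by its pixel MD5 and labeled with the generator's
#' ground truth. Used to validate pipeline count conservation independently
#' of trained-model error.
#'
#' @param truth Truth data.frame from [gen_document()].
#' @return List with `detector` and `tone` functions usable in
#'   [audit_document()].
#' @export
oracle_models <- function(truth) {
  lookup <- function(px) {
    key <- pixels_md5(px)
    hit <- which(truth$md5 == key)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  list(
    detector = function(patch) {
      i <- lookup(patch)
      if (is.na(i)) 0 else as.numeric(truth$is_skin[i])
    },
    tone = function(patch, mask) {
      i <- lookup(patch)
      if (is.na(i) || is.na(truth$tone[i])) 0
      else as.numeric(truth$tone[i] == "V-VI")
    }
  )
}
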