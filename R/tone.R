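# Skin tone estimation: ITA-threshold mapping to Fitzpatrick categories,
# ensemble classifiers on masked tone features, prediction plumbing shared
# with the CNN path, weighted metrics, and the stratified 70/10/20 split.

.FST_ROMAN <- c("I", "II", "III", "IV", "V", "VI")

#' Default ITA to Fitzpatrick threshold table
#'
#' Decreasing ITA thresholds (degrees) separating FST I..VI:
#' I: ITA > 55; II: (41, 55\]; III: (28, 41\]; IV: (10, 28\];
#' V: (-30, 10\]; VI: <= -30. With this table the binary cut is
#' FST V-VI iff ITA <= 10 degrees. Boundary values belong to the darker
#' (higher-index) category by default; set `tie = "lighter"` to flip.
#'
#' @param thresholds Strictly decreasing numeric vector of 5 thresholds.
#' @param tie `"darker"` (default) or `"lighter"`: which category a value
#'   exactly on a threshold belongs to.
#' @return An `ita_fst_table` object.
#' @export
ita_fst_table <- function(thresholds = c(55, 41, 28, 10, -30),
                          tie = c("darker", "lighter")) {
  tie <- match.arg(tie)
  if (length(thresholds) != 5 || any(diff(thresholds) >= 0)) {
    stop("thresholds must be 5 strictly decreasing values")
  }
  structure(list(thresholds = thresholds, tie = tie),
            class = "ita_fst_table")
}

#' Map an ITA value to a Fitzpatrick category
#'
#' Interval lookup in an [ita_fst_table()]; the binary class is V-VI iff
#' the Fitzpatrick index is V or VI (with the default table, iff
#' ITA <= 10 degrees).
#'
#' @param ita ITA in degrees, in \[-90, 90\].
#' @param table An [ita_fst_table()].
#' @return A `tone_label` list: `fst_index` (roman numeral), `fst_class`
#'   (`"I-IV"` / `"V-VI"`), `score` (1 if V-VI else 0), `ita`.
#' @export
ita_to_fst <- function(ita, table = ita_fst_table()) {
  if (!is.numeric(ita) || length(ita) != 1 || is.na(ita) ||
      ita < -90 || ita > 90) {
    stop("ita must be a single value in [-90, 90] degrees")
  }
  idx <- if (table$tie == "darker") {
    1L + sum(table$thresholds >= ita)
  } else {
    1L + sum(table$thresholds > ita)
  }
  cls <- if (idx >= 5) "V-VI" else "I-IV"
  structure(
    list(fst_index = .FST_ROMAN[idx], fst_class = cls,
         score = as.numeric(cls == "V-VI"), ita = ita),
    class = "tone_label"
  )
}

#' @export
print.tone_label <- function(x, ...) {
  cat(sprintf("<tone_label> FST %s (%s), P(V-VI) = %.3f%s\n",
              x$fst_index %||% "-", x$fst_class, x$score,
              if (!is.null(x$ita)) sprintf(", mean ITA %.1f deg", x$ita)
              else ""))
  invisible(x)
}

#' Classify skin tone from the mean ITA over a mask
#'
#' Summarizes the per-pixel ITA of the masked skin region by its mean and
#' maps it through the threshold table.
#'
#' @param patch Image patch.
#' @param mask Non-empty logical skin mask.
#' @param table An [ita_fst_table()].
#' @return A `tone_label` (with `ita` = the mean ITA used).
#' @export
classify_tone_ita <- function(patch, mask, table = ita_fst_table()) {
  ita <- ita_map(patch, mask)
  ita_to_fst(mean(ita), table)
}

.as_tone_labels <- function(y) {
  if (is.logical(y)) y <- ifelse(y, "V-VI", "I-IV")
  y <- factor(as.character(y), levels = c("I-IV", "V-VI"))
  if (anyNA(y)) stop("tone labels must be 'I-IV'/'V-VI' (or logical)")
  y
}

# SAMME.R AdaBoost over depth-1 rpart stumps (binary)
.train_adaboost <- function(X, y, n_stumps = 60, seed = 1) {
  set.seed(seed)
  n <- nrow(X)
  w <- rep(1 / n, n)
  ypm <- ifelse(y == levels(y)[2], 1, -1)
  df <- data.frame(y = y, X)
  stumps <- vector("list", n_stumps)
  eps <- 1e-6
  for (t in seq_len(n_stumps)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = -1, minsplit = 2,
                          minbucket = 1, xval = 0))
    p <- stats::predict(fit, df)[, 2]
    p <- pmin(pmax(p, eps), 1 - eps)
    h <- 0.5 * (log(p) - log1p(-p))
    w <- w * exp(-ypm * h)
    w <- w / sum(w)
    stumps[[t]] <- fit
  }
  stumps
}

.predict_adaboost <- function(stumps, X) {
  df <- as.data.frame(X)
  eps <- 1e-6
  score <- rowSums(vapply(stumps, function(fit) {
    p <- stats::predict(fit, df)[, 2]
    p <- pmin(pmax(p, eps), 1 - eps)
    0.5 * (log(p) - log1p(-p))
  }, numeric(nrow(df))))
  1 / (1 + exp(-2 * score))
}

#' Train an ensemble skin-tone classifier
#'
#' Fits one of five ensemble kinds on tone feature vectors
#' ([tone_features()]): random forest, balanced random forest (per-class
#' balanced bootstrap sampling, for the imbalanced FST V-VI minority),
#' extremely randomized trees, AdaBoost (SAMME.R over stumps), or gradient
#' boosting. The positive class is FST V-VI.
#'
#' @param X n x p matrix of tone feature vectors.
#' @param y Labels `"I-IV"` / `"V-VI"` (or logical, TRUE = V-VI).
#' @param kind One of `"random-forest"`, `"balanced-random-forest"`,
#'   `"extra-trees"`, `"adaboost"`, `"gradient-boosting"`.
#' @param seed RNG seed.
#' @return A `tone_model` object.
#' @export
train_tone_ensemble <- function(X, y,
                                kind = c("random-forest",
                                         "balanced-random-forest",
                                         "extra-trees", "adaboost",
                                         "gradient-boosting"),
                                seed = 1) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- .as_tone_labels(y)
  if (length(unique(y)) < 2) {
    stop("training error: both tone classes must be present")
  }
  set.seed(seed)
  inner <- switch(kind,
    "random-forest" = randomForest::randomForest(X, y, ntree = 300),
    "balanced-random-forest" = {
      nmin <- min(table(y))
      randomForest::randomForest(X, y, ntree = 300,
                                 sampsize = c(nmin, nmin), strata = y)
    },
    "extra-trees" = ranger::ranger(
      x = X, y = y, num.trees = 300, splitrule = "extratrees",
      probability = TRUE, seed = seed, num.threads = 1),
    "adaboost" = .train_adaboost(X, y, seed = seed),
    "gradient-boosting" = .xgb_fit(X, as.integer(y == "V-VI"),
                                   nrounds = 100, max_depth = 3, eta = 0.1,
                                   seed = seed)
  )
  structure(
    list(kind = kind, inner = inner, feature_dim = ncol(X), seed = seed),
    class = "tone_model"
  )
}

#' Predict the probability of FST V-VI from tone features
#'
#' @param model A [train_tone_ensemble()] model.
#' @param X n x p matrix of tone feature vectors.
#' @return Numeric vector of P(V-VI).
#' @export
predict_tone_ensemble <- function(model, X) {
  if (!inherits(model, "tone_model")) stop("model is not fitted")
  X <- as.matrix(X)
  if (ncol(X) != model$feature_dim) {
    stop(sprintf("feature matrix must have %d columns", model$feature_dim))
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  switch(model$kind,
    "extra-trees" = stats::predict(model$inner, data = X,
                                   num.threads = 1)$predictions[, "V-VI"],
    "adaboost" = .predict_adaboost(model$inner, X),
    "gradient-boosting" = .xgb_prob(model$inner, X),
    stats::predict(model$inner, X, type = "prob")[, "V-VI"]
  )
}

#' Classify the tone of one masked image
#'
#' Dispatches on the model type: ensemble models consume the tone feature
#' vector of the masked region; CNN models consume the masked image
#' (non-skin pixels zeroed) resized to the network input; `"ita"` uses the
#' mean-ITA threshold path. An empty mask raises a `no skin detected`
#' error.
#'
#' @param model A `tone_model`, a `cnn_model`, or the string `"ita"`.
#' @param patch Image patch.
#' @param mask Logical skin mask (non-empty).
#' @param table ITA threshold table for the `"ita"` path.
#' @return A `tone_label` with `score` = P(V-VI) and hard class at 0.5.
#' @export
predict_tone <- function(model, patch, mask, table = ita_fst_table()) {
  patch <- image_patch(patch)
  mask <- as_mask(mask, dim(patch)[1:2])
  if (!any(mask)) {
    stop("no skin detected: mask is empty")
  }
  if (identical(model, "ita")) {
    return(classify_tone_ita(patch, mask, table))
  }
  if (inherits(model, "tone_model")) {
    p <- predict_tone_ensemble(model, matrix(tone_features(patch, mask), 1))
  } else if (inherits(model, "cnn_model")) {
    p <- predict_cnn(model, list(.masked_image(patch, mask)))
  } else if (is.function(model)) {
    p <- model(patch, mask)
  } else {
    stop("config error: unsupported tone model")
  }
  cls <- if (p >= 0.5) "V-VI" else "I-IV"
  structure(list(fst_index = NULL, fst_class = cls, score = as.numeric(p),
                 ita = NULL),
            class = "tone_label")
}

.masked_image <- function(patch, mask) {
  patch * as.numeric(rep(mask, 3))
}

#' Frequency-weighted binary classification metrics
#'
#' Per-class binary precision, recall and F1 averaged with weights equal to
#' the class frequencies in `y_true` (so they reduce to the ordinary binary
#' metrics under exact class balance), plus plain accuracy and the
#' threshold-free AUROC with FST V-VI as the positive class.
#'
#' @param y_true True labels `"I-IV"`/`"V-VI"` (or logical, TRUE = V-VI).
#' @param scores Predicted P(V-VI).
#' @param threshold Hard-label threshold (default 0.5).
#' @return Named list: `accuracy`, `precision`, `recall`, `f1` (weighted),
#'   `auroc` (NA with a warning if only one class is present).
#' @export
weighted_metrics <- function(y_true, scores, threshold = 0.5) {
  y_true <- .as_tone_labels(y_true)
  pred <- factor(ifelse(scores >= threshold, "V-VI", "I-IV"),
                 levels = levels(y_true))
  per_class <- lapply(levels(y_true), function(cl) {
    t_pos <- y_true == cl
    p_pos <- pred == cl
    tp <- sum(t_pos & p_pos)
    prec <- if (sum(p_pos) > 0) tp / sum(p_pos) else 0
    rec <- if (sum(t_pos) > 0) tp / sum(t_pos) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec = prec, rec = rec, f1 = f1, w = mean(t_pos))
  })
  pc <- do.call(rbind, per_class)
  auc <- if (length(unique(y_true)) < 2) {
    warning("AUROC undefined: only one class present in y_true")
    NA_real_
  } else {
    auroc(y_true == "V-VI", scores)
  }
  list(
    accuracy = mean(pred == y_true),
    precision = sum(pc[, "prec"] * pc[, "w"]),
    recall = sum(pc[, "rec"] * pc[, "w"]),
    f1 = sum(pc[, "f1"] * pc[, "w"]),
    auroc = auc
  )
}

#' Stratified train/validation/test split
#'
#' Splits indices into 70/10/20 (by default) proportions, stratified by
#' class so each split's proportions match to within one sample per class.
#'
#' @param y Class labels.
#' @param props Length-3 proportions summing to 1.
#' @param seed RNG seed.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_data <- function(y, props = c(0.7, 0.1, 0.2), seed = 1) {
  if (length(props) != 3 || abs(sum(props) - 1) > 1e-8) {
    stop("props must be three proportions summing to 1")
  }
  y <- as.factor(y)
  set.seed(seed)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    n <- length(idx)
    n_tr <- round(props[1] * n)
    n_va <- min(round(props[2] * n), n - n_tr)
    out$train <- c(out$train, idx[seq_len(n_tr)])
    out$val <- c(out$val, idx[seq_len(n_va) + n_tr])
    if (n_tr + n_va < n) {
      out$test <- c(out$test, idx[seq.int(n_tr + n_va + 1, n)])
    }
  }
  lapply(out, sort)
}
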