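# Skin vs non-skin image classification on the 38-dim detection descriptor:
# nu-SVM (RBF) or gradient-boosted trees with internal 3-fold calibration,
# evaluated with stratified k-fold cross-validation (AUROC and F1, skin
# positive).

.DETECTION_DIM <- 38L

.as_detection_labels <- function(y) {
  if (is.logical(y)) {
    y <- ifelse(y, "skin", "nonskin")
  }
  y <- factor(as.character(y), levels = c("nonskin", "skin"))
  if (anyNA(y)) stop("labels must be 'skin'/'nonskin' (or logical)")
  y
}

.check_features <- function(X, dim_expected = .DETECTION_DIM) {
  X <- as.matrix(X)
  if (ncol(X) != dim_expected) {
    stop(sprintf("feature matrix must have %d columns, got %d",
                 dim_expected, ncol(X)))
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("feature matrix contains NA or non-finite values")
  }
  X
}

#' AUROC with a fixed score orientation
#'
#' Wrapper around pROC with `direction` pinned so that larger scores for
#' the positive class mean better, never auto-flipped.
#'
#' @param truth Logical vector (TRUE = positive class).
#' @param scores Numeric scores.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(truth, scores) {
  if (length(unique(truth)) < 2) {
    stop("AUROC undefined: only one class present")
  }
  as.numeric(pROC::auc(pROC::roc(
    response = factor(truth, levels = c(FALSE, TRUE)),
    predictor = scores, levels = c("FALSE", "TRUE"),
    direction = "<", quiet = TRUE
  )))
}

.f1_score <- function(truth, pred) {
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Stratified k-fold assignment
#'
#' @param y Factor (or coercible) class labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold assignment in `1:k`, with each fold's class ratio
#'   within one sample of the global ratio.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop(sprintf(
      "each class needs at least k = %d members; use a smaller k", k))
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.xgb_grid <- function() {
  expand.grid(max_depth = c(2, 4), nrounds = c(50, 150), eta = c(0.1, 0.3))
}

.xgb_fit <- function(X, y01, nrounds, max_depth, eta, seed) {
  set.seed(seed)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y01, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
}

.xgb_prob <- function(fit, X) {
  stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1))
}

.train_xgb <- function(X, y01, seed, calibrate = TRUE) {
  grid <- .xgb_grid()
  best <- list(auc = -Inf, row = 1)
  if (calibrate) {
    folds <- stratified_folds(factor(y01), 3, seed = seed)
    for (g in seq_len(nrow(grid))) {
      aucs <- vapply(1:3, function(f) {
        tr <- folds != f
        m <- .xgb_fit(X[tr, , drop = FALSE], y01[tr], grid$nrounds[g],
                      grid$max_depth[g], grid$eta[g], seed)
        if (length(unique(y01[!tr])) < 2) return(NA_real_)
        auroc(y01[!tr] == 1, .xgb_prob(m, X[!tr, , drop = FALSE]))
      }, numeric(1))
      a <- mean(aucs, na.rm = TRUE)
      if (a > best$auc) best <- list(auc = a, row = g)
    }
  }
  g <- best$row
  fit <- .xgb_fit(X, y01, grid$nrounds[g], grid$max_depth[g], grid$eta[g],
                  seed)
  list(fit = fit, params = grid[g, ], cv_auc = best$auc)
}

.train_nusvm <- function(X, y, seed) {
  set.seed(seed)
  fit <- e1071::svm(
    x = X, y = y, type = "nu-classification", kernel = "radial",
    nu = 0.01, gamma = 0.05, scale = TRUE
  )
  dvm <- attr(stats::predict(fit, X, decision.values = TRUE),
              "decision.values")
  # orient the decision axis so larger means the positive (second) level,
  # then map scores to probabilities through a logistic fit
  pos <- levels(y)[2]
  sgn <- if (startsWith(colnames(dvm)[1], paste0(pos, "/"))) 1 else -1
  z <- sgn * dvm[, 1]
  cal <- suppressWarnings(
    stats::glm((y == pos) ~ z, family = stats::binomial()))
  list(fit = fit, sign = sgn, calibration = cal)
}

#' Train the skin-image detector
#'
#' Fits either a nu-SVM with RBF kernel (nu = 0.01, gamma = 0.05; scores
#' calibrated to probabilities by a logistic fit on the training decision
#' values) or gradient-boosted trees whose hyperparameters are chosen by an
#' internal 3-fold cross-validated AUROC over a small grid of depth, number
#' of rounds, and learning rate.
#'
#' @param X n x 38 feature matrix (rows from [detection_features()]).
#' @param y Labels: `"skin"` / `"nonskin"`, or logical (TRUE = skin).
#' @param algorithm `"xgb"` (default) or `"svm"`.
#' @param seed RNG seed; the whole fit is reproducible given the seed.
#' @return A `detection_model` object.
#' @export
train_detector <- function(X, y, algorithm = c("xgb", "svm"), seed = 1) {
  algorithm <- match.arg(algorithm)
  X <- .check_features(X)
  y <- .as_detection_labels(y)
  if (nrow(X) != length(y)) stop("X and y lengths differ")
  if (nrow(X) < 10) stop("need at least 10 training samples")
  if (length(unique(y)) < 2) {
    stop("training error: both classes must be present in y")
  }
  inner <- if (algorithm == "xgb") {
    .train_xgb(X, as.integer(y == "skin"), seed)
  } else {
    .train_nusvm(X, y, seed)
  }
  structure(
    list(algorithm = if (algorithm == "xgb") "gradient-boosted-trees"
         else "nu-svm-rbf",
         inner = inner, feature_dim = .DETECTION_DIM,
         positive_class = "skin", seed = seed),
    class = "detection_model"
  )
}

#' Predict skin probabilities for images
#'
#' @param model A fitted [train_detector()] model.
#' @param X n x 38 feature matrix.
#' @param threshold Probability threshold for the hard label (default 0.5;
#'   label is skin iff p >= threshold).
#' @return List with `prob` (P(skin)) and `label` (factor).
#' @export
predict_detector <- function(model, X, threshold = 0.5) {
  if (!inherits(model, "detection_model")) stop("model is not fitted")
  X <- .check_features(X, model$feature_dim)
  if (model$algorithm == "gradient-boosted-trees") {
    p <- .xgb_prob(model$inner$fit, X)
  } else {
    dv <- attr(stats::predict(model$inner$fit, X, decision.values = TRUE),
               "decision.values")[, 1]
    z <- model$inner$sign * dv
    p <- as.numeric(stats::predict(model$inner$calibration,
                                   newdata = data.frame(z = z),
                                   type = "response"))
  }
  list(prob = p,
       label = factor(ifelse(p >= threshold, "skin", "nonskin"),
                      levels = c("nonskin", "skin")))
}

#' Stratified cross-validated evaluation of the detector
#'
#' Stratified k-fold cross-validation reporting per-fold AUROC and F1
#' (skin positive, threshold 0.5) and their mean and standard deviation.
#'
#' @param X n x 38 feature matrix.
#' @param y Labels as in [train_detector()].
#' @param algorithm `"xgb"` or `"svm"`.
#' @param k Number of folds (default 5); every class needs >= k members.
#' @param seed RNG seed.
#' @return An `eval_result` list: `per_fold` data.frame, `auroc`, `f1`,
#'   `auroc_sd`, `f1_sd`.
#' @export
crossval_evaluate <- function(X, y, algorithm = c("xgb", "svm"), k = 5,
                              seed = 1) {
  algorithm <- match.arg(algorithm)
  X <- .check_features(X)
  y <- .as_detection_labels(y)
  folds <- stratified_folds(y, k, seed = seed)
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- train_detector(X[tr, , drop = FALSE], y[tr], algorithm,
                        seed = seed + f)
    pr <- predict_detector(m, X[!tr, , drop = FALSE])
    truth <- y[!tr] == "skin"
    data.frame(fold = f,
               auroc = auroc(truth, pr$prob),
               f1 = .f1_score(truth, pr$label == "skin"))
  }))
  structure(
    list(per_fold = per_fold,
         auroc = mean(per_fold$auroc), auroc_sd = stats::sd(per_fold$auroc),
         f1 = mean(per_fold$f1), f1_sd = stats::sd(per_fold$f1),
         k = k, algorithm = algorithm),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s): AUROC %.3f +/- %.3f, F1 %.3f +/- %.3f\n",
              x$k, x$algorithm, x$auroc, x$auroc_sd, x$f1, x$f1_sd))
  invisible(x)
}
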