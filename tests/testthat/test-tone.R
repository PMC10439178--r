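# ITA-based Fitzpatrick mapping, ensemble tone classifiers, weighted
# metrics and the stratified data split.

test_that("ITA threshold table maps angles to Fitzpatrick categories", {
  tb <- ita_fst_table()
  expect_equal(ita_to_fst(60, tb)$fst_index, "I")
  expect_equal(ita_to_fst(60, tb)$fst_class, "I-IV")
  r0 <- ita_to_fst(0, tb)
  expect_equal(r0$fst_index, "V")
  expect_equal(r0$fst_class, "V-VI")
  expect_equal(ita_to_fst(-45, tb)$fst_index, "VI")
  # binary cut: V-VI iff ITA <= 10 with the default table
  expect_equal(ita_to_fst(10, tb)$fst_class, "V-VI")
  expect_equal(ita_to_fst(10 + 1e-9, tb)$fst_class, "I-IV")
  # boundary tie rule is explicit and configurable
  expect_equal(ita_to_fst(55, tb)$fst_index, "II")
  expect_equal(ita_to_fst(55, ita_fst_table(tie = "lighter"))$fst_index, "I")
  # monotone: higher ITA never darker
  idx <- vapply(seq(-85, 85, by = 2.5), function(a) {
    match(ita_to_fst(a, tb)$fst_index, c("I", "II", "III", "IV", "V", "VI"))
  }, numeric(1))
  expect_true(all(diff(idx) <= 0))
  expect_error(ita_to_fst(120, tb), "degrees")
  expect_error(ita_fst_table(c(10, 20, 30, 40, 50)), "decreasing")
})

test_that("mean-ITA classification matches closed forms and is scale invariant", {
  light <- uniform_patch(round(lab_to_srgb(matrix(c(70, 10, 20), 1))), 20, 20)
  dark <- uniform_patch(round(lab_to_srgb(matrix(c(35, 10, 8), 1))), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  expect_equal(classify_tone_ita(light, mask)$fst_class, "I-IV")
  rd <- classify_tone_ita(dark, mask)
  expect_equal(rd$fst_index, "VI")
  expect_equal(rd$fst_class, "V-VI")
  # closed form: ITA of (L = 35, b = 8) is atan(-15 / 8) = -61.93 degrees,
  # up to the quantization of the rendered 8-bit color
  expect_equal(rd$ita, -61.93, tolerance = 0.02)
  lab_realized <- srgb_to_lab(matrix(dark[1, 1, ], 1))
  expect_equal(rd$ita, ita_angle(lab_realized[1], lab_realized[3]),
               tolerance = 1e-9)

  # invariant to uniform rescaling of the image
  big <- uniform_patch(round(lab_to_srgb(matrix(c(70, 10, 20), 1))), 60, 60)
  expect_equal(classify_tone_ita(big, matrix(TRUE, 60, 60))$ita,
               classify_tone_ita(light, mask)$ita, tolerance = 1e-9)

  # half light / half dark pixels: label from the hand-computed mean
  px <- array(0, dim = c(10, 10, 3))
  lr <- round(lab_to_srgb(matrix(c(70, 10, 20), 1)))
  dr <- round(lab_to_srgb(matrix(c(35, 10, 8), 1)))
  for (ch in 1:3) {
    px[1:5, , ch] <- lr[ch]
    px[6:10, , ch] <- dr[ch]
  }
  m <- matrix(TRUE, 10, 10)
  ita_vals <- ita_map(px, m)
  expect_equal(classify_tone_ita(px, m)$ita, mean(ita_vals))
  expect_equal(classify_tone_ita(px, m)$ita,
               (45 + -61.93) / 2, tolerance = 0.15)
  expect_error(classify_tone_ita(px, matrix(FALSE, 10, 10)), "no skin")
})

tone_fixture <- function(n = 300, seed = 1, p_dark = 0.5) {
  spec <- synthetic_spec(seed = seed, n_images = n, skin_prop = 1,
                        tone_mix = p_dark)
  ds <- gen_dataset(spec)
  X <- t(vapply(seq_len(n), function(i) {
    tone_features(ds$images[[i]], ds$masks[[i]])
  }, numeric(38)))
  list(X = X, y = droplevels(ds$tone))
}

test_that("every ensemble kind recovers the separable tone classes", {
  fx <- tone_fixture(n = 120, seed = 31, p_dark = 0.4)
  sp <- split_data(fx$y, seed = 2)
  for (kind in c("random-forest", "balanced-random-forest", "extra-trees",
                 "adaboost", "gradient-boosting")) {
    m <- train_tone_ensemble(fx$X[sp$train, ], fx$y[sp$train], kind, seed = 3)
    p <- predict_tone_ensemble(m, fx$X[sp$test, ])
    wm <- weighted_metrics(fx$y[sp$test], p)
    expect_gte(wm$f1, 0.9)
  }
  expect_error(train_tone_ensemble(fx$X, rep("I-IV", nrow(fx$X))),
               "both tone classes")
})

test_that("permuted tone labels give chance-level AUROC", {
  fx <- tone_fixture(n = 120, seed = 32, p_dark = 0.5)
  set.seed(4)
  yp <- sample(fx$y)
  sp <- split_data(yp, seed = 5)
  m <- train_tone_ensemble(fx$X[sp$train, ], yp[sp$train], "random-forest",
                           seed = 6)
  p <- predict_tone_ensemble(m, fx$X[sp$test, ])
  a <- weighted_metrics(yp[sp$test], p)$auroc
  expect_gt(a, 0.2)
  expect_lt(a, 0.8)
})

test_that("balanced random forest lifts minority recall under 9:1 imbalance", {
  # overlapping clouds so the plain forest can sacrifice the minority
  set.seed(7)
  n_maj <- 360; n_min <- 40
  X <- rbind(matrix(rnorm(n_maj * 38), n_maj, 38),
             matrix(rnorm(n_min * 38, mean = 0.45), n_min, 38))
  y <- factor(c(rep("I-IV", n_maj), rep("V-VI", n_min)),
              levels = c("I-IV", "V-VI"))
  sp <- split_data(y, seed = 8)
  recall <- vapply(c("random-forest", "balanced-random-forest"), function(k) {
    m <- train_tone_ensemble(X[sp$train, ], y[sp$train], k, seed = 9)
    p <- predict_tone_ensemble(m, X[sp$test, ])
    truth <- y[sp$test] == "V-VI"
    sum(p >= 0.5 & truth) / sum(truth)
  }, numeric(1))
  expect_gt(recall["balanced-random-forest"], recall["random-forest"])
})

test_that("weighted metrics match a hand-worked confusion and reduce under balance", {
  # 10 samples: 7 I-IV, 3 V-VI; one error each way
  y <- factor(c(rep("I-IV", 7), rep("V-VI", 3)), levels = c("I-IV", "V-VI"))
  scores <- c(0.1, 0.2, 0.1, 0.3, 0.2, 0.1, 0.9, 0.8, 0.7, 0.2)
  m <- weighted_metrics(y, scores)
  # hand arithmetic: V-VI tp=2 fp=1 fn=1; I-IV tp=6 fp=1 fn=1
  prec_dark <- 2 / 3; rec_dark <- 2 / 3; f1_dark <- 2 / 3
  prec_light <- 6 / 7; rec_light <- 6 / 7; f1_light <- 6 / 7
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.7 * prec_light + 0.3 * prec_dark)
  expect_equal(m$recall, 0.7 * rec_light + 0.3 * rec_dark)
  expect_equal(m$f1, 0.7 * f1_light + 0.3 * f1_dark)

  # perfect predictions
  mp <- weighted_metrics(y, as.numeric(y == "V-VI"))
  expect_equal(unlist(mp), c(accuracy = 1, precision = 1, recall = 1,
                             f1 = 1, auroc = 1))

  # balanced classes: weighted F1 equals macro F1
  yb <- factor(rep(c("I-IV", "V-VI"), each = 5), levels = c("I-IV", "V-VI"))
  sb <- c(0.1, 0.9, 0.2, 0.1, 0.3, 0.8, 0.2, 0.9, 0.7, 0.6)
  mb <- weighted_metrics(yb, sb)
  f1s <- vapply(c("I-IV", "V-VI"), function(cl) {
    pred <- ifelse(sb >= 0.5, "V-VI", "I-IV")
    tp <- sum(pred == cl & yb == cl)
    prec <- tp / sum(pred == cl); rec <- tp / sum(yb == cl)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_equal(mb$f1, mean(f1s))

  expect_warning(weighted_metrics(rep("I-IV", 5), runif(5)), "one class")
})

test_that("the data split reproduces 70/10/20 with stratification", {
  y <- factor(rep(c("I-IV", "V-VI"), times = c(80, 20)))
  sp <- split_data(y, seed = 10)
  expect_equal(length(sp$train), 70, tolerance = 1)
  expect_equal(length(sp$val), 10, tolerance = 1)
  expect_equal(length(sp$test), 20, tolerance = 1)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:100)
  # stratified: dark share preserved in each split
  for (part in sp) {
    expect_equal(mean(y[part] == "V-VI"), 0.2, tolerance = 0.06)
  }
  expect_error(split_data(y, props = c(0.5, 0.5, 0.5)), "summing to 1")
})
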