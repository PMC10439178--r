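# Image descriptors: gradients, global HOG, CIELAB statistics, ITA, tone
# features and the PCA projection.

test_that("CIELAB conversion matches the per-pixel reference and known points", {
  expect_equal(unname(srgb_to_lab(matrix(c(255, 255, 255), 1))[1, ]),
               c(100, 0, 0), tolerance = 1e-4)
  expect_equal(unname(srgb_to_lab(matrix(c(0, 0, 0), 1))[1, ]),
               c(0, 0, 0), tolerance = 1e-6)
  for (seed in 1:5) {
    p <- random_patch(6, 5, seed = seed)
    ours <- lab_stats(p)
    expect_equal(unname(ours), naive_lab_stats(p), tolerance = 1e-9)
  }
  # independent library cross-check (different internal constants, loose)
  set.seed(3)
  rgb <- matrix(runif(60, 0, 255), 20, 3)
  ref <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  expect_lt(max(abs(srgb_to_lab(rgb) - ref)), 0.5)
  # round trip through the inverse
  set.seed(4)
  lab <- cbind(runif(30, 20, 90), runif(30, -30, 30), runif(30, -30, 40))
  expect_equal(srgb_to_lab(lab_to_srgb(lab)), lab, tolerance = 0.6,
               ignore_attr = TRUE)
})

test_that("image gradients follow the central-difference definition", {
  const <- uniform_patch(c(100, 100, 100))
  g <- image_gradients(const)
  expect_true(all(g$gx == 0) && all(g$gy == 0))

  ramp <- array(0, dim = c(6, 8, 3))
  for (ch in 1:3) ramp[, , ch] <- matrix(seq_len(8) - 1, 6, 8, byrow = TRUE)
  g <- image_gradients(ramp)
  expect_true(all(abs(g$gx - 2) < 1e-12))
  expect_true(all(g$gy == 0))
  expect_equal(dim(g$gx), c(4, 6))

  for (seed in 1:5) {
    p <- random_patch(8, 8, seed = seed + 10)
    expect_equal(image_gradients(p), naive_gradients(p), tolerance = 1e-12)
  }
  expect_error(image_gradients(random_patch(2, 5)), "3 x 3")
})

test_that("HOG matches a brute-force per-pixel oracle", {
  for (seed in 1:20) {
    p <- random_patch(10, 10, seed = seed)
    expect_equal(hog_descriptor(p), naive_hog(p), tolerance = 1e-9)
  }
})

test_that("HOG closed forms: constant, step edge, normalization", {
  expect_equal(hog_descriptor(uniform_patch(c(42, 42, 42))), numeric(32))

  step <- array(0, dim = c(8, 8, 3))
  step[, 5:8, ] <- 255
  h <- hog_descriptor(step)
  # Gy = 0 everywhere => all mass in the bin containing theta = 0
  centers <- -pi / 2 + (pi / 32) * (1:32 - 0.5)
  zero_bin <- which.min(abs(centers))
  expect_equal(h[zero_bin], 1)
  expect_equal(sum(h), 1)
  expect_error(hog_descriptor(step, bins = 1), "bins")
})

test_that("HOG is invariant to a constant photometric shift and sums to 1", {
  for (seed in 1:6) {
    p <- random_patch(9, 11, seed = seed) * 0.7  # leave headroom
    h1 <- hog_descriptor(p)
    h2 <- hog_descriptor(p + 40)
    expect_equal(h1, h2, tolerance = 1e-9)
    expect_true(all(h1 >= 0))
    expect_equal(sum(h1), 1, tolerance = 1e-12)
  }
})

test_that("lab_stats of a two-color checkerboard is the two-point mixture", {
  c1 <- c(200, 150, 120); c2 <- c(40, 90, 160)
  px <- array(0, dim = c(8, 8, 3))
  chk <- outer(1:8, 1:8, function(r, c) (r + c) %% 2 == 0)
  for (ch in 1:3) {
    pl <- matrix(c2[ch], 8, 8)
    pl[chk] <- c1[ch]
    px[, , ch] <- pl
  }
  l1 <- naive_lab_pixel(c1); l2 <- naive_lab_pixel(c2)
  s <- lab_stats(px)
  expect_equal(unname(s[1:3]), (l1 + l2) / 2, tolerance = 1e-9)
  expect_equal(unname(s[4:6]), abs(l1 - l2) / 2, tolerance = 1e-9)
})

test_that("detection feature vector is the 38-dim concatenation", {
  for (dims in list(c(3, 3), c(10, 7), c(25, 40))) {
    p <- random_patch(dims[1], dims[2], seed = dims[1])
    f <- detection_features(p)
    expect_length(f, 38)
    expect_equal(unname(f), unname(c(hog_descriptor(p), lab_stats(p))))
  }
  f <- detection_features(uniform_patch(c(128, 128, 128)))
  expect_equal(unname(f[1:32]), numeric(32))
  expect_equal(unname(f[36:38]), c(0, 0, 0))
})

test_that("ITA closed forms and monotonicity", {
  expect_equal(ita_angle(50, 15), 0)
  expect_equal(ita_angle(70, 20), 45)
  expect_equal(ita_angle(30, 20), -45)
  expect_equal(ita_angle(80, 0), 90)
  expect_equal(ita_angle(50, 0), 0)
  # increasing in L at fixed b > 0
  Ls <- seq(20, 90, by = 5)
  expect_true(all(diff(ita_angle(Ls, rep(15, length(Ls)))) > 0))
  # decreasing in b at fixed L > 50
  bs <- seq(2, 40, by = 2)
  expect_true(all(diff(ita_angle(rep(70, length(bs)), bs)) < 0))
})

test_that("ita_map works over a mask and rejects an empty mask", {
  lab <- c(70, 10, 20)  # ITA 45
  px <- uniform_patch(round(lab_to_srgb(matrix(lab, 1))), 6, 6)
  mask <- matrix(TRUE, 6, 6)
  expect_equal(ita_map(px, mask), rep(45, 36), tolerance = 0.15)
  expect_error(ita_map(px, matrix(FALSE, 6, 6)), "no skin")
})

test_that("tone features summarize the masked region only", {
  lab1 <- c(70, 10, 20)   # ITA 45
  lab2 <- c(35, 10, 8.02) # ITA ~ -61.9
  rgb1 <- round(lab_to_srgb(matrix(lab1, 1)))
  rgb2 <- round(lab_to_srgb(matrix(lab2, 1)))
  px <- array(0, dim = c(6, 8, 3))
  for (ch in 1:3) {
    px[, 1:4, ch] <- rgb1[ch]
    px[, 5:8, ch] <- rgb2[ch]
  }
  full <- matrix(TRUE, 6, 8)
  half <- full; half[, 5:8] <- FALSE

  tf_half <- tone_features(px, half)
  expect_length(tf_half, 38)
  lab_true <- naive_lab_pixel(as.numeric(rgb1))
  expect_equal(unname(tf_half[c("muL", "mub")]), lab_true[c(1, 3)],
               tolerance = 1e-9)
  expect_equal(unname(tf_half[c("sdL", "sdb", "sd_ita")]), c(0, 0, 0),
               tolerance = 1e-9)

  # mixed-mask stats equal the direct two-value computation
  tf_full <- tone_features(px, full)
  l1 <- naive_lab_pixel(as.numeric(rgb1)); l2 <- naive_lab_pixel(as.numeric(rgb2))
  expect_equal(unname(tf_full["muL"]), (l1[1] + l2[1]) / 2, tolerance = 1e-9)
  expect_equal(unname(tf_full["sdb"]), abs(l1[3] - l2[3]) / 2, tolerance = 1e-9)
  ita1 <- atan((l1[1] - 50) / l1[3]) * 180 / pi
  ita2 <- atan((l2[1] - 50) / l2[3]) * 180 / pi
  expect_equal(unname(tf_full["mu_ita"]), (ita1 + ita2) / 2, tolerance = 1e-9)

  # uniform patch: identical under full mask and no-op mask copies
  pu <- uniform_patch(round(lab_to_srgb(matrix(lab1, 1))), 7, 7)
  m <- matrix(TRUE, 7, 7)
  expect_identical(tone_features(pu, m), tone_features(pu, m & TRUE))
  # mean-only mode drops one entry
  expect_length(tone_features(px, full, ita_stats = "mean"), 37)
  expect_error(tone_features(px, matrix(FALSE, 6, 8)), "empty")
})

test_that("PCA projection matches the eigendecomposition of the covariance", {
  set.seed(7)
  X <- matrix(rnorm(50 * 38), 50, 38)
  sc <- pca_project(X, k = 2)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values[1:2]
  expect_equal(unname(apply(sc, 2, stats::var)), ev, tolerance = 1e-9)

  # rank-1 data: second component vanishes
  line <- outer(seq_len(20), rnorm(38))
  sc1 <- pca_project(line, k = 2)
  expect_lt(max(abs(sc1[, 2])), 1e-8)

  same <- matrix(1, 5, 38)
  expect_equal(max(abs(pca_project(same, 2))), 0)
  expect_error(pca_project(X[1:2, ], k = 2), "k \\+ 1")
})
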