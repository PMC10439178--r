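# The 18-layer residual network: topology constants, gradient correctness
# against finite differences, training behavior and determinism.

test_that("topology parameter counts match the canonical architecture", {
  m1000 <- build_cnn(1000, input_size = 64, seed = 1)
  expect_equal(n_parameters(m1000), 11689512)
  m2 <- build_cnn(2, input_size = 64, seed = 1)
  expect_equal(n_parameters(m2), 11177538)
  # difference is exactly the swap of the classification head
  expect_equal(11689512 - n_parameters(m2), 512 * 1000 + 1000 - (512 * 2 + 2))
  expect_error(build_cnn(1), "num_classes")
})

test_that("incompatible weight files are rejected, compatible ones load", {
  m <- build_cnn(2, input_size = 32, seed = 1)
  w_bad <- list(conv1.W = rnorm(10))
  f <- tempfile(fileext = ".rds")
  saveRDS(w_bad, f)
  expect_error(load_cnn_weights(m, f), "expected")
  saveRDS(list(unknown.W = rnorm(3)), f)
  expect_error(load_cnn_weights(m, f), "unknown")
  w_ok <- list(conv1.W = m$params[["conv1.W"]] * 2)
  saveRDS(w_ok, f)
  m2 <- load_cnn_weights(m, f)
  expect_equal(m2$params[["conv1.W"]], m$params[["conv1.W"]] * 2)
})

test_that("single layers match finite differences exactly", {
  set.seed(20)
  # convolution: dW and dx
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  W <- matrix(rnorm(27 * 4, 0, 0.3), 27, 4)
  out <- skinaudit:::.conv_fw(x, W, 3L, 2L, 1L)
  R <- array(rnorm(length(out$y)), dim(out$y))
  bk <- skinaudit:::.conv_bw(R, W, out$cache)
  loss_conv <- function(x, W) sum(skinaudit:::.conv_fw(x, W, 3L, 2L, 1L)$y * R)
  eps <- 1e-5
  Wp <- W; Wp[13] <- Wp[13] + eps; Wm <- W; Wm[13] <- Wm[13] - eps
  expect_equal(bk$dW[13], (loss_conv(x, Wp) - loss_conv(x, Wm)) / (2 * eps),
               tolerance = 1e-6)
  xp <- x; xp[100] <- xp[100] + eps; xm <- x; xm[100] <- xm[100] - eps
  expect_equal(bk$dx[100], (loss_conv(xp, W) - loss_conv(xm, W)) / (2 * eps),
               tolerance = 1e-6)

  # batch normalization in training mode: dx and dgamma
  g <- runif(3, 0.5, 1.5); b <- rnorm(3)
  rm0 <- rep(0, 3); rv0 <- rep(1, 3)
  xb <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  ob <- skinaudit:::.bn_fw(xb, g, b, rm0, rv0, TRUE)
  Rb <- array(rnorm(length(ob$y)), dim(ob$y))
  bb <- skinaudit:::.bn_bw(Rb, ob$cache)
  loss_bn <- function(x, g) {
    sum(skinaudit:::.bn_fw(x, g, b, rm0, rv0, TRUE)$y * Rb)
  }
  xq <- xb; xq[50] <- xq[50] + eps; xr <- xb; xr[50] <- xr[50] - eps
  expect_equal(bb$dx[50], (loss_bn(xq, g) - loss_bn(xr, g)) / (2 * eps),
               tolerance = 1e-6)
  gp <- g; gp[2] <- gp[2] + eps; gm <- g; gm[2] <- gm[2] - eps
  expect_equal(bb$dgamma[2], (loss_bn(xb, gp) - loss_bn(xb, gm)) / (2 * eps),
               tolerance = 1e-6)
})

test_that("a downsampling residual block matches finite differences", {
  set.seed(2)
  P <- list()
  P[["t.conv1.W"]] <- matrix(rnorm(72 * 16, 0, 0.2), 72, 16)
  P[["t.bn1.gamma"]] <- runif(16, 0.5, 1.5); P[["t.bn1.beta"]] <- rnorm(16, 0, 0.1)
  P[["t.conv2.W"]] <- matrix(rnorm(144 * 16, 0, 0.2), 144, 16)
  P[["t.bn2.gamma"]] <- runif(16, 0.5, 1.5); P[["t.bn2.beta"]] <- rnorm(16, 0, 0.1)
  P[["t.down.W"]] <- matrix(rnorm(8 * 16, 0, 0.3), 8, 16)
  P[["t.downbn.gamma"]] <- runif(16, 0.5, 1.5); P[["t.downbn.beta"]] <- rnorm(16, 0, 0.1)
  S <- list()
  for (nm in c("bn1", "bn2", "downbn")) {
    S[[paste0("t.", nm, ".rmean")]] <- rep(0, 16)
    S[[paste0("t.", nm, ".rvar")]] <- rep(1, 16)
  }
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  out <- skinaudit:::.block_fw(x, P, S, "t", 2L, TRUE)
  R <- array(rnorm(length(out$y)), dim(out$y))
  bk <- skinaudit:::.block_bw(R, P, "t", out$cache, list())
  loss_at <- function(P, x) {
    sum(skinaudit:::.block_fw(x, P, S, "t", 2L, TRUE)$y * R)
  }
  eps <- 1e-5
  for (pr in list(c("t.conv1.W", 7), c("t.bn1.gamma", 3), c("t.conv2.W", 40),
                  c("t.down.W", 5), c("t.downbn.beta", 9))) {
    nm <- pr[1]; i <- as.integer(pr[2])
    Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
    Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
    expect_equal(bk$grads[[nm]][i],
                 (loss_at(Pp, x) - loss_at(Pm, x)) / (2 * eps),
                 tolerance = 1e-5, label = paste("grad of", nm))
  }
  xp <- x; xp[123] <- xp[123] + eps; xm <- x; xm[123] <- xm[123] - eps
  expect_equal(bk$dx[123], (loss_at(P, xp) - loss_at(P, xm)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(21)
  m <- build_cnn(2, input_size = 32, seed = 22)
  x <- array(rnorm(32 * 32 * 3 * 4), dim = c(32, 32, 3, 4))
  yidx <- c(1L, 2L, 2L, 1L)
  wts <- c(1, 2)
  loss_at <- function(model) {
    fw <- skinaudit:::.cnn_forward(model, x, train = TRUE)
    skinaudit:::.weighted_ce(fw$logits, yidx, wts)$loss
  }
  fw <- skinaudit:::.cnn_forward(m, x, train = TRUE)
  ce <- skinaudit:::.weighted_ce(fw$logits, yidx, wts)
  grads <- skinaudit:::.cnn_backward(m, ce$dlogits, fw$caches)

  probes <- list(c("conv1.W", 5), c("bn1.gamma", 3), c("s1b1.conv2.W", 101),
                 c("s2b1.down.W", 17), c("s3b2.bn2.beta", 12),
                 c("fc.W", 7), c("fc.b", 2))
  eps <- 1e-5
  for (pr in probes) {
    nm <- pr[1]; i <- as.integer(pr[2])
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    ana <- grads[[nm]][i]
    expect_lt(abs(ana - num) / max(abs(num), 1e-4), 1e-3,
              label = sprintf("relative gradient error of %s[%d]", nm, i))
  }
})

test_that("fine-tuning decreases the loss and is seed-deterministic", {
  spec <- synthetic_spec(seed = 41, n_images = 24, skin_prop = 1,
                         tone_mix = 0.5, img_size = c(48, 48))
  ds <- gen_dataset(spec)
  imgs <- lapply(seq_len(24), function(i) {
    ds$images[[i]] * as.numeric(rep(ds$masks[[i]], 3))
  })
  m0 <- build_cnn(2, input_size = 32, seed = 42)
  m1 <- finetune_cnn(m0, imgs, ds$tone, epochs = 3, lr = 0.01,
                     batch_size = 8, seed = 43)
  expect_lt(m1$history[3], m1$history[1])

  m2 <- finetune_cnn(m0, imgs, ds$tone, epochs = 3, lr = 0.01,
                     batch_size = 8, seed = 43)
  expect_identical(m1$params, m2$params)

  # equal class weights reproduce the unweighted loss exactly
  m3 <- finetune_cnn(m0, imgs, ds$tone, epochs = 1, lr = 0.01,
                     batch_size = 8, class_weights = c(1, 1), seed = 44)
  m4 <- finetune_cnn(m0, imgs, ds$tone, epochs = 1, lr = 0.01,
                     batch_size = 8, seed = 44)
  expect_equal(m3$history, m4$history, tolerance = 1e-6)

  # duplicate inputs get identical scores
  p <- predict_cnn(m1, imgs[c(1, 1)])
  expect_identical(p[1], p[2])
  expect_error(finetune_cnn(m0, list(), factor(character(0))), "empty")
})
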