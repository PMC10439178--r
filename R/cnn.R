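# An 18-layer residual convolutional network with a configurable
# classification head, implemented natively: convolution as im2col + BLAS
# matrix multiplication, batch normalization, max/global-average pooling,
# and momentum SGD with per-epoch linear learning-rate decay. Feature maps
# are stored as (H, W, C, N) arrays. Index matrices for the im2col gather
# are cached per shape.

.cnn_env <- new.env(parent = emptyenv())

.im2col_info <- function(H, W, C, N, k, stride, pad) {
  key <- paste(H, W, C, N, k, stride, pad, sep = "_")
  hit <- .cnn_env[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  oh <- (Hp - k) %/% stride + 1L
  ow <- (Wp - k) %/% stride + 1L
  a <- rep(seq_len(k), times = k * C)
  b <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  rowterm <- a + Hp * (b - 1L) + Hp * Wp * (cc - 1L)
  i <- rep(seq_len(oh), times = ow)
  j <- rep(seq_len(ow), each = oh)
  colterm <- (i - 1L) * stride + Hp * (j - 1L) * stride
  idx1 <- outer(rowterm, colterm, "+")
  nr <- k * k * C
  idx <- matrix(rep(as.vector(idx1), N), nrow = nr)
  if (N > 1) {
    idx <- idx + rep((0:(N - 1)) * (Hp * Wp * C), each = nr * oh * ow)
  }
  info <- list(idx = idx, Hp = Hp, Wp = Wp, oh = oh, ow = ow,
               k = k, stride = stride, pad = pad,
               H = H, W = W, C = C, N = N)
  .cnn_env[[key]] <- info
  info
}

.pad4 <- function(x, pad, fill = 0) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(fill, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

.conv_fw <- function(x, W, k, stride, pad) {
  d <- dim(x)
  info <- .im2col_info(d[1], d[2], d[3], d[4], k, stride, pad)
  xp <- .pad4(x, pad)
  # index with the flattened vector: a matrix subscript whose column count
  # happens to equal the array rank would be read as coordinates
  Xcol <- xp[as.vector(info$idx)]
  dim(Xcol) <- dim(info$idx)
  Cout <- ncol(W)
  Y <- crossprod(W, Xcol)
  y <- aperm(array(Y, dim = c(Cout, info$oh, info$ow, d[4])), c(2, 3, 1, 4))
  list(y = y, cache = list(Xcol = Xcol, info = info, dimx = d))
}

.conv_bw <- function(dy, W, cache) {
  info <- cache$info
  d <- cache$dimx
  Cout <- ncol(W)
  Dy <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = Cout)
  dW <- tcrossprod(cache$Xcol, Dy)
  dXcol <- W %*% Dy
  dxp <- numeric(info$Hp * info$Wp * d[3] * d[4])
  idx <- info$idx
  for (r in seq_len(nrow(idx))) {
    ii <- idx[r, ]
    dxp[ii] <- dxp[ii] + dXcol[r, ]
  }
  dim(dxp) <- c(info$Hp, info$Wp, d[3], d[4])
  dx <- if (info$pad > 0) {
    dxp[info$pad + seq_len(d[1]), info$pad + seq_len(d[2]), , , drop = FALSE]
  } else {
    dxp
  }
  list(dx = dx, dW = dW)
}

.chan_stat <- function(v, HW, C, N) {
  # per-channel sums of an (H, W, C, N) array given as a vector
  s <- colSums(matrix(v, nrow = HW))
  rowSums(matrix(s, nrow = C))
}

.bn_fw <- function(x, gamma, beta, rmean, rvar, train,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  HW <- d[1] * d[2]
  C <- d[3]
  M <- HW * d[4]
  if (train) {
    mu <- .chan_stat(x, HW, C, d[4]) / M
    ex2 <- .chan_stat(x * x, HW, C, d[4]) / M
    va <- pmax(ex2 - mu^2, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * va * M / max(M - 1, 1)
  } else {
    mu <- rmean
    va <- rvar
  }
  invstd <- 1 / sqrt(va + eps)
  mu_f <- rep(rep(mu, each = HW), times = d[4])
  is_f <- rep(rep(invstd, each = HW), times = d[4])
  g_f <- rep(rep(gamma, each = HW), times = d[4])
  b_f <- rep(rep(beta, each = HW), times = d[4])
  xhat <- (as.vector(x) - mu_f) * is_f
  y <- array(xhat * g_f + b_f, dim = d)
  list(y = y, rmean = rmean, rvar = rvar,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d))
}

.bn_bw <- function(dy, cache) {
  d <- cache$d
  HW <- d[1] * d[2]
  C <- d[3]
  M <- HW * d[4]
  dyv <- as.vector(dy)
  xhat <- cache$xhat
  dbeta <- .chan_stat(dyv, HW, C, d[4])
  dgamma <- .chan_stat(dyv * xhat, HW, C, d[4])
  g_is <- cache$gamma * cache$invstd
  gi_f <- rep(rep(g_is, each = HW), times = d[4])
  db_f <- rep(rep(dbeta / M, each = HW), times = d[4])
  dg_f <- rep(rep(dgamma / M, each = HW), times = d[4])
  dx <- array(gi_f * (dyv - db_f - xhat * dg_f), dim = d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.relu_fw <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, cache = mask)
}

.relu_bw <- function(dy, mask) {
  dy[!mask] <- 0
  dy
}

.maxpool_fw <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  nmap <- d[3] * d[4]
  info <- .im2col_info(d[1], d[2], 1L, nmap, k, stride, pad)
  xp <- .pad4(x, pad, fill = -Inf)
  X <- xp[as.vector(info$idx)]
  dim(X) <- dim(info$idx)
  mx <- X[1, ]
  wh <- rep(1L, length(mx))
  for (r in 2:nrow(X)) {
    sel <- X[r, ] > mx
    mx[sel] <- X[r, sel]
    wh[sel] <- r
  }
  y <- array(mx, dim = c(info$oh, info$ow, d[3], d[4]))
  list(y = y, cache = list(info = info, wh = wh, dimx = d))
}

.maxpool_bw <- function(dy, cache) {
  info <- cache$info
  d <- cache$dimx
  dxp <- numeric(info$Hp * info$Wp * d[3] * d[4])
  dyv <- as.vector(dy)
  idx <- info$idx
  for (r in seq_len(nrow(idx))) {
    sel <- cache$wh == r
    if (!any(sel)) next
    ii <- idx[r, sel]
    dxp[ii] <- dxp[ii] + dyv[sel]
  }
  dim(dxp) <- c(info$Hp, info$Wp, d[3], d[4])
  if (info$pad > 0) {
    dxp[info$pad + seq_len(d[1]), info$pad + seq_len(d[2]), , ,
        drop = FALSE]
  } else {
    dxp
  }
}

# ---- parameter construction ------------------------------------------------

.he_conv <- function(k, cin, cout) {
  matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         nrow = k * k * cin, ncol = cout)
}

.bn_params <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C))
}

.bn_state <- function(C) {
  list(rmean = rep(0, C), rvar = rep(1, C))
}

.RESNET_PLANES <- c(64L, 128L, 256L, 512L)
.RESNET_STRIDES <- c(1L, 2L, 2L, 2L)

#' Build the 18-layer residual network
#'
#' Standard 18-layer residual topology: a 7x7 stride-2 stem convolution
#' with batch norm and 3x3 stride-2 max pooling, four stages of two basic
#' blocks (64, 128, 256, 512 channels; stages 2-4 downsample by stride-2
#' convolutions with 1x1 projection shortcuts), global average pooling and
#' a fully connected head with `num_classes` outputs. Weights are
#' He-initialized from `seed`; a compatible pretrained backbone can be
#' loaded with [load_cnn_weights()] when a weights file is available.
#'
#' @param num_classes Number of output classes (>= 2).
#' @param input_size Square input side in pixels (default 224). The
#'   parameter count is independent of this choice.
#' @param seed RNG seed for the initialization.
#' @return A `cnn_model` with flat parameter/state lists; the trainable
#'   parameter count is reported by [n_parameters()] (11,689,512 for a
#'   1000-class head).
#' @export
build_cnn <- function(num_classes = 2, input_size = 224, seed = 1) {
  if (!is.numeric(num_classes) || num_classes < 2) {
    stop("num_classes must be >= 2")
  }
  num_classes <- as.integer(num_classes)
  set.seed(seed)
  P <- list()
  S <- list()
  P[["conv1.W"]] <- .he_conv(7L, 3L, 64L)
  bp <- .bn_params(64L); bs <- .bn_state(64L)
  P[["bn1.gamma"]] <- bp$gamma; P[["bn1.beta"]] <- bp$beta
  S[["bn1.rmean"]] <- bs$rmean; S[["bn1.rvar"]] <- bs$rvar
  inplanes <- 64L
  for (s in 1:4) {
    planes <- .RESNET_PLANES[s]
    for (b in 1:2) {
      pre <- sprintf("s%db%d", s, b)
      stride <- if (b == 1) .RESNET_STRIDES[s] else 1L
      P[[paste0(pre, ".conv1.W")]] <- .he_conv(3L, inplanes, planes)
      bp <- .bn_params(planes); bs <- .bn_state(planes)
      P[[paste0(pre, ".bn1.gamma")]] <- bp$gamma
      P[[paste0(pre, ".bn1.beta")]] <- bp$beta
      S[[paste0(pre, ".bn1.rmean")]] <- bs$rmean
      S[[paste0(pre, ".bn1.rvar")]] <- bs$rvar
      P[[paste0(pre, ".conv2.W")]] <- .he_conv(3L, planes, planes)
      bp <- .bn_params(planes); bs <- .bn_state(planes)
      P[[paste0(pre, ".bn2.gamma")]] <- bp$gamma
      P[[paste0(pre, ".bn2.beta")]] <- bp$beta
      S[[paste0(pre, ".bn2.rmean")]] <- bs$rmean
      S[[paste0(pre, ".bn2.rvar")]] <- bs$rvar
      if (stride != 1L || inplanes != planes) {
        P[[paste0(pre, ".down.W")]] <- .he_conv(1L, inplanes, planes)
        bp <- .bn_params(planes); bs <- .bn_state(planes)
        P[[paste0(pre, ".downbn.gamma")]] <- bp$gamma
        P[[paste0(pre, ".downbn.beta")]] <- bp$beta
        S[[paste0(pre, ".downbn.rmean")]] <- bs$rmean
        S[[paste0(pre, ".downbn.rvar")]] <- bs$rvar
      }
      inplanes <- planes
    }
  }
  P[["fc.W"]] <- matrix(stats::rnorm(512L * num_classes, 0, 0.01),
                        nrow = 512L)
  P[["fc.b"]] <- rep(0, num_classes)
  structure(
    list(params = P, state = S, num_classes = num_classes,
         input_size = as.integer(input_size),
         classes = NULL, history = NULL, seed = seed),
    class = "cnn_model"
  )
}

#' Count trainable parameters of a CNN
#'
#' Convolution weights, batch-norm scale/shift and the fully connected
#' head; batch-norm running statistics are state, not parameters.
#'
#' @param model A `cnn_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Load pretrained backbone weights from an RDS file
#'
#' The file must contain a named list matching the model's parameter
#' shapes; the classification head (`fc.*`) may be omitted (kept as
#' initialized).
#'
#' @param model A `cnn_model`.
#' @param path RDS file with a named parameter list.
#' @return The model with replaced weights.
#' @export
load_cnn_weights <- function(model, path) {
  w <- readRDS(path)
  for (nm in names(w)) {
    if (!nm %in% names(model$params)) {
      stop(sprintf("weights load error: unknown parameter '%s'", nm))
    }
    if (length(w[[nm]]) != length(model$params[[nm]])) {
      stop(sprintf("weights load error: '%s' has %d values, expected %d",
                   nm, length(w[[nm]]), length(model$params[[nm]])))
    }
    dim(w[[nm]]) <- dim(model$params[[nm]])
    model$params[[nm]] <- w[[nm]]
  }
  model
}

# ---- forward / backward ----------------------------------------------------

.block_fw <- function(x, P, S, pre, stride, train) {
  caches <- list()
  cv1 <- .conv_fw(x, P[[paste0(pre, ".conv1.W")]], 3L, stride, 1L)
  caches$conv1 <- cv1$cache
  bn1 <- .bn_fw(cv1$y, P[[paste0(pre, ".bn1.gamma")]],
                P[[paste0(pre, ".bn1.beta")]],
                S[[paste0(pre, ".bn1.rmean")]],
                S[[paste0(pre, ".bn1.rvar")]], train)
  S[[paste0(pre, ".bn1.rmean")]] <- bn1$rmean
  S[[paste0(pre, ".bn1.rvar")]] <- bn1$rvar
  caches$bn1 <- bn1$cache
  r1 <- .relu_fw(bn1$y)
  caches$relu1 <- r1$cache
  cv2 <- .conv_fw(r1$y, P[[paste0(pre, ".conv2.W")]], 3L, 1L, 1L)
  caches$conv2 <- cv2$cache
  bn2 <- .bn_fw(cv2$y, P[[paste0(pre, ".bn2.gamma")]],
                P[[paste0(pre, ".bn2.beta")]],
                S[[paste0(pre, ".bn2.rmean")]],
                S[[paste0(pre, ".bn2.rvar")]], train)
  S[[paste0(pre, ".bn2.rmean")]] <- bn2$rmean
  S[[paste0(pre, ".bn2.rvar")]] <- bn2$rvar
  caches$bn2 <- bn2$cache
  has_down <- !is.null(P[[paste0(pre, ".down.W")]])
  if (has_down) {
    cvd <- .conv_fw(x, P[[paste0(pre, ".down.W")]], 1L, stride, 0L)
    caches$down <- cvd$cache
    bnd <- .bn_fw(cvd$y, P[[paste0(pre, ".downbn.gamma")]],
                  P[[paste0(pre, ".downbn.beta")]],
                  S[[paste0(pre, ".downbn.rmean")]],
                  S[[paste0(pre, ".downbn.rvar")]], train)
    S[[paste0(pre, ".downbn.rmean")]] <- bnd$rmean
    S[[paste0(pre, ".downbn.rvar")]] <- bnd$rvar
    caches$downbn <- bnd$cache
    sc <- bnd$y
  } else {
    sc <- x
  }
  pre_relu <- bn2$y + sc
  r2 <- .relu_fw(pre_relu)
  caches$relu2 <- r2$cache
  caches$has_down <- has_down
  list(y = r2$y, S = S, cache = caches)
}

.block_bw <- function(dy, P, pre, cache, grads) {
  dy <- .relu_bw(dy, cache$relu2)
  dsc <- dy
  b2 <- .bn_bw(dy, cache$bn2)
  grads[[paste0(pre, ".bn2.gamma")]] <- b2$dgamma
  grads[[paste0(pre, ".bn2.beta")]] <- b2$dbeta
  c2 <- .conv_bw(b2$dx, P[[paste0(pre, ".conv2.W")]], cache$conv2)
  grads[[paste0(pre, ".conv2.W")]] <- c2$dW
  dr1 <- .relu_bw(c2$dx, cache$relu1)
  b1 <- .bn_bw(dr1, cache$bn1)
  grads[[paste0(pre, ".bn1.gamma")]] <- b1$dgamma
  grads[[paste0(pre, ".bn1.beta")]] <- b1$dbeta
  c1 <- .conv_bw(b1$dx, P[[paste0(pre, ".conv1.W")]], cache$conv1)
  grads[[paste0(pre, ".conv1.W")]] <- c1$dW
  dx <- c1$dx
  if (cache$has_down) {
    bd <- .bn_bw(dsc, cache$downbn)
    grads[[paste0(pre, ".downbn.gamma")]] <- bd$dgamma
    grads[[paste0(pre, ".downbn.beta")]] <- bd$dbeta
    cd <- .conv_bw(bd$dx, P[[paste0(pre, ".down.W")]], cache$down)
    grads[[paste0(pre, ".down.W")]] <- cd$dW
    dx <- dx + cd$dx
  } else {
    dx <- dx + dsc
  }
  list(dx = dx, grads = grads)
}

.cnn_forward <- function(model, x, train = FALSE) {
  P <- model$params
  S <- model$state
  caches <- list()
  cv <- .conv_fw(x, P[["conv1.W"]], 7L, 2L, 3L)
  caches$conv1 <- cv$cache
  bn <- .bn_fw(cv$y, P[["bn1.gamma"]], P[["bn1.beta"]],
               S[["bn1.rmean"]], S[["bn1.rvar"]], train)
  S[["bn1.rmean"]] <- bn$rmean
  S[["bn1.rvar"]] <- bn$rvar
  caches$bn1 <- bn$cache
  r <- .relu_fw(bn$y)
  caches$relu1 <- r$cache
  mp <- .maxpool_fw(r$y)
  caches$maxpool <- mp$cache
  h <- mp$y
  for (s in 1:4) {
    for (b in 1:2) {
      pre <- sprintf("s%db%d", s, b)
      stride <- if (b == 1) .RESNET_STRIDES[s] else 1L
      blk <- .block_fw(h, P, S, pre, stride, train)
      h <- blk$y
      S <- blk$S
      caches[[pre]] <- blk$cache
    }
  }
  d <- dim(h)
  feat <- matrix(colSums(matrix(h, nrow = d[1] * d[2])), nrow = d[3]) /
    (d[1] * d[2])
  caches$gap_dim <- d
  logits <- crossprod(P[["fc.W"]], feat) + P[["fc.b"]]
  caches$feat <- feat
  list(logits = logits, caches = caches, S = S)
}

.cnn_backward <- function(model, dlogits, caches) {
  P <- model$params
  grads <- list()
  grads[["fc.W"]] <- tcrossprod(caches$feat, dlogits)
  grads[["fc.b"]] <- rowSums(dlogits)
  dfeat <- P[["fc.W"]] %*% dlogits
  d <- caches$gap_dim
  dh <- array(rep(as.vector(dfeat), each = d[1] * d[2]) / (d[1] * d[2]),
              dim = d)
  for (s in 4:1) {
    for (b in 2:1) {
      pre <- sprintf("s%db%d", s, b)
      bk <- .block_bw(dh, P, pre, caches[[pre]], grads)
      dh <- bk$dx
      grads <- bk$grads
    }
  }
  dh <- .maxpool_bw(dh, caches$maxpool)
  dh <- .relu_bw(dh, caches$relu1)
  b1 <- .bn_bw(dh, caches$bn1)
  grads[["bn1.gamma"]] <- b1$dgamma
  grads[["bn1.beta"]] <- b1$dbeta
  c1 <- .conv_bw(b1$dx, P[["conv1.W"]], caches$conv1)
  grads[["conv1.W"]] <- c1$dW
  grads
}

# ---- training --------------------------------------------------------------

.prep_cnn_batch <- function(images, size) {
  n <- length(images)
  x <- array(0, dim = c(size, size, 3, n))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (!identical(dim(img)[1:2], c(size, size))) {
      img <- EBImage::resize(img, w = size, h = size)
      img <- array(pmin(pmax(img, 0), 255), dim = c(size, size, 3))
    }
    x[, , , i] <- (img / 255 - 0.5) / 0.25
  }
  x
}

.weighted_ce <- function(logits, yidx, wts) {
  K <- nrow(logits)
  n <- ncol(logits)
  mx <- apply(logits, 2, max)
  z <- sweep(logits, 2, mx)
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  wi <- wts[yidx]
  picked <- p[cbind(yidx, seq_len(n))]
  loss <- -sum(wi * log(pmax(picked, 1e-12))) / sum(wi)
  onehot <- matrix(0, K, n)
  onehot[cbind(yidx, seq_len(n))] <- 1
  dlogits <- (p - onehot) * rep(wi, each = K) / sum(wi)
  list(loss = loss, dlogits = dlogits)
}

#' Fine-tune the CNN on labeled images
#'
#' Momentum stochastic gradient descent on class-weighted cross-entropy.
#' The learning rate decays linearly from `lr` to 0 across the epochs
#' (epoch e uses lr * (1 - (e - 1) / epochs)). Fully reproducible from
#' `seed`.
#'
#' @param model A `cnn_model` from [build_cnn()].
#' @param images List of H x W x 3 pixel arrays in \[0, 255\] (masked skin
#'   images; they are resized to the network input size).
#' @param labels Class labels (factor or coercible; for tone estimation,
#'   `"I-IV"` / `"V-VI"`).
#' @param epochs Number of epochs (default 20).
#' @param lr Initial learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 32).
#' @param class_weights Per-class loss weights in `levels(labels)` order;
#'   NULL (default) weights every class 1.
#' @param momentum SGD momentum (default 0.9).
#' @param seed RNG seed for shuffling.
#' @param verbose Print per-epoch losses.
#' @return The trained model, with `$history` holding per-epoch mean loss.
#' @export
finetune_cnn <- function(model, images, labels, epochs = 20, lr = 1e-3,
                         batch_size = 32, class_weights = NULL,
                         momentum = 0.9, seed = 1, verbose = FALSE) {
  if (length(images) == 0) stop("empty dataset")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (nlevels(labels) != model$num_classes) {
    stop(sprintf("model has %d outputs but labels have %d levels",
                 model$num_classes, nlevels(labels)))
  }
  if (is.null(class_weights)) class_weights <- rep(1, nlevels(labels))
  yidx <- as.integer(labels)
  n <- length(images)
  size <- model$input_size
  x_all <- .prep_cnn_batch(images, size)
  vel <- lapply(model$params, function(p) p * 0)
  history <- numeric(epochs)
  set.seed(seed)
  for (e in seq_len(epochs)) {
    lr_e <- lr * (1 - (e - 1) / epochs)
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      bidx <- ord[start:min(start + batch_size - 1, n)]
      xb <- x_all[, , , bidx, drop = FALSE]
      fw <- .cnn_forward(model, xb, train = TRUE)
      model$state <- fw$S
      ce <- .weighted_ce(fw$logits, yidx[bidx], class_weights)
      losses <- c(losses, ce$loss)
      grads <- .cnn_backward(model, ce$dlogits, fw$caches)
      for (nm in names(model$params)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        vel[[nm]] <- momentum * vel[[nm]] + g
        model$params[[nm]] <- model$params[[nm]] - lr_e * vel[[nm]]
      }
    }
    history[e] <- mean(losses)
    if (verbose) {
      message(sprintf("epoch %d/%d lr %.2e loss %.4f",
                      e, epochs, lr_e, history[e]))
    }
  }
  model$history <- history
  model$classes <- levels(labels)
  model
}

#' Predict class probabilities with the CNN
#'
#' Runs the network in evaluation mode (batch-norm running statistics).
#'
#' @param model A trained `cnn_model`.
#' @param images List of pixel arrays.
#' @param batch_size Evaluation batch size.
#' @return For a 2-class model, the probability of the second class
#'   (FST V-VI for tone models); otherwise an n x K probability matrix.
#' @export
predict_cnn <- function(model, images, batch_size = 32) {
  n <- length(images)
  size <- model$input_size
  out <- matrix(0, n, model$num_classes)
  for (start in seq(1, n, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1, n)
    xb <- .prep_cnn_batch(images[bidx], size)
    fw <- .cnn_forward(model, xb, train = FALSE)
    z <- sweep(fw$logits, 2, apply(fw$logits, 2, max))
    ez <- exp(z)
    out[bidx, ] <- t(sweep(ez, 2, colSums(ez), "/"))
  }
  if (model$num_classes == 2) out[, 2] else out
}
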