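# Shared fixtures and independent per-pixel reference implementations.
# The oracles below deliberately use scalar loops and textbook formulas so
# they stay independent of the package's vectorized implementations.

random_patch <- function(h, w, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))
}

uniform_patch <- function(rgb, h = 8, w = 8) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  px
}

# scalar sRGB -> CIELAB, one pixel at a time (D65, 2 degree observer)
naive_lab_pixel <- function(rgb) {
  v <- rgb / 255
  lin <- vapply(v, function(u) {
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }, numeric(1))
  X <- 0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3]
  Y <- 0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3]
  Z <- 0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3]
  f <- function(t) {
    if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  }
  fx <- f(X / 0.95047); fy <- f(Y / 1); fz <- f(Z / 1.08883)
  c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

naive_lab_stats <- function(patch) {
  h <- dim(patch)[1]; w <- dim(patch)[2]
  labs <- matrix(0, h * w, 3)
  k <- 0
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      k <- k + 1
      labs[k, ] <- naive_lab_pixel(patch[r, c, ])
    }
  }
  mu <- colMeans(labs)
  sd_pop <- sqrt(colMeans((labs - matrix(mu, h * w, 3, byrow = TRUE))^2))
  c(mu, sd_pop)
}

naive_intensity <- function(patch) {
  0.299 * patch[, , 1] + 0.587 * patch[, , 2] + 0.114 * patch[, , 3]
}

naive_gradients <- function(patch) {
  I <- naive_intensity(patch)
  h <- nrow(I); w <- ncol(I)
  gx <- matrix(0, h - 2, w - 2)
  gy <- matrix(0, h - 2, w - 2)
  for (r in 2:(h - 1)) {
    for (c in 2:(w - 1)) {
      gx[r - 1, c - 1] <- I[r, c + 1] - I[r, c - 1]
      gy[r - 1, c - 1] <- I[r + 1, c] - I[r - 1, c]
    }
  }
  list(gx = gx, gy = gy)
}

naive_hog <- function(patch, bins = 32) {
  g <- naive_gradients(patch)
  centers <- -pi / 2 + (pi / bins) * (seq_len(bins) - 0.5)
  hist <- numeric(bins)
  for (i in seq_along(g$gx)) {
    gx <- g$gx[i]; gy <- g$gy[i]
    m <- sqrt(gx^2 + gy^2)
    if (m == 0) next
    theta <- if (gx == 0) pi / 2 else atan(gy / gx)
    b <- which.min(abs(centers - theta))  # first minimum = lower index
    hist[b] <- hist[b] + m
  }
  if (sum(hist) > 0) hist <- hist / sum(hist)
  hist
}

# two well-separated Gaussian clouds in 38 dimensions
separable_features <- function(n = 200, seed = 1, gap = 6) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  X <- matrix(rnorm(n * 38), n, 38)
  X[y, 1:4] <- X[y, 1:4] + gap
  list(X = X, y = y)
}

solid_ellipse_fixture <- function(h = 100, w = 100,
                                  skin = c(200, 150, 125),
                                  bg = c(80, 110, 200)) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ell <- ((xx - w / 2) / (0.3 * w))^2 + ((yy - h / 2) / (0.22 * h))^2 <= 1
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    pl <- matrix(bg[ch], h, w)
    pl[ell] <- skin[ch]
    px[, , ch] <- pl
  }
  list(pixels = px, mask = ell)
}
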