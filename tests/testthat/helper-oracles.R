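# Independent brute-force oracles. These deliberately use naive per-pixel /
# per-assignment loops and share no code with the package internals.

# naive O(N * k^2) 2-D convolution with edge-replication padding
oracle_conv2 <- function(img, kernel) {
  h <- nrow(img)
  w <- ncol(img)
  r <- (nrow(kernel) - 1) / 2
  out <- matrix(0, h, w)
  clamp <- function(v, lo, hi) pmin(hi, pmax(lo, v))
  for (i in 1:h) for (j in 1:w) {
    acc <- 0
    for (a in -r:r) for (b in -r:r)
      acc <- acc + kernel[a + r + 1, b + r + 1] *
        img[clamp(i + a, 1, h), clamp(j + b, 1, w)]
    out[i, j] <- acc
  }
  out
}

# rasterize disks over every pixel (0-based centers, same inclusion rule
# as documented for the renderer: squared distance <= r^2)
oracle_disk_pixels <- function(objects, h, w) {
  inside <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    x <- j - 1
    y <- i - 1
    for (ob in objects)
      if ((x - ob$cx)^2 + (y - ob$cy)^2 <= ob$r^2) inside[i, j] <- TRUE
  }
  inside
}

# direct voting over all edge pixels, one vote per angle bin
oracle_hough_accumulator <- function(edges, theta_steps) {
  h <- nrow(edges)
  w <- ncol(edges)
  d_max <- ceiling(sqrt(h^2 + w^2))
  thetas <- (seq_len(theta_steps) - 1) * pi / theta_steps
  acc <- matrix(0L, 2 * d_max + 1, theta_steps)
  for (i in 1:h) for (j in 1:w) {
    if (!edges[i, j]) next
    x <- j - 1
    y <- i - 1
    for (t in seq_len(theta_steps)) {
      rho <- x * cos(thetas[t]) + y * sin(thetas[t])
      bin <- floor(rho + 0.5) + d_max + 1
      acc[bin, t] <- acc[bin, t] + 1L
    }
  }
  acc
}

# --- direct-summation metric oracles (population statistics) ---------------

oracle_eligible <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  elig <- matrix(FALSE, h, w)
  for (i in 2:(h - 1)) for (j in 2:(w - 1))
    elig[i, j] <- all(mask[(i - 1):(i + 1), (j - 1):(j + 1)])
  elig
}

oracle_sharpness <- function(img, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  elig <- oracle_eligible(mask)
  vals <- c()
  for (i in 1:nrow(img)) for (j in 1:ncol(img)) {
    if (!elig[i, j]) next
    lap <- img[i - 1, j] + img[i + 1, j] + img[i, j - 1] + img[i, j + 1] -
      4 * img[i, j]
    vals <- c(vals, lap)
  }
  mean((vals - mean(vals))^2)
}

oracle_entropy <- function(img, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  v <- img[mask]
  hsum <- 0
  for (lev in 0:255) {
    p <- sum(v == lev) / length(v)
    if (p > 0) hsum <- hsum - p * log2(p)
  }
  hsum
}

oracle_contrast <- function(img, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  v <- img[mask]
  sqrt(sum((v - mean(v))^2) / length(v))
}

oracle_snr <- function(img, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  v <- img[mask]
  mean(v) / sqrt(sum((v - mean(v))^2) / length(v))
}

oracle_edge_intensity <- function(img, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  elig <- oracle_eligible(mask)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx, x = columns
  ky <- t(kx)                                               # d/dy, y = rows
  m <- img / 255
  vals <- c()
  for (i in 1:nrow(img)) for (j in 1:ncol(img)) {
    if (!elig[i, j]) next
    win <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    gx <- sum(win * kx)
    gy <- sum(win * ky)
    vals <- c(vals, sqrt(gx^2 + gy^2))
  }
  mean(vals) / (4 * sqrt(2))
}

# --- exact signed-rank oracle: literal enumeration of all 2^n assignments --

oracle_wilcoxon <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ts <- as.vector(signs %*% r)
  p <- (sum(ts <= min(w_pos, w_neg) + 1e-9) +
          sum(ts >= max(w_pos, w_neg) - 1e-9)) / 2^n
  min(1, p)
}

# small seeded random test image
rand_gray <- function(h, w, seed, levels = 0:255) {
  withr::with_seed(seed, matrix(sample(levels, h * w, replace = TRUE), h, w))
}

# seeded random validity mask with a guaranteed fully-valid 3x3 block
rand_mask <- function(h, w, seed, p_valid = 0.85) {
  withr::with_seed(seed, {
    m <- matrix(sample(c(TRUE, FALSE), h * w, replace = TRUE,
                       prob = c(p_valid, 1 - p_valid)), h, w)
    i <- sample(2:(h - 3), 1)
    j <- sample(2:(w - 3), 1)
    m[i:(i + 2), j:(j + 2)] <- TRUE
    m
  })
}
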