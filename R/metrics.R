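#' @name quality-metrics
#' @rdname quality-metrics
#' @title Five no-reference image quality metrics
#'
#' @description
#' The per-image quality scores used to compare staining protocols, all
#' computed over the valid-pixel region of an 8-bit grayscale image:
#'
#' * `laplacian_sharpness()` - population variance of the discrete Laplacian
#'   (4-neighbour kernel: centre -4, N/S/E/W +1) on raw 0-255 intensities;
#'   high values indicate concentrated fine detail.
#' * `shannon_entropy()` - Shannon entropy, in bits, of the 256-bin intensity
#'   histogram of valid pixels (`0 * log 0` taken as 0); at most 8 bits.
#' * `global_contrast()` - population standard deviation (divide by N) of
#'   valid-pixel intensities on the 0-255 scale; at most 127.5.
#' * `snr()` - mean valid-pixel intensity divided by its population standard
#'   deviation; undefined (an error) for constant images.
#' * `edge_intensity()` - mean Sobel gradient magnitude on intensities
#'   rescaled to `[0, 1]`, divided by `4 * sqrt(2)` (the largest magnitude the
#'   3x3 Sobel pair can produce) so values are a dimensionless fraction of a
#'   full-contrast edge.
#'
#' Metrics built on a 3x3 stencil (sharpness, edge intensity) are evaluated
#' only at pixels whose full 3x3 neighbourhood is valid and interior; no
#' padding is used, so masked-out markers cannot leak phantom edges into the
#' scores.
#'
#' @param image integer/numeric matrix of 8-bit intensities in `[0, 255]`.
#' @param mask optional logical validity matrix of the same shape (`TRUE` =
#'   valid); `NULL` means all pixels are valid.
#' @return a single numeric value; `metric_vector()` returns a named numeric
#'   vector with elements `sharpness`, `entropy`, `contrast`, `snr`,
#'   `edge_intensity`.
#' @examples
#' img <- matrix(c(0, 255), 16, 16)
#' shannon_entropy(img)   # 1 bit: two equiprobable levels
#' global_contrast(img)   # 127.5
#' snr(img)               # 1.0
NULL

# pixels whose full 3x3 neighbourhood is valid and inside the frame
eligible_3x3 <- function(mask) {
  elig <- mask
  for (di in -1:1) for (dj in -1:1)
    if (di != 0L || dj != 0L)
      elig <- elig & shift_mat(mask, di, dj, FALSE)
  elig[c(1, nrow(mask)), ] <- FALSE
  elig[, c(1, ncol(mask))] <- FALSE
  elig
}

pop_var <- function(x) {
  mu <- mean(x)
  mean((x - mu)^2)
}

#' @rdname quality-metrics
#' @export
laplacian_sharpness <- function(image, mask = NULL) {
  assert_gray_image(image)
  assert_mask(mask, image)
  if (is.null(mask)) mask <- full_mask(image)
  elig <- eligible_3x3(mask)
  if (!any(elig))
    stop("sharpness: no pixel has a fully valid 3x3 neighbourhood")
  m <- image + 0
  lap <- shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
    shift_mat(m, 0, 1) + shift_mat(m, 0, -1) - 4 * m
  pop_var(lap[elig])
}

#' @rdname quality-metrics
#' @export
shannon_entropy <- function(image, mask = NULL) {
  assert_gray_image(image)
  assert_mask(mask, image)
  if (is.null(mask)) mask <- full_mask(image)
  if (!any(mask)) stop("entropy: empty mask")
  counts <- tabulate(as.integer(image[mask]) + 1L, nbins = 256L)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' @rdname quality-metrics
#' @export
global_contrast <- function(image, mask = NULL) {
  assert_gray_image(image)
  assert_mask(mask, image)
  if (is.null(mask)) mask <- full_mask(image)
  if (!any(mask)) stop("contrast: empty mask")
  sqrt(pop_var(image[mask]))
}

#' @rdname quality-metrics
#' @export
snr <- function(image, mask = NULL) {
  assert_gray_image(image)
  assert_mask(mask, image)
  if (is.null(mask)) mask <- full_mask(image)
  if (!any(mask)) stop("snr: empty mask")
  v <- image[mask]
  sigma <- sqrt(pop_var(v))
  if (sigma == 0)
    stop("snr: undefined for a constant image (zero intensity variance)")
  mean(v) / sigma
}

#' @rdname quality-metrics
#' @export
edge_intensity <- function(image, mask = NULL) {
  assert_gray_image(image)
  assert_mask(mask, image)
  if (is.null(mask)) mask <- full_mask(image)
  elig <- eligible_3x3(mask)
  if (!any(elig))
    stop("edge_intensity: no pixel has a fully valid 3x3 neighbourhood")
  g <- sobel_gradients(image / 255)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mean(mag[elig]) / (4 * sqrt(2))
}

#' @rdname quality-metrics
#' @export
metric_vector <- function(image, mask = NULL) {
  c(sharpness = laplacian_sharpness(image, mask),
    entropy = shannon_entropy(image, mask),
    contrast = global_contrast(image, mask),
    snr = snr(image, mask),
    edge_intensity = edge_intensity(image, mask))
}
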