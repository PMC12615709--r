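#' Convert a raster to 8-bit grayscale
#'
#' Single-channel rasters pass through unchanged; 3-channel rasters are
#' reduced with the fixed luminance weights `0.299 R + 0.587 G + 0.114 B` and
#' rounded to the nearest integer (halves away from zero).
#'
#' @param raster an `h x w` matrix or an `h x w x c` array (`c` = 1 or 3) of
#'   integer samples in `[0, 255]`.
#' @return an integer matrix of 8-bit intensities.
#' @export
to_grayscale <- function(raster) {
  if (is.matrix(raster)) {
    assert_gray_image(raster, "raster")
    return(raster)
  }
  if (!is.array(raster) || length(dim(raster)) != 3L)
    stop("raster must be a matrix or a 3-D array")
  nc <- dim(raster)[3]
  if (nc == 1L) return(to_grayscale(raster[, , 1]))
  if (nc != 3L) stop("unsupported channel count: ", nc)
  g <- 0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
  out <- matrix(as.integer(floor(g + 0.5)), dim(raster)[1], dim(raster)[2])
  assert_gray_image(out, "raster")
  out
}

# Sobel gradients (x: along columns, y: along rows) on the given intensity
# scale; border pixels are returned as 0 and must be excluded by the caller.
sobel_gradients <- function(m) {
  nw <- shift_mat(m, 1, 1)
  n_ <- shift_mat(m, 1, 0)
  ne <- shift_mat(m, 1, -1)
  w_ <- shift_mat(m, 0, 1)
  e_ <- shift_mat(m, 0, -1)
  sw <- shift_mat(m, -1, 1)
  s_ <- shift_mat(m, -1, 0)
  se <- shift_mat(m, -1, -1)
  gx <- (ne + 2 * e_ + se) - (nw + 2 * w_ + sw)
  gy <- (sw + 2 * s_ + se) - (nw + 2 * n_ + ne)
  h <- nrow(m)
  w <- ncol(m)
  gx[c(1, h), ] <- 0
  gx[, c(1, w)] <- 0
  gy[c(1, h), ] <- 0
  gy[, c(1, w)] <- 0
  list(gx = gx, gy = gy)
}

dilate3x3 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1)
    if (di != 0L || dj != 0L)
      out <- out | shift_mat(m, di, dj, FALSE)
  out
}

# gradient-direction non-maximum suppression (4 quantized directions):
# keep a pixel only if its magnitude is not clearly exceeded by either
# neighbour along the gradient direction, thinning blurred ramps to narrow
# ridges. Neighbours within 5% count as a plateau tie and are kept, so the
# ridge of a sharp straight edge survives in full even when pixel noise
# makes its two flanking rows alternate as the per-pixel maximum.
nonmax_suppress <- function(mag, gx, gy, tol = 0.05) {
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  nb <- function(di, dj) shift_mat(mag, -di, -dj)  # nb[r,c] = mag[r+di,c+dj]
  pairs <- list(list(nb(0, 1), nb(0, -1)),    # gradient ~ horizontal
                list(nb(1, 1), nb(-1, -1)),   # ~ 45 degrees
                list(nb(1, 0), nb(-1, 0)),    # ~ vertical
                list(nb(1, -1), nb(-1, 1)))   # ~ 135 degrees
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    sel <- sector == s
    keep[sel] <- mag[sel] >= (1 - tol) * pairs[[s + 1]][[1]][sel] &
      mag[sel] >= (1 - tol) * pairs[[s + 1]][[2]][sel]
  }
  keep
}

#' Gradient-magnitude edge map with hysteresis
#'
#' Marks edge pixels from the Sobel gradient magnitude: the magnitude ridge is
#' first thinned by gradient-direction non-maximum suppression (defocused
#' boundaries otherwise produce multi-pixel-wide bands that corrupt the Hough
#' vote counts), then hysteresis thresholding keeps ridge pixels at or above
#' `high_fraction * max(magnitude)` plus the 8-connected ridge pixels at or
#' above `low_fraction * max(magnitude)` reachable from them. A constant
#' image yields an empty edge map.
#'
#' @param image 8-bit grayscale matrix.
#' @param low_fraction,high_fraction hysteresis thresholds as fractions of the
#'   maximum gradient magnitude, `0 <= low <= high <= 1`.
#' @return a logical matrix, `TRUE` at edge pixels.
#' @seealso [hough_lines()]
#' @export
edge_map <- function(image, low_fraction = 0.1, high_fraction = 0.3) {
  assert_gray_image(image)
  if (low_fraction < 0 || low_fraction > high_fraction || high_fraction > 1)
    stop("need 0 <= low_fraction <= high_fraction <= 1")
  g <- sobel_gradients(image + 0)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  ridge <- nonmax_suppress(mag, g$gx, g$gy)
  strong <- ridge & mag >= high_fraction * mx & mag > 0
  weak <- ridge & mag >= low_fraction * mx & mag > 0
  keep <- strong
  repeat {
    grown <- keep | (weak & dilate3x3(keep))
    if (identical(grown, keep)) break
    keep <- grown
  }
  keep
}

#' Hough accumulator for straight lines
#'
#' Builds the full voting accumulator over the line normal form
#' `x*cos(theta) + y*sin(theta) = rho` (origin at the top-left pixel, 0-based
#' coordinates, `x` along columns): every edge pixel casts one vote per angle
#' into the bin of its rounded `rho`. Resolution is 1 pixel in `rho` and
#' `pi / theta_steps` in `theta`.
#'
#' @param edges logical edge matrix, e.g. from [edge_map()].
#' @param theta_steps number of angle bins over `[0, pi)` (>= 90).
#' @return a list with the integer accumulator matrix `votes`
#'   (`length(rhos)` x `theta_steps`), the bin centres `rhos` and `thetas`.
#' @seealso [hough_lines()]
#' @export
hough_accumulator <- function(edges, theta_steps = 180L) {
  stopifnot(is.matrix(edges), is.logical(edges))
  theta_steps <- as.integer(theta_steps)
  if (theta_steps < 90L) stop("theta_steps must be >= 90")
  h <- nrow(edges)
  w <- ncol(edges)
  d_max <- as.integer(ceiling(sqrt(h^2 + w^2)))
  rhos <- (-d_max):d_max
  thetas <- (seq_len(theta_steps) - 1L) * pi / theta_steps
  acc <- matrix(0L, length(rhos), theta_steps)
  idx <- which(edges, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    x <- idx[, 2] - 1
    y <- idx[, 1] - 1
    rho <- outer(x, cos(thetas)) + outer(y, sin(thetas))
    bin <- as.integer(floor(rho + 0.5)) + d_max + 1L
    flat <- bin + rep((seq_len(theta_steps) - 1L) * length(rhos),
                      each = length(x))
    acc <- matrix(tabulate(flat, nbins = length(rhos) * theta_steps),
                  length(rhos), theta_steps)
  }
  list(votes = acc, rhos = rhos, thetas = thetas)
}

#' Detect dominant straight lines with the Hough transform
#'
#' Returns the local maxima of the [hough_accumulator()] whose votes reach
#' `vote_fraction` times the image diagonal, sorted by votes descending with
#' ties broken by `(theta, rho)` ascending. A maximum is a cell whose votes
#' are not exceeded by any of its 8 accumulator neighbours (plateaus keep the
#' smallest `(theta, rho)` cell). The default threshold of half the diagonal
#' rejects short cell boundaries and keeps only frame-scale overlays.
#'
#' @inheritParams hough_accumulator
#' @param vote_fraction detection threshold as a fraction of the image
#'   diagonal, in `(0, 1]`.
#' @return a data frame with columns `rho`, `theta`, `votes` (possibly 0 rows).
#' @export
hough_lines <- function(edges, theta_steps = 180L, vote_fraction = 0.5) {
  if (vote_fraction <= 0 || vote_fraction > 1)
    stop("vote_fraction must lie in (0, 1]")
  accu <- hough_accumulator(edges, theta_steps)
  acc <- accu$votes
  threshold <- vote_fraction * sqrt(nrow(edges)^2 + ncol(edges)^2)
  n_rho <- nrow(acc)
  is_max <- acc >= threshold
  if (any(is_max)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      nb <- shift_mat(acc, -di, -dj, -1L)  # nb[i,j] = acc[i+di, j+dj]
      # neighbour later in (theta, rho) order loses equal-vote plateaus
      later <- dj > 0L || (dj == 0L && di > 0L)
      is_max <- is_max & (acc > nb | (acc == nb & later))
    }
  }
  hits <- which(is_max, arr.ind = TRUE)
  out <- data.frame(rho = accu$rhos[hits[, 1]],
                    theta = accu$thetas[hits[, 2]],
                    votes = acc[hits])
  out[order(-out$votes, out$theta, out$rho), , drop = FALSE]
}

#' Binary validity mask excluding marker lines
#'
#' Marks as invalid every pixel within perpendicular distance `dilation` of
#' any detected line; all other pixels stay valid. The union is idempotent and
#' independent of the order of the lines.
#'
#' @param lines data frame with columns `rho` and `theta` (as from
#'   [hough_lines()]); zero rows give an all-valid mask.
#' @param shape integer vector `c(height, width)`.
#' @param dilation mask half-width in pixels (>= 1).
#' @return a logical matrix, `TRUE` where pixels are valid.
#' @export
marker_mask <- function(lines, shape, dilation = 3) {
  if (dilation < 1) stop("dilation must be >= 1")
  h <- as.integer(shape[1])
  w <- as.integer(shape[2])
  valid <- matrix(TRUE, h, w)
  if (!is.null(lines) && nrow(lines) > 0L) {
    X <- matrix(rep(0:(w - 1), each = h), h, w)
    Y <- matrix(rep(0:(h - 1), times = w), h, w)
    for (i in seq_len(nrow(lines))) {
      d <- abs(X * cos(lines$theta[i]) + Y * sin(lines$theta[i]) - lines$rho[i])
      valid[d <= dilation] <- FALSE
    }
  }
  if (sum(valid) < 9L)
    stop("marker suppression would leave fewer than 9 valid pixels")
  valid
}

#' Preprocessing parameters
#'
#' Defaults for marker suppression: `theta_steps = 180` (1 degree angular
#' resolution), `vote_fraction = 0.5` (a genuine embedded marker spans a large
#' fraction of the frame), `dilation = 3`, hysteresis thresholds 0.1/0.3 of
#' the maximum gradient magnitude.
#'
#' @param theta_steps,vote_fraction see [hough_lines()].
#' @param dilation see [marker_mask()].
#' @param low_fraction,high_fraction see [edge_map()].
#' @return a named list of parameters.
#' @export
preprocess_params <- function(theta_steps = 180L, vote_fraction = 0.5,
                              dilation = 3, low_fraction = 0.1,
                              high_fraction = 0.3) {
  list(theta_steps = as.integer(theta_steps), vote_fraction = vote_fraction,
       dilation = dilation, low_fraction = low_fraction,
       high_fraction = high_fraction)
}

#' Preprocess an image: marker detection and exclusion mask
#'
#' Detects microscope-embedded marker lines (edge map, Hough transform) and
#' builds the binary validity mask that excludes them. The image itself is
#' never modified or inpainted: suppression is purely exclusion-by-mask, so
#' the masked image carries no synthetic pixel values into the metrics. With
#' suppression disabled, or when no line reaches the vote threshold, the mask
#' is all-valid.
#'
#' @param image 8-bit grayscale matrix (see [to_grayscale()]).
#' @param suppress_marker logical; disable to force an all-valid mask.
#' @param params a [preprocess_params()] list.
#' @return a list with elements `image` (unchanged), `mask` (logical validity
#'   matrix) and `lines` (the detected lines, a possibly empty data frame).
#' @export
preprocess <- function(image, suppress_marker = TRUE,
                       params = preprocess_params()) {
  assert_gray_image(image)
  if (!suppress_marker) {
    return(list(image = image, mask = full_mask(image),
                lines = data.frame(rho = numeric(0), theta = numeric(0),
                                   votes = integer(0))))
  }
  edges <- edge_map(image, params$low_fraction, params$high_fraction)
  lines <- hough_lines(edges, params$theta_steps, params$vote_fraction)
  mask <- marker_mask(lines, dim(image), params$dilation)
  list(image = image, mask = mask, lines = lines)
}

# --- image file I/O ---------------------------------------------------------

#' Read an image file as 8-bit grayscale
#'
#' Reads a PNG or TIFF file (8-bit, 1 or 3 channels; an alpha channel is
#' dropped) and converts it to an integer intensity matrix via
#' [to_grayscale()].
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return an integer matrix of 8-bit intensities.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", path))
  if (length(dim(raw)) == 3L && dim(raw)[3] %in% c(2L, 4L))
    raw <- raw[, , -dim(raw)[3], drop = FALSE]  # drop alpha
  if (length(dim(raw)) == 3L && dim(raw)[3] == 1L)
    raw <- raw[, , 1]
  samples <- floor(raw * 255 + 0.5)
  out <- if (is.matrix(samples)) to_grayscale(samples)
  else to_grayscale(array(samples, dim(samples)))
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit grayscale PNG
#'
#' @param image integer matrix with values in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  assert_gray_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}
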