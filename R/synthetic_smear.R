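#' Marker line specification
#'
#' Describes a straight marker line in normal form `x*cos(theta) + y*sin(theta)
#' = rho`, with the origin at the top-left pixel, `x` increasing along columns
#' and `y` along rows (0-based). Emulates the graticule/scale-bar overlays that
#' some microscope cameras burn into exported frames.
#'
#' @param rho signed normal distance from the origin, in pixels.
#' @param theta line normal angle in radians, in `[0, pi)`.
#' @param thickness line thickness in pixels (>= 1).
#' @param level 8-bit intensity the line is drawn at, in `[0, 255]`.
#' @return an object of class `marker_spec`.
#' @seealso [render_scene()], [marker_mask()]
#' @export
#' @examples
#' marker_spec(rho = 64, theta = pi / 2)  # horizontal line through row 64
marker_spec <- function(rho, theta, thickness = 3, level = 30) {
  stopifnot(is.numeric(rho), length(rho) == 1L,
            is.numeric(theta), length(theta) == 1L,
            is.numeric(thickness), length(thickness) == 1L,
            is.numeric(level), length(level) == 1L)
  if (theta < 0 || theta >= pi) stop("theta must lie in [0, pi)")
  if (thickness < 1) stop("thickness must be >= 1 pixel")
  if (level < 0 || level > 255) stop("level must lie in [0, 255]")
  structure(list(rho = rho, theta = theta, thickness = thickness,
                 level = level),
            class = "marker_spec")
}

#' Synthetic smear scene configuration
#'
#' Bundles and validates the parameters of a synthetic stained-smear scene:
#' morphology and number of foreground objects, image size, the two intensity
#' levels, the degradation strengths, an optional embedded marker line, and the
#' seed that makes rendering bit-reproducible.
#'
#' Morphologies:
#' * `"cocci"` - filled disks (spherical bacteria / yeasts);
#' * `"bacilli"` - round-capped rods at random orientation;
#' * `"hyphae"` - constant-width tubes from a seeded random walk, with one
#'   branching event per 50 steps and periodic septa drawn at the background
#'   level;
#' * `"capsule"` - a bright halo annulus around an unstained cell interior,
#'   as in negative (India-ink style) capsule preparations.
#'
#' @param morphology one of `"cocci"`, `"bacilli"`, `"hyphae"`, `"capsule"`.
#' @param n_objects number of foreground objects (0 gives a flat background).
#' @param height,width image size in pixels (>= 64).
#' @param background_level,foreground_level 8-bit intensities in `[0, 255]`;
#'   must differ when `n_objects > 0`.
#' @param blur_sigma isotropic Gaussian blur scale in pixels (defocus proxy),
#'   >= 0.
#' @param noise_sigma additive Gaussian noise scale in intensity units, >= 0.
#' @param marker optional [marker_spec()] drawn (unblurred) on top of the
#'   degraded scene.
#' @param seed integer seed; identical configurations render identical images.
#' @return an object of class `scene_config`.
#' @export
#' @examples
#' cfg <- scene_config("cocci", n_objects = 5, height = 64, width = 64,
#'                     blur_sigma = 0, noise_sigma = 0, seed = 7)
#' img <- render_scene(cfg)
#' sort(unique(as.vector(img)))  # exactly the two configured levels
scene_config <- function(morphology = c("cocci", "bacilli", "hyphae", "capsule"),
                         n_objects = 12L,
                         height = 512L, width = 512L,
                         background_level = 200,
                         foreground_level = 90,
                         blur_sigma = 0,
                         noise_sigma = 0,
                         marker = NULL,
                         seed = 1L) {
  morphology <- match.arg(morphology)
  height <- as.integer(height)
  width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 64L || width < 64L)
    stop("height and width must be at least 64 pixels")
  for (lv in c(background_level, foreground_level))
    if (lv < 0 || lv > 255) stop("intensity levels must lie in [0, 255]")
  if (n_objects < 0) stop("n_objects must be non-negative")
  if (n_objects > 0 && foreground_level == background_level)
    stop("foreground_level must differ from background_level when objects are drawn")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.null(marker)) {
    if (!inherits(marker, "marker_spec")) stop("marker must be a marker_spec")
    if (!line_intersects_extent(marker, height, width))
      stop("marker line does not intersect the image extent")
  }
  structure(list(morphology = morphology, n_objects = as.integer(n_objects),
                 height = height, width = width,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 marker = marker, seed = as.integer(seed)),
            class = "scene_config")
}

# does the (thick) line meet the [0,w-1] x [0,h-1] rectangle?
line_intersects_extent <- function(marker, height, width) {
  xs <- c(0, width - 1, 0, width - 1)
  ys <- c(0, 0, height - 1, height - 1)
  d <- xs * cos(marker$theta) + ys * sin(marker$theta) - marker$rho
  half <- marker$thickness / 2
  any(abs(d) <= half) || (min(d) < -half && max(d) > half) ||
    (min(d) < 0 && max(d) > 0)
}

# --- drawing primitives -----------------------------------------------------
# All primitives write `level` into `img` (a numeric matrix) over the pixels
# selected by an inclusion test evaluated at 0-based pixel centers, restricted
# to the bounding box of the shape.

draw_region <- function(img, x0, x1, y0, y1, test, level) {
  h <- nrow(img)
  w <- ncol(img)
  c0 <- max(1L, floor(x0) + 1L)
  c1 <- min(w, ceiling(x1) + 1L)
  r0 <- max(1L, floor(y0) + 1L)
  r1 <- min(h, ceiling(y1) + 1L)
  if (c0 > c1 || r0 > r1) return(img)
  X <- matrix(rep((c0:c1) - 1, each = r1 - r0 + 1L), nrow = r1 - r0 + 1L)
  Y <- matrix(rep((r0:r1) - 1, times = c1 - c0 + 1L), nrow = r1 - r0 + 1L)
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  sub[test(X, Y)] <- level
  img[r0:r1, c0:c1] <- sub
  img
}

draw_disk <- function(img, cx, cy, r, level) {
  draw_region(img, cx - r, cx + r, cy - r, cy + r,
              function(X, Y) (X - cx)^2 + (Y - cy)^2 <= r^2, level)
}

draw_annulus <- function(img, cx, cy, r_in, r_out, level) {
  draw_region(img, cx - r_out, cx + r_out, cy - r_out, cy + r_out,
              function(X, Y) {
                d2 <- (X - cx)^2 + (Y - cy)^2
                d2 >= r_in^2 & d2 <= r_out^2
              }, level)
}

# round-capped rod: all pixels within half_w of the segment (x1,y1)-(x2,y2)
draw_rod <- function(img, x1, y1, x2, y2, half_w, level) {
  draw_region(img, min(x1, x2) - half_w, max(x1, x2) + half_w,
              min(y1, y2) - half_w, max(y1, y2) + half_w,
              function(X, Y) {
                dx <- x2 - x1
                dy <- y2 - y1
                l2 <- dx * dx + dy * dy
                t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((X - x1) * dx + (Y - y1) * dy) / l2))
                (X - x1 - t * dx)^2 + (Y - y1 - t * dy)^2 <= half_w^2
              }, level)
}

draw_marker_line <- function(img, marker) {
  h <- nrow(img)
  w <- ncol(img)
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  d <- abs(X * cos(marker$theta) + Y * sin(marker$theta) - marker$rho)
  img[d <= marker$thickness / 2] <- marker$level
  img
}

# --- scene content ----------------------------------------------------------

draw_cocci <- function(canvas, cfg) {
  h <- cfg$height
  w <- cfg$width
  objs <- vector("list", cfg$n_objects)
  for (i in seq_len(cfg$n_objects)) {
    r <- runif(1, 4, 12)
    cx <- runif(1, r, w - 1 - r)
    cy <- runif(1, r, h - 1 - r)
    canvas <- draw_disk(canvas, cx, cy, r, cfg$foreground_level)
    objs[[i]] <- list(kind = "disk", cx = cx, cy = cy, r = r)
  }
  list(canvas = canvas, objects = objs)
}

draw_bacilli <- function(canvas, cfg) {
  h <- cfg$height
  w <- cfg$width
  objs <- vector("list", cfg$n_objects)
  for (i in seq_len(cfg$n_objects)) {
    len <- runif(1, 18, 36)
    half_w <- runif(1, 2.5, 4.5)
    ang <- runif(1, 0, pi)
    cx <- runif(1, len / 2, w - 1 - len / 2)
    cy <- runif(1, len / 2, h - 1 - len / 2)
    x1 <- cx - cos(ang) * len / 2
    y1 <- cy - sin(ang) * len / 2
    x2 <- cx + cos(ang) * len / 2
    y2 <- cy + sin(ang) * len / 2
    canvas <- draw_rod(canvas, x1, y1, x2, y2, half_w, cfg$foreground_level)
    objs[[i]] <- list(kind = "rod", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                      half_w = half_w)
  }
  list(canvas = canvas, objects = objs)
}

# constant-width tube from a random walk; branches every `branch_every` steps;
# septa (cross-walls at the background level) every `septum_every` steps
draw_hypha_walk <- function(canvas, cfg, x, y, ang, n_steps, half_w, depth) {
  step_len <- 4
  branch_every <- 50L
  septum_every <- 12L
  septa <- list()
  segs <- list()
  for (s in seq_len(n_steps)) {
    ang <- ang + rnorm(1, 0, 0.45)
    x2 <- x + cos(ang) * step_len
    y2 <- y + sin(ang) * step_len
    canvas <- draw_rod(canvas, x, y, x2, y2, half_w, cfg$foreground_level)
    segs[[length(segs) + 1L]] <- c(x, y, x2, y2)
    if (s %% septum_every == 0L)
      septa[[length(septa) + 1L]] <- c(x2, y2, ang)
    if (s %% branch_every == 0L && depth < 2L) {
      side <- sample(c(-1, 1), 1)
      res <- draw_hypha_walk(canvas, cfg, x2, y2, ang + side * 0.7,
                             n_steps - s, half_w, depth + 1L)
      canvas <- res$canvas
      septa <- c(septa, res$septa)
      segs <- c(segs, res$segs)
    }
    x <- x2
    y <- y2
  }
  list(canvas = canvas, septa = septa, segs = segs)
}

draw_hyphae <- function(canvas, cfg) {
  h <- cfg$height
  w <- cfg$width
  objs <- vector("list", cfg$n_objects)
  all_septa <- list()
  for (i in seq_len(cfg$n_objects)) {
    x <- runif(1, 0.15 * w, 0.85 * w)
    y <- runif(1, 0.15 * h, 0.85 * h)
    ang <- runif(1, 0, 2 * pi)
    half_w <- runif(1, 2, 3)
    res <- draw_hypha_walk(canvas, cfg, x, y, ang, 110L, half_w, 0L)
    canvas <- res$canvas
    all_septa <- c(all_septa, lapply(res$septa, function(s) c(s, half_w)))
    objs[[i]] <- list(kind = "hypha", segs = res$segs, half_w = half_w)
  }
  # septa drawn after all tubes so crossings do not erase them
  for (s in all_septa) {
    ang <- s[3] + pi / 2
    hw <- s[4]
    canvas <- draw_rod(canvas,
                       s[1] - cos(ang) * hw, s[2] - sin(ang) * hw,
                       s[1] + cos(ang) * hw, s[2] + sin(ang) * hw,
                       0.8, cfg$background_level)
  }
  list(canvas = canvas, objects = objs)
}

draw_capsules <- function(canvas, cfg) {
  h <- cfg$height
  w <- cfg$width
  objs <- vector("list", cfg$n_objects)
  for (i in seq_len(cfg$n_objects)) {
    r_cell <- runif(1, 6, 10)
    r_out <- r_cell * 1.9
    cx <- runif(1, r_out, w - 1 - r_out)
    cy <- runif(1, r_out, h - 1 - r_out)
    # halo annulus only: the cell interior stays at the (ink) background level
    canvas <- draw_annulus(canvas, cx, cy, r_cell, r_out, cfg$foreground_level)
    objs[[i]] <- list(kind = "capsule", cx = cx, cy = cy,
                      r_in = r_cell, r_out = r_out)
  }
  list(canvas = canvas, objects = objs)
}

# --- degradation chain ------------------------------------------------------

# 1-D Gaussian kernel truncated at 3*sigma, normalized to sum 1
gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(3 * sigma)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with edge-replication padding
conv_axis_replicate <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m * k)
  h <- nrow(m)
  mp <- m[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out <- matrix(0, h, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[j:(j + h - 1L), , drop = FALSE]
  out
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel1d(sigma)
  t(conv_axis_replicate(t(conv_axis_replicate(m, k)), k))
}

clip_quantize <- function(m) {
  m[m < 0] <- 0
  m[m > 255] <- 255
  matrix(as.integer(floor(m + 0.5)), nrow(m), ncol(m))
}

apply_degradation <- function(m, blur_sigma, noise_sigma) {
  m <- gaussian_blur(m, blur_sigma)
  if (noise_sigma > 0)
    m <- m + matrix(rnorm(length(m), 0, noise_sigma), nrow(m), ncol(m))
  clip_quantize(m)
}

#' Render a synthetic stained-smear image
#'
#' Draws `n_objects` foreground structures of the configured morphology at
#' `foreground_level` on a flat `background_level` canvas, then applies the
#' degradation chain (isotropic Gaussian blur truncated at `3*blur_sigma`,
#' additive independent Gaussian noise, clipping to `[0, 255]`, quantization
#' with halves rounded away from zero) and finally draws the marker line, if
#' any, at its own level. Rendering is bit-reproducible for a fixed
#' configuration (including the seed).
#'
#' @param config a [scene_config()].
#' @return an integer matrix (`height` x `width`) of 8-bit intensities, with
#'   the drawn object parameters attached as attribute `"scene_objects"` (used
#'   by geometry oracles in validation).
#' @seealso [degrade()], [paired_fixture_suite()]
#' @export
render_scene <- function(config) {
  if (!inherits(config, "scene_config")) stop("config must be a scene_config")
  withr::with_seed(config$seed, {
    canvas <- matrix(as.numeric(config$background_level),
                     config$height, config$width)
    objects <- list()
    if (config$n_objects > 0) {
      res <- switch(config$morphology,
                    cocci = draw_cocci(canvas, config),
                    bacilli = draw_bacilli(canvas, config),
                    hyphae = draw_hyphae(canvas, config),
                    capsule = draw_capsules(canvas, config))
      canvas <- res$canvas
      objects <- res$objects
    }
    img <- apply_degradation(canvas, config$blur_sigma, config$noise_sigma)
    if (!is.null(config$marker))
      img <- clip_quantize(draw_marker_line(img, config$marker))
    attr(img, "scene_objects") <- objects
    img
  })
}

#' Degrade an existing image
#'
#' Applies the same blur-then-noise-then-clip-then-quantize chain used by
#' [render_scene()] to an existing 8-bit image. With both scales zero the
#' input is returned unchanged.
#'
#' @param image integer/numeric matrix with values in `[0, 255]`.
#' @param blur_sigma Gaussian blur scale in pixels, >= 0.
#' @param noise_sigma additive noise scale in intensity units, >= 0.
#' @param seed integer seed for the noise draw.
#' @return a degraded integer matrix of the same size.
#' @export
degrade <- function(image, blur_sigma, noise_sigma, seed = 1L) {
  assert_gray_image(image)
  if (blur_sigma < 0 || noise_sigma < 0)
    stop("blur_sigma and noise_sigma must be >= 0")
  if (blur_sigma == 0 && noise_sigma == 0) return(image)
  withr::with_seed(as.integer(seed),
                   apply_degradation(image + 0, blur_sigma, noise_sigma))
}

#' Paired synthetic fixture suite
#'
#' Generates six labelled organism pairs of synthetic smear images emulating a
#' paired dye-comparison study: for each organism a "standard"-dye image
#' (larger foreground/background separation, milder defocus) and a "test"-dye
#' image (smaller separation, stronger defocus) at equal noise, so the
#' ground-truth quality ordering within each pair is known by construction.
#'
#' @param seed integer master seed; the full suite is reproducible from it.
#' @param height,width image size in pixels (default 256, the package's
#'   fixture working size).
#' @return a list of 6 elements, each
#'   `list(organism = <label>, test = <image>, standard = <image>)`.
#' @seealso [write_fixture_suite()] to materialize the suite as PNG files plus
#'   a manifest CSV.
#' @export
paired_fixture_suite <- function(seed = 1L, height = 256L, width = 256L) {
  organisms <- c("mold_alpha", "mold_beta", "mold_gamma",
                 "encapsulated_yeast", "zygomycete", "dermatophyte")
  morphologies <- c("hyphae", "hyphae", "hyphae", "capsule", "hyphae", "hyphae")
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L, 12L))
  lapply(seq_along(organisms), function(i) {
    n_obj <- if (morphologies[i] == "capsule") 10L else 4L
    std <- scene_config(morphologies[i], n_objects = n_obj,
                        height = height, width = width,
                        background_level = 200, foreground_level = 70,
                        blur_sigma = 0.8, noise_sigma = 5,
                        seed = sub_seeds[2L * i - 1L])
    tst <- scene_config(morphologies[i], n_objects = n_obj,
                        height = height, width = width,
                        background_level = 200, foreground_level = 120,
                        blur_sigma = 1.8, noise_sigma = 5,
                        seed = sub_seeds[2L * i])
    list(organism = organisms[i],
         test = render_scene(tst),
         standard = render_scene(std))
  })
}

#' Write the paired fixture suite to disk
#'
#' Renders [paired_fixture_suite()] and writes the twelve images as 8-bit
#' grayscale PNGs together with a manifest CSV (columns `organism`,
#' `dye_role`, `path`) in the layout [run_study()] consumes.
#'
#' @inheritParams paired_fixture_suite
#' @param dir output directory (created if missing).
#' @return the manifest as a data frame, invisibly; the manifest file is
#'   written to `file.path(dir, "manifest.csv")`.
#' @export
write_fixture_suite <- function(dir, seed = 1L, height = 256L, width = 256L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suite <- paired_fixture_suite(seed, height, width)
  rows <- list()
  for (pair in suite) {
    for (role in c("test", "standard")) {
      path <- file.path(dir, sprintf("%s_%s.png", pair$organism, role))
      write_gray_png(pair[[role]], path)
      rows[[length(rows) + 1L]] <- data.frame(organism = pair$organism,
                                              dye_role = role, path = path,
                                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
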