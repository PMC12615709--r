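test_that("grayscale conversion follows the fixed luminance weights", {
  m <- rand_gray(8, 8, 1)
  expect_identical(to_grayscale(m), m)
  arr <- array(0, c(4, 4, 3))
  arr[, , 1] <- 77
  arr[, , 2] <- 77
  arr[, , 3] <- 77
  expect_true(all(to_grayscale(arr) == 77L))
  arr[1, 1, ] <- c(100, 150, 200)
  expect_equal(to_grayscale(arr)[1, 1],
               as.integer(floor(0.299 * 100 + 0.587 * 150 + 0.114 * 200 + 0.5)))
  expect_error(to_grayscale(array(0, c(4, 4, 5))), "channel")
})

test_that("edge map is empty for constant images and hugs a step edge", {
  expect_false(any(edge_map(matrix(100L, 16, 16))))
  img <- matrix(0L, 20, 20)
  img[, 11:20] <- 255L
  e <- edge_map(img)
  expect_true(any(e))
  expect_true(all(which(e, arr.ind = TRUE)[, 2] %in% c(10L, 11L)))
})

test_that("edge pixels of a thick drawn line stay within 2 px of its locus", {
  img <- matrix(200L, 64, 64)
  img <- clip_quantize_for_test(draw_line_for_test(img, rho = 31.4,
                                                   theta = pi / 3,
                                                   thickness = 3, level = 20))
  e <- edge_map(img)
  idx <- which(e, arr.ind = TRUE)
  d <- abs((idx[, 2] - 1) * cos(pi / 3) + (idx[, 1] - 1) * sin(pi / 3) - 31.4)
  expect_true(all(d <= 1.5 + 2))
})

test_that("the vectorized Hough accumulator equals direct per-pixel voting", {
  for (seed in 1:3) {
    edges <- withr::with_seed(seed, matrix(runif(40 * 48) < 0.03, 40, 48))
    got <- hough_accumulator(edges, theta_steps = 90)
    expect_identical(unname(got$votes), unname(oracle_hough_accumulator(edges, 90)))
  }
  # and on structured input: two perpendicular full-length lines
  edges <- matrix(FALSE, 64, 64)
  edges[20, ] <- TRUE
  edges[, 45] <- TRUE
  expect_identical(unname(hough_accumulator(edges, 180)$votes),
                   unname(oracle_hough_accumulator(edges, 180)))
})

test_that("axis-aligned lines are recovered at their exact (rho, theta)", {
  edges <- matrix(FALSE, 64, 64)
  edges[21, ] <- TRUE  # horizontal line at y = 20
  lines <- hough_lines(edges)
  expect_equal(nrow(lines), 1L)
  expect_equal(lines$theta, pi / 2)
  expect_equal(lines$rho, 20)
  expect_equal(lines$votes, 64L)
  expect_equal(nrow(hough_lines(matrix(FALSE, 64, 64))), 0L)
})

test_that("two perpendicular lines give exactly two maxima within one cell", {
  edges <- matrix(FALSE, 64, 64)
  edges[20, ] <- TRUE   # y = 19  -> rho 19, theta pi/2
  edges[, 45] <- TRUE   # x = 44  -> rho 44, theta 0
  lines <- hough_lines(edges)
  expect_equal(nrow(lines), 2L)
  got <- lines[order(lines$theta), ]
  expect_equal(got$rho, c(44, 19), tolerance = 1e-12)
  expect_equal(got$theta, c(0, pi / 2), tolerance = pi / 180)
})

test_that("marker masks are geometric bands, idempotent and order-independent", {
  expect_true(all(marker_mask(NULL, c(16, 16))))
  one <- data.frame(rho = 8, theta = pi / 2, votes = 10L)
  m1 <- marker_mask(one, c(20, 20), dilation = 2)
  # exactly rows 7..11 (0-based rows 6..10) invalid, a 5-row band
  expect_identical(which(!apply(m1, 1, all)), 7:11)
  expect_true(all(m1[-(7:11), ]))
  dup <- rbind(one, one)
  expect_identical(marker_mask(dup, c(20, 20), dilation = 2), m1)
  two <- rbind(one, data.frame(rho = 3, theta = 0, votes = 5L))
  expect_identical(marker_mask(two, c(20, 20), dilation = 2),
                   marker_mask(two[2:1, ], c(20, 20), dilation = 2))
  # over-aggressive masking is an error
  wipe <- data.frame(rho = c(4, 12, 20), theta = rep(pi / 2, 3), votes = 1L)
  expect_error(marker_mask(wipe, c(24, 8), dilation = 12), "9 valid")
})

test_that("preprocess returns an all-valid mask when disabled or marker-free", {
  img <- render_scene(scene_config("hyphae", n_objects = 4, height = 128,
                                   width = 128, blur_sigma = 1, noise_sigma = 4,
                                   seed = 9))
  off <- preprocess(img, suppress_marker = FALSE)
  expect_true(all(off$mask))
  expect_identical(off$image, img)
  on <- preprocess(img)
  expect_true(all(on$mask))
  expect_equal(nrow(on$lines), 0L)
})

test_that("an embedded marker is masked on its dilated locus and nowhere much else", {
  mk <- marker_spec(rho = 60, theta = pi / 2, thickness = 3, level = 20)
  cfg <- scene_config("hyphae", n_objects = 4, height = 160, width = 160,
                      blur_sigma = 1, noise_sigma = 4, seed = 21, marker = mk)
  pre <- preprocess(render_scene(cfg))
  expect_gt(nrow(pre$lines), 0L)
  X <- matrix(rep(0:159, each = 160), 160, 160)
  Y <- matrix(rep(0:159, times = 160), 160, 160)
  d <- abs(X * cos(mk$theta) + Y * sin(mk$theta) - mk$rho)
  # every pixel of the true marker band is excluded...
  expect_true(all(!pre$mask[d <= mk$thickness / 2]))
  # ...and the exclusion stays within the dilated neighbourhood of the marker
  expect_true(all(pre$mask[d > mk$thickness / 2 + 3 + 1.5]))
})

test_that("metrics over the suppression mask track the marker-free image", {
  cfg0 <- scene_config("hyphae", n_objects = 4, height = 160, width = 160,
                       blur_sigma = 1, noise_sigma = 4, seed = 33)
  mk <- marker_spec(rho = 75, theta = pi / 2, thickness = 3, level = 20)
  cfg1 <- scene_config("hyphae", n_objects = 4, height = 160, width = 160,
                       blur_sigma = 1, noise_sigma = 4, seed = 33, marker = mk)
  clean <- render_scene(cfg0)
  marked <- render_scene(cfg1)
  pre <- preprocess(marked)
  masked <- metric_vector(marked, pre$mask)
  ref <- metric_vector(clean)
  expect_true(all(abs(masked - ref) / abs(ref) < 0.05))
  # without masking the marker's edges inflate the derivative metrics
  expect_gt(laplacian_sharpness(marked), laplacian_sharpness(clean))
  expect_gt(edge_intensity(marked), edge_intensity(clean))
})
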