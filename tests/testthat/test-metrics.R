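test_that("analytic values hold exactly on degenerate images", {
  flat <- matrix(77L, 16, 16)
  expect_equal(laplacian_sharpness(flat), 0)
  expect_equal(shannon_entropy(flat), 0)
  expect_equal(global_contrast(flat), 0)
  expect_error(snr(flat), "constant")
  expect_equal(edge_intensity(flat), 0)

  ramp <- matrix(rep(0:15, each = 16), 16, 16)  # linear in x
  expect_equal(laplacian_sharpness(ramp), 0)

  half <- matrix(c(0L, 255L), 16, 16)
  expect_equal(shannon_entropy(half), 1.0)
  expect_equal(global_contrast(half), 127.5)
  expect_equal(snr(half), 1.0)

  uniform <- matrix(rep(0:255, each = 256), 256, 256)
  expect_equal(shannon_entropy(uniform), 8.0)

  expect_equal(global_contrast(matrix(c(0L, 100L, 200L, 255L), 4, 4)),
               sqrt(mean((c(0, 100, 200, 255) - 138.75)^2)))
  expect_equal(snr(matrix(c(50L, 100L, 150L, 200L), 4, 4)),
               125 / sqrt(mean((c(50, 100, 150, 200) - 125)^2)))
})

test_that("the 4x4 two-column step matches the hand-evaluable Laplacian oracle", {
  img <- matrix(rep(c(0L, 0L, 255L, 255L), each = 4), 4, 4)
  # four eligible interior pixels; Laplacian there is {255, 255, -255, -255}
  # on columns 2 and 3 -> population variance 255^2
  expect_equal(laplacian_sharpness(img), 255^2)
  expect_equal(laplacian_sharpness(img), oracle_sharpness(img))
})

test_that("a full-contrast vertical step carries normalized Sobel magnitude 1/sqrt(2)", {
  img <- matrix(0L, 12, 12)
  img[, 7:12] <- 255L
  g <- oracle_edge_intensity(img)
  expect_equal(edge_intensity(img), g)
  # eligible pixels: 10 rows x 10 cols; the two columns flanking the step
  # carry |gx| = 4 on the [0,1] scale, i.e. 1/sqrt(2) after normalization
  expect_equal(edge_intensity(img), (20 / 100) / sqrt(2))
})

test_that("all five metrics match direct-summation oracles on small images", {
  for (seed in 1:4) {
    img <- rand_gray(17, 23, seed)
    mask <- if (seed %% 2 == 0) rand_mask(17, 23, seed + 100) else NULL
    expect_equal(laplacian_sharpness(img, mask), oracle_sharpness(img, mask),
                 tolerance = 1e-9)
    expect_equal(shannon_entropy(img, mask), oracle_entropy(img, mask),
                 tolerance = 1e-9)
    expect_equal(global_contrast(img, mask), oracle_contrast(img, mask),
                 tolerance = 1e-9)
    expect_equal(snr(img, mask), oracle_snr(img, mask), tolerance = 1e-9)
    expect_equal(edge_intensity(img, mask), oracle_edge_intensity(img, mask),
                 tolerance = 1e-9)
  }
})

test_that("intensity inversion preserves all metrics except SNR", {
  img <- rand_gray(20, 20, 11, levels = 30:220)
  inv <- 255L - img
  expect_equal(laplacian_sharpness(inv), laplacian_sharpness(img))
  expect_equal(shannon_entropy(inv), shannon_entropy(img))
  expect_equal(global_contrast(inv), global_contrast(img))
  expect_equal(edge_intensity(inv), edge_intensity(img))
  expect_false(isTRUE(all.equal(snr(inv), snr(img))))
})

test_that("metric ranges hold on random and rendered images", {
  imgs <- list(rand_gray(16, 16, 1), rand_gray(24, 16, 2),
               render_scene(scene_config("capsule", n_objects = 6,
                                         height = 96, width = 96,
                                         background_level = 60,
                                         foreground_level = 230,
                                         blur_sigma = 1, noise_sigma = 6,
                                         seed = 2)))
  for (img in imgs) {
    mv <- metric_vector(img)
    expect_true(all(is.finite(mv)))
    expect_true(all(mv >= 0 | names(mv) == "snr"))
    expect_lte(mv[["entropy"]], 8)
    expect_lte(mv[["contrast"]], 127.5)
    expect_gte(mv[["snr"]], 0)
  }
})

test_that("metric_vector is deterministic and names its failing metric", {
  img <- rand_gray(16, 16, 9)
  expect_identical(metric_vector(img), metric_vector(img))
  expect_named(metric_vector(img),
               c("sharpness", "entropy", "contrast", "snr", "edge_intensity"))
  expect_error(metric_vector(matrix(5L, 8, 8)), "snr")
  # masks leaving no fully valid 3x3 neighbourhood are rejected by name
  mask <- matrix(FALSE, 8, 8)
  mask[1:2, ] <- TRUE
  expect_error(laplacian_sharpness(rand_gray(8, 8, 2), mask), "sharpness")
  expect_error(shannon_entropy(rand_gray(8, 8, 2), matrix(FALSE, 8, 8)),
               "empty")
})

test_that("defocus degrades sharpness and edge strength monotonically", {
  vals <- lapply(c(0, 1, 2, 4), function(b) {
    img <- render_scene(scene_config("hyphae", n_objects = 4, height = 160,
                                     width = 160, blur_sigma = b,
                                     noise_sigma = 0, seed = 11))
    c(s = laplacian_sharpness(img), e = edge_intensity(img))
  })
  s <- vapply(vals, `[[`, 0, "s")
  e <- vapply(vals, `[[`, 0, "e")
  expect_true(all(diff(s) < 0))
  expect_true(all(diff(e) < 0))
})

test_that("noise degrades SNR monotonically", {
  snrs <- vapply(c(0, 5, 15, 30), function(nz) {
    snr(render_scene(scene_config("hyphae", n_objects = 4, height = 160,
                                  width = 160, blur_sigma = 1,
                                  noise_sigma = nz, seed = 11)))
  }, 0)
  expect_true(all(diff(snrs) < 0))
})
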