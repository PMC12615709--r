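# independent per-pixel line rasterizer (normal form, 0-based pixel centers)
draw_line_for_test <- function(img, rho, theta, thickness, level) {
  for (i in 1:nrow(img)) for (j in 1:ncol(img)) {
    d <- abs((j - 1) * cos(theta) + (i - 1) * sin(theta) - rho)
    if (d <= thickness / 2) img[i, j] <- level
  }
  img
}

clip_quantize_for_test <- function(m) {
  matrix(as.integer(floor(pmin(255, pmax(0, m)) + 0.5)), nrow(m), ncol(m))
}
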