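test_that("downscale block-averages by the requested factor", {
  img <- array(as.integer(sample(0:255, 160 * 160 * 3, TRUE)),
               c(160, 160, 3))
  small <- downscale(img, 8)
  expect_equal(dim(small), c(20, 20, 3))
  expect_equal(small[1, 1, 1],
               as.integer(round(mean(img[1:8, 1:8, 1]))))
  expect_identical(downscale(img, 1), img)

  flat <- array(77L, c(64, 64, 3))
  expect_true(all(downscale(flat, 4) == 77L))
  expect_equal(dim(downscale(flat, 4)), c(16, 16, 3))

  expect_error(downscale(img, 500), "exceeds")
  expect_error(downscale(img, 0), ">= 1")
})

test_that("skin detection separates a Gaussian blob from a dark background", {
  # one skin-colored Gaussian blob covering most of a dark backdrop
  h <- 64; w <- 64
  r <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  blob <- ((r - h / 2) / (0.46 * h))^2 + ((cc - w / 2) / (0.46 * w))^2 <= 1
  n <- h * w
  set.seed(10)
  lab <- cbind(pmax(rnorm(n, 18, 6), 5), rnorm(n, 0, 1.5), rnorm(n, -10, 1.5))
  nb <- sum(blob)
  lab[blob, ] <- cbind(rnorm(nb, 60, 5), rnorm(nb, 14, 2), rnorm(nb, 17, 2))
  rgb <- lab_to_rgb(lab)
  img <- array(as.integer(round(255 * rgb)), c(h, w, 3))
  mask <- detect_skin(img, seed = 1)
  iou <- sum(mask & blob) / sum(mask | blob)
  expect_gte(iou, 0.98)
})

test_that("skin detection reaches IoU 0.9 on default synthetic faces", {
  fx <- generate_face(face_spec("normal", seed = 17))
  sp <- skin_pixels(fx$image, fx$mouth_box)
  gt <- downscale_mask(fx$skin_mask, 8)
  expect_gte(sum(sp$mask & gt) / sum(sp$mask | gt), 0.9)
})

test_that("impossible thresholds and degenerate images raise errors", {
  img <- array(as.integer(sample(0:255, 48 * 48 * 3, TRUE)), c(48, 48, 3))
  expect_error(detect_skin(img, skin_detector_params(density_threshold = 1)),
               "no pixel passed")
  expect_error(detect_skin(array(100L, c(32, 32, 3))), "single-color")
  expect_error(skin_detector_params(density_threshold = 0), "0, 1")
  expect_error(skin_detector_params(histogram_bins = 4), ">= 8")
})

test_that("mouth exclusion is exact set subtraction", {
  mask <- matrix(TRUE, 40, 40)
  out <- exclude_mouth(mask, c(11, 11, 14, 20))
  expect_equal(sum(mask) - sum(out), 4 * 10)
  expect_false(any(out[11:14, 11:20]))
  out[11:14, 11:20] <- TRUE
  expect_true(all(out))

  # zero-area box leaves the mask unchanged
  expect_identical(exclude_mouth(mask, c(5, 5, 4, 10)), mask)
  expect_identical(exclude_mouth(mask, NULL), mask)

  expect_error(exclude_mouth(mask, c(0, 1, 5, 5)), "bounds")
  expect_error(exclude_mouth(mask, c(1, 1, 50, 5)), "bounds")
  expect_error(exclude_mouth(mask, c(1, 2, 3)), "row0")
})

test_that("no lip pixels survive mouth exclusion on fixtures", {
  fx <- generate_face(face_spec("red", seed = 6, image_size = c(128, 128)))
  mask <- matrix(TRUE, 128, 128)
  out <- exclude_mouth(mask, fx$mouth_box)
  # the generator's lip ellipse lies inside the mouth box
  lip_rows <- (fx$mouth_box[1]):(fx$mouth_box[3])
  expect_false(any(out[lip_rows, fx$mouth_box[2]:fx$mouth_box[4]]))
})

test_that("denoising trims the declared luminance tails", {
  set.seed(3)
  lab <- cbind(runif(1000, 0, 100), rnorm(1000), rnorm(1000))
  out <- denoise_extremes(lab, 0.01, 0.01)
  expect_gte(nrow(out), 979)
  expect_lte(nrow(out), 981)

  expect_identical(denoise_extremes(lab, 0, 0), structure(lab, kept = rep(TRUE, 1000)))

  # planted near-black artifacts fall in the removed tail
  lab2 <- cbind(c(rnorm(4995, 60, 5), rep(8, 5)), rnorm(5000), rnorm(5000))
  out2 <- denoise_extremes(lab2, 0.01, 0.01)
  expect_true(all(out2[, 1] > 20))
  # never removes more than the tails plus ties
  expect_lte(nrow(lab2) - nrow(out2), ceiling(0.02 * 5000) + 5)

  expect_error(denoise_extremes(lab, 0.3, 0.1), "0, 0.2")
  expect_error(denoise_extremes(lab, 0.2, 0.2), NA)
})

test_that("extract_skin_pixels returns masked pixels in row-major order", {
  img <- array(0L, c(2, 3, 3))
  img[, , 1] <- matrix(c(10L, 20L, 30L, 40L, 50L, 60L), 2, 3, byrow = TRUE)
  img[, , 2] <- 100L
  img[, , 3] <- 200L
  mask <- matrix(c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE), 2, 3, byrow = TRUE)
  lab <- extract_skin_pixels(img, mask)
  expect_equal(nrow(lab), sum(mask))
  expected <- rgb_to_lab(cbind(c(10, 30, 40, 60), 100, 200), bit8 = TRUE)
  expect_equal(lab, expected)

  flat <- array(120L, c(4, 4, 3))
  lab_flat <- extract_skin_pixels(flat, matrix(TRUE, 4, 4))
  expect_equal(nrow(unique(lab_flat)), 1)

  expect_error(extract_skin_pixels(flat, matrix(FALSE, 4, 4)), "empty mask")
  expect_error(extract_skin_pixels(flat, matrix(TRUE, 2, 2)), "shape")
})

test_that("the pipeline is deterministic given image, params, and seed", {
  fx <- generate_face(face_spec("cyan", seed = 12, image_size = c(128, 128)))
  cfg <- complexion_config(downscale_factor = 4L)
  a <- skin_pixels(fx$image, fx$mouth_box, cfg, seed = 5)
  b <- skin_pixels(fx$image, fx$mouth_box, cfg, seed = 5)
  expect_identical(a$mask, b$mask)
  expect_identical(a$lab, b$lab)
})
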