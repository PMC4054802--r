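test_that("feature_length reproduces every layout dimension", {
  # brute-force enumeration of bin edges as the oracle
  for (iv in c(1, 2, 3, 5, 7, 10, 14, 23, 35)) {
    bn <- luminance_binning(25, 95, iv)
    edges <- seq(25, by = iv, length.out = floor(70 / iv) + 1)
    expect_equal(bn$edges, edges)
    expect_equal(feature_length(bn, TRUE), 4 * (length(edges) - 1) + 4)
    expect_equal(feature_length(bn, FALSE), 4 * (length(edges) - 1))
  }
  expect_equal(feature_length(luminance_binning(0, 100, 10), FALSE), 40L)
  expect_equal(feature_length(luminance_binning(25, 95, 14), TRUE), 24L)
  expect_equal(feature_length(luminance_binning(25, 95, 1), TRUE), 284L)
  expect_equal(feature_length(luminance_binning(25, 95, 35), TRUE), 12L)
  expect_error(luminance_binning(95, 25), "exceed")
  expect_error(luminance_binning(25, 95, 80), "interval")
})

test_that("assign_pixels puts forced pixels in the right sub-bin", {
  bases <- mini_bases()
  bm <- base_matrix(bases)
  # all pixels exactly at the yellow base with L = 50: sub-bin 39-53
  px <- cbind(rep(50, 100), rep(bm["yellow", "a"], 100),
              rep(bm["yellow", "b"], 100))
  h <- assign_pixels(px, bases, luminance_binning(25, 95, 14))
  expect_equal(unname(h$values[["yellow.base"]]), 1)
  expect_equal(unname(h$values[["yellow.L39_53"]]), 1)
  expect_equal(sum(h$values), 2)
  expect_equal(length(h$values), 24)

  # luminance outside the range is clamped into the boundary bins
  px2 <- cbind(c(2, 99), rep(bm["red", "a"], 2), rep(bm["red", "b"], 2))
  h2 <- assign_pixels(px2, bases, luminance_binning(25, 95, 14))
  expect_equal(unname(h2$values[["red.L25_39"]]), 0.5)
  expect_equal(unname(h2$values[["red.L81_95"]]), 0.5)

  expect_error(assign_pixels(px[0, ], bases), "empty")
})

test_that("normalization identities hold for random pixels", {
  set.seed(14)
  bases <- mini_bases()
  px <- cbind(runif(500, 20, 90), rnorm(500, 12, 8), rnorm(500, 15, 8))
  h <- assign_pixels(px, bases, luminance_binning(25, 95, 14), TRUE, TRUE)
  agg <- h$values[seq(1, 24, by = 6)]
  expect_equal(sum(agg), 1, tolerance = 1e-9)
  expect_equal(sum(h$values) - sum(agg), 1, tolerance = 1e-9)

  # permutation invariance
  h2 <- assign_pixels(px[sample(500), ], bases, luminance_binning(25, 95, 14))
  expect_equal(h$values, h2$values)

  # restoring counts via n_pixels and renormalizing is the identity
  counts <- h$values * h$n_pixels
  expect_equal(counts / h$n_pixels, h$values, tolerance = 1e-9)
  expect_true(all(abs(counts - round(counts)) < 1e-9))

  # chromaticity-only view equals the aggregate bins
  c4 <- chromaticity_only_histogram(px, bases)
  expect_equal(unname(c4), unname(agg), tolerance = 1e-12)
  expect_length(c4, 4)
})

test_that("luminance merging sums sub-bins over bases and regions", {
  set.seed(15)
  bases <- mini_bases()
  bn <- luminance_binning(25, 95, 14)
  px <- cbind(runif(400, 20, 90), rnorm(400, 12, 8), rnorm(400, 15, 8))
  h <- assign_pixels(px, bases, bn)
  lum <- luminance_only_histogram(h)
  expect_equal(sum(lum), 1, tolerance = 1e-9)

  # all mass at the top bin
  top <- assign_pixels(cbind(rep(94, 50), rnorm(50, 13), rnorm(50, 16)),
                       bases, bn)
  lt <- luminance_only_histogram(top)
  expect_equal(unname(lt[5]), 1)
  expect_equal(sum(lt[1:4]), 0)
})

test_that("region segmentation splits the bounding box proportionally", {
  mask <- matrix(FALSE, 120, 110)
  mask[11:110, 6:105] <- TRUE  # a 100 x 100 rectangle
  part <- segment_regions(mask)
  areas <- vapply(part, sum, 0L)
  expect_equal(unname(areas["forehead"]), 33 * 100)
  expect_equal(unname(areas["left_cheek"]), 42 * 35)
  expect_equal(unname(areas["nose"]), 42 * 30)
  expect_equal(unname(areas["right_cheek"]), 42 * 35)
  expect_equal(unname(areas["jaw"]), 25 * 100)
  expect_equal(sum(areas), sum(mask))

  # pairwise disjoint and within the mask
  stack <- Reduce(`+`, lapply(part, function(m) m * 1))
  expect_true(all(stack <= 1))
  expect_true(all(stack[!mask] == 0))

  # a hole in the nose block shrinks only the nose region
  mask2 <- mask
  mask2[55:70, 50:60] <- FALSE
  part2 <- segment_regions(mask2)
  areas2 <- vapply(part2, sum, 0L)
  expect_lt(areas2["nose"], areas["nose"])
  expect_equal(unname(areas2["forehead"]), unname(areas["forehead"]))
  expect_equal(unname(areas2["jaw"]), unname(areas["jaw"]))

  expect_error(segment_regions(matrix(FALSE, 5, 5)), "empty")
})

test_that("fixture masks yield five non-empty disjoint regions", {
  rec <- mini_pixels()[[1]]
  part <- segment_regions(rec$mask)
  expect_true(all(vapply(part, sum, 0L) > 0))
  stack <- Reduce(`+`, lapply(part, function(m) m * 1))
  expect_true(all(stack <= 1))
})

test_that("regional histograms and fusion follow the weighted layout", {
  bases <- mini_bases()
  bn <- luminance_binning(25, 95, 14)
  # uniform-color face: five identical histograms
  img <- array(0L, c(40, 40, 3))
  img[, , 1] <- 180L; img[, , 2] <- 120L; img[, , 3] <- 100L
  mask <- matrix(FALSE, 40, 40); mask[5:36, 5:36] <- TRUE
  part <- segment_regions(mask)
  hs <- regional_histograms(img, part, bases, bn)
  for (rg in names(hs)[-1]) expect_equal(hs[[rg]]$values, hs[[1]]$values,
                                         ignore_attr = TRUE)
  for (rg in names(hs))
    expect_equal(sum(hs[[rg]]$values[seq(1, 24, by = 6)]), 1,
                 tolerance = 1e-9)

  fused <- fuse_features(hs, region_weights_default())
  expect_length(fused$values, 120)
  w <- region_weights_default()
  for (rg in names(w)) {
    block <- fused$values[grepl(paste0("^", rg, "\\."), names(fused$values))]
    expect_equal(unname(block), unname(w[[rg]] * hs[[rg]]$values))
  }
  # total aggregate mass across regions is 1 with no renormalization
  agg_idx <- grepl("\\.base$", names(fused$values))
  expect_equal(sum(fused$values[agg_idx]), 1, tolerance = 1e-9)

  badw <- region_weights_default(); badw["jaw"] <- 0.5
  expect_error(fuse_features(hs, badw), "sum to 1")
})

test_that("regional aggregate proportions reconcile with the whole face", {
  rec <- mini_pixels()[[3]]
  bases <- mini_bases()
  bn <- luminance_binning(25, 95, 14)
  part <- segment_regions(rec$mask)
  hs <- regional_histograms(rec$small, part, bases, bn)
  # pixel-count weighted sum over regions equals the tiled whole-face bins
  tiled <- Reduce(`|`, part)
  whole <- assign_pixels(extract_skin_pixels(rec$small, tiled), bases, bn)
  npx <- vapply(hs, `[[`, 0, "n_pixels")
  mix <- Reduce(`+`, lapply(names(hs), function(rg)
    hs[[rg]]$values * npx[[rg]]))/sum(npx)
  expect_equal(unname(mix), unname(whole$values), tolerance = 1e-9)
})
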