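#' Luminance binning of the complexion histogram
#'
#' Splits each chromaticity base into `K = floor((hi - lo) / interval)`
#' luminance sub-bases. The refined default spans L = 25 to 95 with
#' interval 14 (5 sub-bins per base); the coarse preliminary layout spans
#' 0 to 100 with interval 10.
#'
#' @param lo,hi Luminance range endpoints in `[0, 100]`, `hi > lo`.
#' @param interval Bin width, `0 < interval <= hi - lo`.
#' @return List of class `luminance_binning` with `lo`, `hi`, `interval`,
#'   `K`, and `edges`.
#' @export
luminance_binning <- function(lo = 25, hi = 95, interval = 14) {
  if (hi <= lo) stop("hi must exceed lo")
  if (interval <= 0 || interval > hi - lo)
    stop("interval must lie in (0, hi - lo]")
  k <- floor((hi - lo) / interval)
  structure(list(lo = lo, hi = hi, interval = interval, K = as.integer(k),
                 edges = lo + interval * (0:k)),
            class = "luminance_binning")
}

#' Feature-vector length of a complexion histogram
#'
#' `4 K` sub-bins, plus one aggregate bin per base when
#' `include_base_bins`: 40 for the coarse 0-100/10 layout, 24 for the
#' refined 25-95/14 layout, 12 and 284 at the sweep endpoints
#' (intervals 35 and 1).
#'
#' @param binning A [luminance_binning()].
#' @param include_base_bins Whether per-base aggregate bins are included.
#' @return Integer feature count.
#' @export
feature_length <- function(binning, include_base_bins = TRUE) {
  stopifnot(inherits(binning, "luminance_binning"))
  4L * binning$K + if (include_base_bins) 4L else 0L
}

.hist_names <- function(binning, include_base_bins) {
  sub <- paste0("L", head(binning$edges, -1), "_",
                binning$edges[-1])
  unlist(lapply(.BASE_CLASSES, function(g)
    paste(g, if (include_base_bins) c("base", sub) else sub, sep = ".")))
}

.new_histogram <- function(values, binning, include_base_bins, n_pixels,
                           normalized, n_regions = 1L, region_weights = NULL) {
  structure(list(values = values, binning = binning,
                 include_base_bins = include_base_bins,
                 n_pixels = n_pixels, normalized = normalized,
                 n_regions = n_regions, region_weights = region_weights),
            class = "complexion_histogram")
}

#' @export
print.complexion_histogram <- function(x, ...) {
  cat(sprintf(paste0("complexion histogram: %d features (%d region%s, K = ",
                     "%d%s), %d pixels\n"),
              length(x$values), x$n_regions, if (x$n_regions > 1) "s" else "",
              x$binning$K, if (x$include_base_bins) " + base bins" else "",
              x$n_pixels))
  invisible(x)
}

#' Quantize skin pixels into a complexion histogram
#'
#' Each pixel is assigned to its nearest chromaticity base by Euclidean
#' distance in the `(a, b)` plane; its luminance (clamped to the binning
#' range) selects the sub-bin `min(floor((L - lo) / interval), K - 1)`.
#' Counts go to that base's sub-bin and, when `include_base_bins`, also to
#' the base's aggregate bin. With `normalize`, every bin is divided by the
#' pixel count, so aggregate bins sum to 1 and sub-bins sum to 1.
#'
#' @param lab_pixels Non-empty `N x 3` Lab matrix.
#' @param bases A `base_set`.
#' @param binning A [luminance_binning()].
#' @param include_base_bins Include per-base aggregate bins.
#' @param normalize Divide by the pixel count.
#' @return A `complexion_histogram`.
#' @export
assign_pixels <- function(lab_pixels, bases, binning = luminance_binning(),
                          include_base_bins = TRUE, normalize = TRUE) {
  if (is.null(dim(lab_pixels)) || nrow(lab_pixels) == 0)
    stop("empty pixel input")
  bm <- base_matrix(bases)
  d2 <- outer(rowSums(lab_pixels[, 2:3, drop = FALSE]^2), rep(1, 4)) +
    outer(rep(1, nrow(lab_pixels)), rowSums(bm^2)) -
    2 * lab_pixels[, 2:3, drop = FALSE] %*% t(bm)
  g <- max.col(-d2, ties.method = "first")
  l <- pmin(pmax(lab_pixels[, 1], binning$lo), binning$hi)
  j <- pmin(floor((l - binning$lo) / binning$interval), binning$K - 1L) + 1L
  k <- binning$K
  counts <- tabulate((g - 1L) * k + j, nbins = 4L * k)
  n <- nrow(lab_pixels)
  if (include_base_bins) {
    agg <- tabulate(g, nbins = 4L)
    vals <- numeric(4L * (k + 1L))
    for (gg in 1:4) {
      vals[(gg - 1L) * (k + 1L) + 1L] <- agg[gg]
      vals[(gg - 1L) * (k + 1L) + 1L + seq_len(k)] <-
        counts[(gg - 1L) * k + seq_len(k)]
    }
  } else {
    vals <- counts
  }
  if (normalize) vals <- vals / n
  names(vals) <- .hist_names(binning, include_base_bins)
  .new_histogram(vals, binning, include_base_bins, n, normalize)
}

#' Four-bin chromaticity-only histogram
#'
#' Nearest-base assignment without any luminance split; the normalized
#' per-base pixel proportions used by the color-degree ranking. Identical
#' to the aggregate bins of [assign_pixels()].
#'
#' @inheritParams assign_pixels
#' @return Named length-4 numeric vector in canonical base order.
#' @export
chromaticity_only_histogram <- function(lab_pixels, bases) {
  h <- assign_pixels(lab_pixels, bases, luminance_binning(0, 100, 100),
                     include_base_bins = TRUE, normalize = TRUE)
  setNames(h$values[seq(1, 8, by = 2)], .BASE_CLASSES)
}

#' Merge a complexion histogram into a luminance-only histogram
#'
#' Sums the sub-bins over the four bases (and over regions, for a fused
#' histogram), dropping aggregate bins: the pure luminance distribution
#' used by the gloss score.
#'
#' @param hist A `complexion_histogram` (whole-face or fused).
#' @return Named length-`K` numeric vector.
#' @export
luminance_only_histogram <- function(hist) {
  stopifnot(inherits(hist, "complexion_histogram"))
  k <- hist$binning$K
  block <- k + if (hist$include_base_bins) 1L else 0L
  vals <- hist$values
  out <- numeric(k)
  n_blocks <- 4L * hist$n_regions
  for (bidx in seq_len(n_blocks)) {
    off <- (bidx - 1L) * block + if (hist$include_base_bins) 1L else 0L
    out <- out + vals[off + seq_len(k)]
  }
  names(out) <- paste0("L", head(hist$binning$edges, -1), "_",
                       hist$binning$edges[-1])
  out
}

.REGION_ORDER <- c("left_cheek", "right_cheek", "forehead", "nose", "jaw")

#' Default facial-region weights
#'
#' Cheeks 0.3 each, forehead and nose 0.1, jaw 0.2 (weights reflect the
#' regions' relative classification value).
#'
#' @return Named numeric vector over the five regions, summing to 1.
#' @export
region_weights_default <- function() {
  c(left_cheek = 0.3, right_cheek = 0.3, forehead = 0.1, nose = 0.1,
    jaw = 0.2)
}

#' Segment a skin mask into five facial regions
#'
#' Closes the mask morphologically (square structuring element of side
#' about 3 percent of the bounding-box height, minimum 3), takes the
#' bounding rectangle of the closed skin, splits it by fixed proportions
#' (forehead: top 33 percent of rows; cheeks/nose: rows 33-75 percent with
#' columns split 35/30/35 percent; jaw: bottom 25 percent), and intersects
#' each block with the original mask.
#'
#' @param mask Non-empty logical skin mask.
#' @param closing_size Optional structuring-element side override.
#' @return List of class `region_partition`: five logical masks in fixed
#'   order (left_cheek, right_cheek, forehead, nose, jaw) plus attribute
#'   `bbox`.
#' @export
segment_regions <- function(mask, closing_size = NULL) {
  if (!any(mask)) stop("empty mask cannot be segmented")
  rows0 <- range(which(rowSums(mask) > 0))
  if (is.null(closing_size))
    closing_size <- max(3L, round(0.03 * diff(rows0)))
  if (closing_size %% 2 == 0) closing_size <- closing_size + 1L
  closed <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(closing_size, "box"))
  closed <- EBImage::imageData(closed) > 0.5
  rr <- range(which(rowSums(closed) > 0))
  cc <- range(which(colSums(closed) > 0))
  h <- rr[2] - rr[1] + 1
  w <- cc[2] - cc[1] + 1
  row_cut <- rr[1] - 1 + c(floor(0.33 * h), floor(0.75 * h))
  col_cut <- cc[1] - 1 + c(floor(0.35 * w), floor(0.65 * w))

  blank <- function() matrix(FALSE, nrow(mask), ncol(mask))
  block <- function(r1, r2, c1, c2) {
    m <- blank()
    if (r2 >= r1 && c2 >= c1) m[r1:r2, c1:c2] <- TRUE
    m & mask
  }
  parts <- list(
    left_cheek  = block(row_cut[1] + 1, row_cut[2], cc[1], col_cut[1]),
    right_cheek = block(row_cut[1] + 1, row_cut[2], col_cut[2] + 1, cc[2]),
    forehead    = block(rr[1], row_cut[1], cc[1], cc[2]),
    nose        = block(row_cut[1] + 1, row_cut[2], col_cut[1] + 1, col_cut[2]),
    jaw         = block(row_cut[2] + 1, rr[2], cc[1], cc[2])
  )
  parts <- parts[.REGION_ORDER]
  attr(parts, "bbox") <- c(rr[1], cc[1], rr[2], cc[2])
  class(parts) <- "region_partition"
  parts
}

#' Per-region complexion histograms
#'
#' Builds one normalized complexion histogram (with aggregate bins) per
#' facial region.
#'
#' @param image `H x W x 3` 8-bit RGB array aligned with the partition
#'   masks, or a precomputed `H x W x 3` Lab array.
#' @param partition A [segment_regions()] result.
#' @param bases A `base_set`.
#' @param binning A [luminance_binning()].
#' @param lab_image Set `TRUE` when `image` already holds Lab values.
#' @return Named list of five `complexion_histogram`s in region order.
#' @export
regional_histograms <- function(image, partition, bases,
                                binning = luminance_binning(),
                                lab_image = FALSE) {
  stopifnot(inherits(partition, "region_partition"))
  px <- pixel_matrix(image)
  lab_all <- if (lab_image) px else rgb_to_lab(px, bit8 = TRUE)
  out <- lapply(.REGION_ORDER, function(rg) {
    sel <- as.vector(t(partition[[rg]]))
    if (!any(sel)) stop("region '", rg, "' contains no skin pixels")
    assign_pixels(lab_all[sel, , drop = FALSE], bases, binning,
                  include_base_bins = TRUE, normalize = TRUE)
  })
  names(out) <- .REGION_ORDER
  out
}

#' Fuse regional histograms into one weighted feature vector
#'
#' Concatenates `weight * histogram` blocks in fixed region order
#' (left_cheek, right_cheek, forehead, nose, jaw). Because the weights sum
#' to 1 and each regional histogram is normalized, the total aggregate-bin
#' mass of the fused vector is 1 by construction and no renormalization is
#' applied. With the refined 24-dimensional regional layout the fused
#' vector has 120 dimensions.
#'
#' @param histograms Named list of five regional `complexion_histogram`s.
#' @param weights Named region weights summing to 1 (within 1e-6).
#' @return A fused `complexion_histogram` with `n_regions = 5`.
#' @export
fuse_features <- function(histograms, weights = region_weights_default()) {
  if (!all(.REGION_ORDER %in% names(histograms)))
    stop("histograms must be named with the five regions")
  if (!all(.REGION_ORDER %in% names(weights)) ||
      abs(sum(weights[.REGION_ORDER]) - 1) > 1e-6)
    stop("region weights must cover all five regions and sum to 1")
  h1 <- histograms[[.REGION_ORDER[1]]]
  vals <- unlist(lapply(.REGION_ORDER, function(rg) {
    h <- histograms[[rg]]
    if (h$binning$K != h1$binning$K ||
        h$include_base_bins != h1$include_base_bins)
      stop("regional histograms disagree on binning/layout")
    v <- weights[[rg]] * h$values
    names(v) <- paste(rg, names(h$values), sep = ".")
    v
  }))
  .new_histogram(vals, h1$binning, h1$include_base_bins,
                 sum(vapply(histograms, `[[`, 0, "n_pixels")),
                 normalized = TRUE, n_regions = 5L,
                 region_weights = weights[.REGION_ORDER])
}

#' Region-fused complexion histogram of one face
#'
#' Convenience composition: [segment_regions()] on the skin mask,
#' [regional_histograms()] on the image, and [fuse_features()].
#'
#' @param image 8-bit RGB image aligned with `mask` (typically the
#'   downscaled image from [skin_pixels()]).
#' @param mask Logical skin mask.
#' @param bases A `base_set`.
#' @param binning A [luminance_binning()].
#' @param weights Region weights.
#' @return A fused `complexion_histogram` (120 features under the refined
#'   layout).
#' @export
fused_histogram <- function(image, mask, bases,
                            binning = luminance_binning(),
                            weights = region_weights_default()) {
  part <- segment_regions(mask)
  fuse_features(regional_histograms(image, part, bases, binning), weights)
}

#' Fused histograms for every face of a processed cohort
#'
#' @param cohort A [cohort_pixels()] result.
#' @param bases A `base_set`.
#' @param binning A [luminance_binning()].
#' @param weights Region weights.
#' @return List of fused `complexion_histogram`s.
#' @export
cohort_fused_histograms <- function(cohort, bases,
                                    binning = luminance_binning(),
                                    weights = region_weights_default()) {
  stopifnot(inherits(cohort, "complexion_cohort"))
  lapply(cohort, function(rec)
    fused_histogram(rec$small, rec$mask, bases, binning, weights))
}
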