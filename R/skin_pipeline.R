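.block_mean <- function(m, f) {
  h <- nrow(m) %/% f * f
  w <- ncol(m) %/% f * f
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  ## average f x f blocks: fold rows, then columns
  m <- matrix(colMeans(matrix(m, nrow = f)), nrow = h %/% f, ncol = w)
  t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = w %/% f, ncol = h %/% f))
}

#' Downscale an image by block averaging
#'
#' Each `factor x factor` block is replaced by its channel mean, reducing
#' each dimension by `factor` (trailing rows/columns that do not fill a
#' block are dropped).
#'
#' @param image `H x W x 3` array (any numeric scale) or `H x W` matrix.
#' @param factor Integer >= 1.
#' @return Downscaled array/matrix of the same numeric type semantics;
#'   integer 8-bit input yields rounded integer output.
#' @export
downscale <- function(image, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  d <- dim(image)
  if (factor > min(d[1], d[2]))
    stop("factor exceeds the image dimensions")
  if (factor == 1L) return(image)
  int_in <- is.integer(image)
  out <- if (length(d) == 3L) {
    res <- vapply(seq_len(d[3]), function(k) .block_mean(image[, , k], factor),
                  matrix(0, d[1] %/% factor, d[2] %/% factor))
    array(res, c(d[1] %/% factor, d[2] %/% factor, d[3]))
  } else {
    .block_mean(image, factor)
  }
  if (int_in) {
    out_i <- as.integer(round(out))
    dim(out_i) <- dim(out)
    out <- out_i
  }
  out
}

#' Downscale a logical mask or a mouth box to a reduced grid
#'
#' A block counts as mask when more than half of its pixels are set.
#'
#' @param mask Logical matrix.
#' @param factor Integer >= 1.
#' @return Logical matrix of reduced size.
#' @export
downscale_mask <- function(mask, factor) {
  if (factor == 1L) return(mask)
  .block_mean(mask * 1, factor) > 0.5
}

#' @rdname downscale_mask
#' @param box `c(row0, col0, row1, col1)` on the full-resolution grid.
#' @export
downscale_box <- function(box, factor) {
  c(floor((box[1] - 1) / factor) + 1, floor((box[2] - 1) / factor) + 1,
    ceiling(box[3] / factor), ceiling(box[4] / factor))
}

#' Skin-detector parameters
#'
#' Parameters of the fused histogram + Gaussian-mixture skin detector; see
#' [detect_skin()]. All statistics are fit on the input image itself, so no
#' training stage or external skin corpus is involved.
#'
#' @param histogram_bins Bin count per axis of the 2D `(I, By)` histogram.
#' @param smoothing_sigma Gaussian smoothing width, in bins.
#' @param density_threshold Minimum smoothed density relative to the modal
#'   bin (in `(0, 1)`).
#' @param gmm_components Mixture components (the detector separates skin
#'   from background, so 2).
#' @param gmm_posterior_threshold Minimum posterior of the skin component.
#' @param fusion_rule `"OR"` (detection-favoring, default) or `"AND"`.
#' @return List of class `skin_detector_params`.
#' @export
skin_detector_params <- function(histogram_bins = 24L, smoothing_sigma = 2.5,
                                 density_threshold = 0.15,
                                 gmm_components = 2L,
                                 gmm_posterior_threshold = 0.5,
                                 fusion_rule = c("OR", "AND")) {
  fusion_rule <- match.arg(fusion_rule)
  if (histogram_bins < 8) stop("histogram_bins must be >= 8")
  if (density_threshold <= 0 || density_threshold > 1)
    stop("density_threshold must lie in (0, 1]")
  if (gmm_posterior_threshold <= 0 || gmm_posterior_threshold >= 1)
    stop("gmm_posterior_threshold must lie in (0, 1)")
  p <- list(histogram_bins = as.integer(histogram_bins),
            smoothing_sigma = smoothing_sigma,
            density_threshold = density_threshold,
            gmm_components = as.integer(gmm_components),
            gmm_posterior_threshold = gmm_posterior_threshold,
            fusion_rule = fusion_rule)
  class(p) <- "skin_detector_params"
  p
}

## separable Gaussian smoothing of a matrix (reflected edges)
.smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rev(v[seq_len(r)]), v, rev(v[length(v) - seq_len(r) + 1]))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

.bin_index <- function(x, breaks) {
  pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
       length(breaks) - 1L)
}

#' Detect skin pixels by fused histogram and Gaussian-mixture evidence
#'
#' A pixel counts as skin when (histogram rule) the smoothed 2D histogram
#' density over its `(I, By)` log-opponent bin exceeds
#' `density_threshold` (relative to the modal bin) within the connected
#' above-threshold region containing the modal bin, and/or (mixture rule)
#' its posterior under the skin component of a Gaussian mixture fit to the
#' `(Rg, By)` coordinates exceeds `gmm_posterior_threshold`; the two rules
#' are combined with `fusion_rule`. The skin component is the one whose
#' members' mean `(I, By)` position has the larger smoothed histogram
#' density. Everything is estimated from the input image itself.
#'
#' @param image `H x W x 3` 8-bit RGB array.
#' @param params A [skin_detector_params()].
#' @param seed Seed for the mixture-fit subsample.
#' @return Logical `H x W` skin mask (class `skin_mask` semantics: at least
#'   one pixel must be skin, else an error).
#' @export
detect_skin <- function(image, params = skin_detector_params(), seed = 1L) {
  stopifnot(length(dim(image)) == 3L)
  d <- dim(image)
  px <- pixel_matrix(image)
  if (all(apply(px, 2, function(ch) diff(range(ch)) == 0)))
    stop("degenerate single-color image: zero-variance fit is impossible")
  lo <- rgb_to_log_opponent(px)

  nb <- params$histogram_bins
  bx <- seq(min(lo[, "I"]), max(lo[, "I"]), length.out = nb + 1)
  by <- seq(min(lo[, "By"]), max(lo[, "By"]), length.out = nb + 1)
  ix <- .bin_index(lo[, "I"], bx)
  iy <- .bin_index(lo[, "By"], by)
  hist2 <- matrix(0, nb, nb)
  tab <- table(factor(ix, levels = seq_len(nb)),
               factor(iy, levels = seq_len(nb)))
  hist2[] <- as.numeric(tab)
  dens <- .smooth2d(hist2, params$smoothing_sigma)
  dens <- dens / max(dens)
  ## the skin locus is modeled as the connected above-threshold region
  ## around the modal bin; other dense modes (background) are rejected
  above <- dens > params$density_threshold
  lab_cc <- EBImage::bwlabel(EBImage::Image(above * 1))
  lab_cc <- EBImage::imageData(lab_cc)
  region_mass <- vapply(seq_len(max(lab_cc)), function(l)
    sum(hist2[lab_cc == l]), numeric(1))
  if (length(region_mass) == 0)
    stop("no pixel passed the skin detector; lower density_threshold ",
         "or gmm_posterior_threshold")
  skin_region <- lab_cc == which.max(region_mass)
  hist_skin <- skin_region[cbind(ix, iy)]

  ## Gaussian mixture on (Rg, By), fit on a seeded subsample for speed,
  ## posteriors evaluated for every pixel
  feat <- lo[, c("Rg", "By")]
  n <- nrow(feat)
  sub <- if (n > 2000) withr::with_seed(seed, sample.int(n, 2000)) else seq_len(n)
  fit <- tryCatch(
    Mclust(feat[sub, ], G = params$gmm_components,
           modelNames = "VVI", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    stop("Gaussian mixture fit failed (possibly degenerate chromaticity)")
  z <- predict(fit, newdata = feat)$z
  comp <- max.col(z, ties.method = "first")
  ## the skin component is the one whose members sit at the larger skin-locus
  ## histogram density (density outside the modal connected region is zero,
  ## so a component centered on the background mode can never win)
  dens_skin <- dens * skin_region
  comp_density <- vapply(seq_len(ncol(z)), function(k) {
    if (!any(comp == k)) return(-Inf)
    mu <- colMeans(lo[comp == k, c("I", "By"), drop = FALSE])
    dens_skin[.bin_index(mu[1], bx), .bin_index(mu[2], by)]
  }, numeric(1))
  skin_comp <- which.max(comp_density)
  gmm_skin <- z[, skin_comp] > params$gmm_posterior_threshold

  skin <- if (params$fusion_rule == "OR") hist_skin | gmm_skin
          else hist_skin & gmm_skin
  if (!any(skin))
    stop("no pixel passed the skin detector; lower density_threshold ",
         "or gmm_posterior_threshold")
  ## pixel_matrix order is row-major; map back to the H x W grid
  mask <- matrix(skin, nrow = d[1], byrow = TRUE)
  mask
}

#' Remove a rectangular mouth region from a skin mask
#'
#' @param mask Logical skin mask.
#' @param mouth_box `c(row0, col0, row1, col1)` inclusive, or `NULL` for no
#'   exclusion. A degenerate box (`row1 < row0` or `col1 < col0`) has zero
#'   area and leaves the mask unchanged.
#' @return The mask with all box pixels set `FALSE`.
#' @export
exclude_mouth <- function(mask, mouth_box) {
  if (is.null(mouth_box)) return(mask)
  if (length(mouth_box) != 4 || anyNA(mouth_box))
    stop("mouth_box must be c(row0, col0, row1, col1)")
  if (mouth_box[3] < mouth_box[1] || mouth_box[4] < mouth_box[2])
    return(mask)  # zero-area box
  if (mouth_box[1] < 1 || mouth_box[2] < 1 ||
      mouth_box[3] > nrow(mask) || mouth_box[4] > ncol(mask))
    stop("mouth_box exceeds the mask bounds")
  mask[mouth_box[1]:mouth_box[3], mouth_box[2]:mouth_box[4]] <- FALSE
  mask
}

#' Remove extreme-luminance pixels via the cumulative distribution
#'
#' Drops pixels whose `L` lies below the `low_tail` quantile or above the
#' `1 - high_tail` quantile of the cumulative luminance distribution;
#' removes scattered dark spots (moles, hair) and specular highlights.
#'
#' @param lab_pixels `N x 3` Lab matrix.
#' @param low_tail,high_tail Tail proportions in `[0, 0.2]`, summing to
#'   less than 1.
#' @return The surviving rows, with attribute `kept` (logical index).
#' @export
denoise_extremes <- function(lab_pixels, low_tail = 0.01, high_tail = 0.01) {
  if (low_tail < 0 || low_tail > 0.2 || high_tail < 0 || high_tail > 0.2)
    stop("tail proportions must lie in [0, 0.2]")
  if (low_tail + high_tail >= 1) stop("tails must sum to less than 1")
  l <- lab_pixels[, 1]
  qs <- quantile(l, c(low_tail, 1 - high_tail), names = FALSE, type = 7)
  keep <- l >= qs[1] & l <= qs[2]
  out <- lab_pixels[keep, , drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' Extract masked pixels as CIELAB rows
#'
#' @param image `H x W x 3` 8-bit RGB array.
#' @param mask Logical `H x W` mask with at least one `TRUE` pixel.
#' @return `N x 3` Lab matrix, pixels in row-major order.
#' @export
extract_skin_pixels <- function(image, mask) {
  d <- dim(image)
  if (!all(dim(mask) == d[1:2])) stop("mask shape must match the image")
  if (!any(mask)) stop("empty mask: no skin pixels to extract")
  px <- pixel_matrix(image)
  sel <- as.vector(t(mask))  # row-major order, matching pixel_matrix
  rgb_to_lab(px[sel, , drop = FALSE], bit8 = TRUE)
}

#' Run the whole skin pipeline on one face
#'
#' Downscale, detect skin, exclude the mouth box, convert to Lab, and
#' denoise luminance extremes.
#'
#' @param image `H x W x 3` 8-bit RGB array.
#' @param mouth_box Full-resolution mouth box, or `NULL`.
#' @param config A [complexion_config()].
#' @param seed Seed for the detector's mixture fit.
#' @return List with `lab` (denoised skin pixels), `mask` (downscaled-grid
#'   skin mask after mouth exclusion and luminance denoising), `small` (the
#'   downscaled image), and `factor`.
#' @export
skin_pixels <- function(image, mouth_box = NULL,
                        config = complexion_config(), seed = 1L) {
  f <- config$downscale_factor
  small <- downscale(image, f)
  params <- skin_detector_params(
    histogram_bins = config$histogram_bins,
    smoothing_sigma = config$smoothing_sigma,
    density_threshold = config$density_threshold,
    gmm_posterior_threshold = config$gmm_posterior_threshold,
    fusion_rule = config$fusion_rule)
  mask <- detect_skin(small, params, seed = seed)
  if (!is.null(mouth_box)) {
    box <- if (f > 1) downscale_box(mouth_box, f) else mouth_box
    mask <- exclude_mouth(mask, box)
  }
  denoise_mask(small, mask, config)
}

#' Convert a masked image to denoised Lab skin pixels
#'
#' Shared tail of the skin pipeline: extract Lab pixels under the mask,
#' drop luminance extremes, and reflect the dropped pixels in the mask.
#'
#' @param small Downscaled 8-bit RGB image.
#' @param mask Logical skin mask on the same grid.
#' @param config A [complexion_config()].
#' @return List with `lab`, `mask`, `small`, `factor`.
#' @export
denoise_mask <- function(small, mask, config = complexion_config()) {
  lab <- extract_skin_pixels(small, mask)
  lab <- denoise_extremes(lab, config$low_tail, config$high_tail)
  kept <- attr(lab, "kept")
  tm <- t(mask)
  idx <- which(tm)
  tm[idx[!kept]] <- FALSE
  list(lab = lab, mask = t(tm), small = small,
       factor = config$downscale_factor)
}
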