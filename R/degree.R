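.minmax <- function(x) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

#' Color-degree ranking within each predicted class
#'
#' For each subject the proportion of skin pixels falling on the base of
#' the subject's own (predicted) class is read from the four-bin
#' chromaticity histogram; within every class group these proportions are
#' min-max normalized into `[0, 1]`. A group with constant proportions (or
#' a single subject) receives the midpoint degree 0.5. White and black
#' subjects carry no chromaticity base and are rejected.
#'
#' @param histograms `N x 4` matrix of chromaticity-only histograms
#'   (columns in canonical base order), or a list of length-4 vectors.
#' @param predicted Predicted class per subject, each among the four base
#'   classes.
#' @return Numeric vector of degrees in `[0, 1]`, aligned with the input.
#' @export
color_degree <- function(histograms, predicted) {
  if (is.list(histograms)) histograms <- do.call(rbind, histograms)
  histograms <- as.matrix(histograms)
  predicted <- as.character(predicted)
  stopifnot(ncol(histograms) == 4, nrow(histograms) == length(predicted))
  bad <- setdiff(unique(predicted), .BASE_CLASSES)
  if (length(bad))
    stop("color degree is undefined for class(es): ",
         paste(bad, collapse = ", "))
  own <- histograms[cbind(seq_along(predicted),
                          match(predicted, .BASE_CLASSES))]
  deg <- numeric(length(own))
  for (cl in unique(predicted)) {
    idx <- predicted == cl
    deg[idx] <- .minmax(own[idx])
  }
  deg
}

#' Gloss score of a luminance histogram
#'
#' Weighted sum `sum(w_j h_j)` over the luminance bins, with
#' non-decreasing weights so that brighter (glossier) skin scores higher.
#' The default weight of bin `j` is its bin-center luminance divided by
#' 100, the minimal choice consistent with the monotonicity principle.
#'
#' @param luminance_histogram Normalized length-`K` histogram (e.g. from
#'   [luminance_only_histogram()]).
#' @param binning The [luminance_binning()] that produced it.
#' @param weights Optional non-decreasing weights, one per bin.
#' @return Scalar gloss score.
#' @export
gloss_score <- function(luminance_histogram, binning = luminance_binning(),
                        weights = NULL) {
  k <- binning$K
  h <- as.numeric(luminance_histogram)
  if (length(h) != k) stop("histogram length must equal the bin count K")
  if (is.null(weights)) {
    centers <- (head(binning$edges, -1) + binning$edges[-1]) / 2
    weights <- centers / 100
  }
  if (length(weights) != k) stop("need one weight per bin")
  if (any(diff(weights) < 0))
    stop("gloss weights must be non-decreasing in luminance")
  sum(weights * h)
}

#' Gloss-degree ranking over a cohort
#'
#' Min-max normalization of the gloss scores across the whole cohort (all
#' six classes participate); constant scores map to 0.5.
#'
#' @param cohort_scores Numeric vector of [gloss_score()] values.
#' @return Degrees in `[0, 1]`.
#' @export
gloss_degree <- function(cohort_scores) {
  if (length(cohort_scores) == 0) stop("need at least one score")
  if (length(cohort_scores) == 1) return(0.5)
  .minmax(cohort_scores)
}

#' Two-dimensional complexion ranking coordinates
#'
#' Projects every subject onto the (color degree, gloss degree) plane.
#' Region-fused feature vectors are first collapsed by summing the five
#' weighted region blocks into one whole-face histogram; its aggregate
#' bins feed the color degree (per predicted class, `NA` for white/black)
#' and its merged luminance distribution feeds the gloss degree.
#'
#' @param fused_histograms List of fused `complexion_histogram`s (from
#'   [fuse_features()]), or plain whole-face histograms with aggregate
#'   bins.
#' @param predicted Predicted class per subject.
#' @param ids Optional subject identifiers.
#' @param gloss_weights Optional override for [gloss_score()].
#' @return Data frame (`id`, `class`, `color_degree`, `gloss_degree`).
#' @export
ranking_coordinates <- function(fused_histograms, predicted, ids = NULL,
                                gloss_weights = NULL) {
  if (inherits(fused_histograms, "complexion_histogram"))
    fused_histograms <- list(fused_histograms)
  predicted <- as.character(predicted)
  stopifnot(length(fused_histograms) == length(predicted))
  if (is.null(ids)) ids <- as.character(seq_along(predicted))

  collapse <- function(h) {
    stopifnot(inherits(h, "complexion_histogram"), h$include_base_bins)
    k <- h$binning$K
    block <- k + 1L
    v <- h$values
    out <- numeric(4L * block)
    for (r in seq_len(h$n_regions))
      out <- out + v[(r - 1L) * 4L * block + seq_len(4L * block)]
    .new_histogram(out, h$binning, TRUE, h$n_pixels, TRUE)
  }
  whole <- lapply(fused_histograms, collapse)

  chrom <- t(vapply(whole, function(h)
    h$values[seq(1, by = h$binning$K + 1L, length.out = 4L)], numeric(4)))
  colnames(chrom) <- .BASE_CLASSES

  col_deg <- rep(NA_real_, length(predicted))
  chromatic <- predicted %in% .BASE_CLASSES
  if (any(chromatic))
    col_deg[chromatic] <- color_degree(chrom[chromatic, , drop = FALSE],
                                       predicted[chromatic])

  bn <- whole[[1]]$binning
  scores <- vapply(whole, function(h)
    gloss_score(luminance_only_histogram(h), bn, gloss_weights), numeric(1))
  data.frame(id = ids, class = predicted, color_degree = col_deg,
             gloss_degree = gloss_degree(scores))
}
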