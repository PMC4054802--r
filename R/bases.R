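#' Dominant and subdominant chromaticity of one face (pixel-level clustering)
#'
#' Fuzzy c-means with two clusters on the skin pixels' `(a, b)`
#' chromaticities; the center with the larger hard-membership count is the
#' dominant chromaticity, the other the subdominant. Which center is
#' labeled dominant depends only on member counts, not on cluster seeding.
#'
#' A face whose second cluster holds fewer than `min_share` of the pixels
#' is treated as effectively unimodal: the subdominant then duplicates the
#' dominant center. This keeps tiny artifact clusters (e.g. boundary
#' pixels blending skin with the background after downscaling) from
#' polluting the chromaticity-level pool, while any genuine minor facial
#' color occupies far more than that share.
#'
#' @param lab_pixels `N x 3` Lab matrix, `N >= 10`.
#' @param seed FCM initialization seed.
#' @param m,tol,max_iter FCM controls, see [fcm()].
#' @param min_share Minimum hard-count share for a distinct subdominant.
#' @return List with `dominant` and `subdominant` `(a, b)` vectors and
#'   `counts` (hard counts, dominant first).
#' @export
image_dominant_pair <- function(lab_pixels, seed = 1L, m = 2, tol = 1e-5,
                                max_iter = 300L, min_share = 0.1) {
  if (nrow(lab_pixels) < 10) stop("need at least 10 skin pixels")
  ab <- lab_pixels[, 2:3, drop = FALSE]
  res <- fcm(ab, c = 2L, m = m, tol = tol, max_iter = max_iter, seed = seed)
  dom <- largest_cluster(res)
  ## subdominant is the other center (under ties, the lexicographically
  ## larger one, mirroring largest_cluster's rule)
  other <- which.max(colSums((t(res$centers) - dom)^2))
  counts <- res$hard_counts
  dom_idx <- which.min(colSums((t(res$centers) - dom)^2))
  sub <- unname(res$centers[other, ])
  if (counts[other] < min_share * sum(counts)) sub <- unname(dom)
  list(dominant = unname(dom),
       subdominant = sub,
       counts = c(counts[dom_idx], counts[other]))
}

#' A labeled chromaticity base
#'
#' @param label One of the four base classes (normal, cyan, red, yellow).
#' @param ab `(a, b)` coordinates.
#' @param provenance Optional list of bookkeeping counts.
#' @return Object of class `chromaticity_base`.
#' @export
chromaticity_base <- function(label, ab, provenance = NULL) {
  label <- match.arg(label, .BASE_CLASSES)
  stopifnot(length(ab) == 2, all(is.finite(ab)))
  structure(list(label = label, a = unname(ab[1]), b = unname(ab[2]),
                 provenance = provenance),
            class = "chromaticity_base")
}

#' @export
print.chromaticity_base <- function(x, ...) {
  cat(sprintf("chromaticity base %-7s (a = %.2f, b = %.2f)\n",
              x$label, x$a, x$b))
  invisible(x)
}

#' Build one chromaticity base by two-level clustering
#'
#' Second (chromaticity-level) clustering step: the dominant and
#' subdominant centers of every image of the class are pooled (two points
#' per image) and clustered again with two-cluster FCM; the center with the
#' greater number of members becomes the class base. Pooling both centers
#' makes the construction robust to faces on which the morbid color is only
#' the minor pixel cluster: the class's shared morbid chromaticity
#' accumulates across images regardless of whether it was dominant in any
#' single face.
#'
#' @param class_images List of `N x 3` Lab pixel matrices (>= 2 images), or
#'   a list of precomputed [image_dominant_pair()] results.
#' @param label Base label.
#' @param seed FCM seed for both levels.
#' @return A [chromaticity_base()].
#' @export
build_base <- function(class_images, label, seed = 1L) {
  if (length(class_images) < 2) stop("build_base needs at least 2 images")
  pairs <- lapply(seq_along(class_images), function(i) {
    ci <- class_images[[i]]
    if (is.list(ci) && !is.null(ci$dominant)) ci
    else image_dominant_pair(ci, seed = seed + i)
  })
  pooled <- do.call(rbind, lapply(pairs, function(p)
    rbind(p$dominant, p$subdominant)))
  res <- fcm(pooled, c = 2L, seed = seed)
  chromaticity_base(label, largest_cluster(res),
                    provenance = list(n_images = length(class_images),
                                      n_points = nrow(pooled),
                                      hard_counts = res$hard_counts))
}

#' Build the four chromaticity bases from a labeled cohort
#'
#' One [build_base()] per base class, each using only that class's images
#' (bases are constructed separately so no class contaminates another);
#' white/black images are ignored, as those classes carry no base.
#'
#' @param class_images Named list mapping class labels to lists of Lab
#'   pixel matrices (or precomputed dominant pairs); must contain at least
#'   2 images for each of normal, cyan, red, yellow.
#' @param seed Master seed; per-class seeds are derived from it.
#' @return A `base_set`: list of four `chromaticity_base` in canonical
#'   order (normal, cyan, red, yellow).
#' @export
build_all_bases <- function(class_images, seed = 1L) {
  missing <- setdiff(.BASE_CLASSES, names(class_images))
  if (length(missing))
    stop("cohort lacks images for class(es): ", paste(missing, collapse = ", "))
  bases <- lapply(seq_along(.BASE_CLASSES), function(k) {
    lab <- .BASE_CLASSES[k]
    if (length(class_images[[lab]]) < 2)
      stop("cohort lacks images for class(es): ", lab)
    build_base(class_images[[lab]], lab, seed = seed * 10 + k)
  })
  names(bases) <- .BASE_CLASSES
  class(bases) <- "base_set"
  bases
}

#' @export
print.base_set <- function(x, ...) {
  for (b in x) print(b)
  invisible(x)
}

#' Base coordinates as a matrix
#'
#' @param bases A `base_set`.
#' @return `4 x 2` matrix of `(a, b)` rows in canonical order.
#' @export
base_matrix <- function(bases) {
  stopifnot(inherits(bases, "base_set"))
  m <- t(vapply(bases, function(b) c(b$a, b$b), numeric(2)))
  colnames(m) <- c("a", "b")
  m
}

#' Single-level dominant-color baseline
#'
#' Comparison construction without the second clustering level: each image
#' contributes only its dominant (larger-cluster) center, and the base is
#' the arithmetic mean of those dominant centers. On cohorts where the
#' morbid color is the minor pixel cluster this collapses onto basic skin.
#'
#' @inheritParams build_base
#' @return A [chromaticity_base()].
#' @export
single_level_baseline <- function(class_images, label, seed = 1L) {
  if (length(class_images) < 2) stop("needs at least 2 images")
  doms <- t(vapply(seq_along(class_images), function(i) {
    ci <- class_images[[i]]
    p <- if (is.list(ci) && !is.null(ci$dominant)) ci
         else image_dominant_pair(ci, seed = seed + i)
    p$dominant
  }, numeric(2)))
  chromaticity_base(label, colMeans(doms),
                    provenance = list(n_images = length(class_images)))
}

#' Classify a face from its four-bin chromaticity histogram peak
#'
#' Predicts the facial color as the base with the maximal histogram bin
#' (the dominant color); ties resolve to the earliest class in canonical
#' order.
#'
#' @param four_bin_histogram Non-negative length-4 vector in canonical base
#'   order.
#' @return A class label.
#' @export
classify_by_peak <- function(four_bin_histogram) {
  h <- as.numeric(four_bin_histogram)
  if (length(h) != 4 || any(h < 0)) stop("need 4 non-negative bins")
  if (all(h == 0)) stop("all-zero histogram cannot be classified")
  .BASE_CLASSES[which.max(h)]
}

#' Euclidean chromaticity distance in the (a, b) plane
#'
#' @param ab1,ab2 `(a, b)` vectors or a `chromaticity_base`.
#' @return Non-negative distance (Delta E restricted to chromaticity).
#' @export
delta_e_ab <- function(ab1, ab2) {
  take <- function(x) if (inherits(x, "chromaticity_base")) c(x$a, x$b) else x
  sqrt(sum((take(ab1) - take(ab2))^2))
}

#' Serialize / read a base set as JSON
#'
#' @param bases A `base_set`.
#' @param path Output (input) JSON path.
#' @return `write_bases` the path invisibly; `read_bases` a `base_set`.
#' @export
write_bases <- function(bases, path) {
  stopifnot(inherits(bases, "base_set"))
  jsonlite::write_json(
    lapply(unname(bases), function(b) list(label = b$label, a = b$a, b = b$b)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bases
#' @export
read_bases <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  bases <- lapply(raw, function(b)
    chromaticity_base(b$label, c(b$a, b$b)))
  names(bases) <- vapply(bases, `[[`, "", "label")
  bases <- bases[.BASE_CLASSES]
  class(bases) <- "base_set"
  bases
}
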