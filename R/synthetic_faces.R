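## Planted per-class chromaticity centers and luminance means. The chromatic
## centers are fixed constants mutually separated by >= 10 units in the
## (a, b) plane; white and black reuse the normal (basic skin) chromaticity
## with shifted luminance, since those two classes differ from normal skin
## in gloss, not hue.
.CLASS_LABELS <- c("normal", "cyan", "red", "yellow", "white", "black")
.BASE_CLASSES <- c("normal", "cyan", "red", "yellow")
.BASIC_AB <- c(a = 13, b = 16)
.CLASS_AB <- list(
  normal = c(a = 13, b = 16),
  cyan   = c(a = -2, b = 8),
  red    = c(a = 26, b = 14),
  yellow = c(a = 12, b = 30),
  white  = c(a = 13, b = 16),
  black  = c(a = 13, b = 16)
)
.CLASS_L <- c(normal = 60, cyan = 60, red = 60, yellow = 60,
              white = 80, black = 38)

#' Facial-color class labels
#'
#' @param bases_only If `TRUE`, only the four classes that carry a
#'   chromaticity base (normal, cyan, red, yellow).
#' @return Character vector of class labels in canonical order.
#' @export
complexion_classes <- function(bases_only = FALSE) {
  if (bases_only) .BASE_CLASSES else .CLASS_LABELS
}

#' Planted chromaticity and luminance ground truth for a class
#'
#' @param class_label One of [complexion_classes()].
#' @return List with `ab` (planted chromaticity center) and `luminance_mean`.
#' @export
class_ground_truth <- function(class_label) {
  class_label <- match.arg(class_label, .CLASS_LABELS)
  list(ab = .CLASS_AB[[class_label]],
       luminance_mean = unname(.CLASS_L[class_label]))
}

#' Specification for one synthetic face
#'
#' Describes the planted structure of a synthetic frontal face image: an
#' elliptical skin region whose pixel chromaticities are a two-component
#' mixture of the class's planted (morbid) chromaticity, with weight
#' `minor_fraction`, and a shared basic-skin chromaticity; Gaussian
#' luminance; dark mole and hair artifacts; and a lip region whose
#' chromaticity overlaps skin.
#'
#' @param class_label One of [complexion_classes()].
#' @param planted_ab Planted `(a, b)` center; class default if `NULL`.
#' @param ab_spread Per-pixel chromaticity noise SD (Lab units).
#' @param luminance_mean,luminance_sd L-channel profile; class-default mean
#'   if `NULL`.
#' @param minor_fraction Fraction of skin pixels drawn from the planted
#'   chromaticity (the rest use basic skin); in `(0, 1]`. Defaults to 1 for
#'   normal/white/black and 0.7 for the chromatic morbid classes.
#' @param artifact_counts Named vector `c(moles =, hairs =)`.
#' @param image_size `c(height, width)` in pixels.
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return List of class `face_spec`.
#' @export
face_spec <- function(class_label, planted_ab = NULL, ab_spread = 2.5,
                      luminance_mean = NULL, luminance_sd = 7,
                      minor_fraction = NULL,
                      artifact_counts = c(moles = 3, hairs = 2),
                      image_size = c(256, 256), seed = 1L) {
  class_label <- match.arg(class_label, .CLASS_LABELS)
  if (is.null(planted_ab)) planted_ab <- .CLASS_AB[[class_label]]
  if (is.null(luminance_mean)) luminance_mean <- unname(.CLASS_L[class_label])
  if (is.null(minor_fraction))
    minor_fraction <- if (class_label %in% c("cyan", "red", "yellow")) 0.7 else 1
  stopifnot(minor_fraction > 0, minor_fraction <= 1,
            luminance_mean >= 0, luminance_mean <= 100,
            length(image_size) == 2, all(image_size >= 48))
  spec <- list(class_label = class_label,
               planted_ab = unname(planted_ab),
               ab_spread = ab_spread,
               luminance_mean = luminance_mean,
               luminance_sd = luminance_sd,
               minor_fraction = minor_fraction,
               artifact_counts = artifact_counts,
               image_size = as.integer(image_size),
               seed = as.integer(seed))
  class(spec) <- "face_spec"
  spec
}

.disk_mask <- function(h, w, center, radii) {
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((cc - center[2]) / radii[2])^2 <= 1
}

#' Generate one synthetic face fixture
#'
#' Renders the face described by a [face_spec()]: an elliptical skin region
#' on a dark, luminance-varying background, skin pixels sampled in Lab space
#' from the planted mixture, near-black moles and hair strands, and a lip
#' ellipse inside the mouth box. Lab values are converted to 8-bit RGB with
#' the analytic CIELAB inverse; the run errors if more than 1 percent of
#' pixels fall out of gamut.
#'
#' @param spec A [face_spec()].
#' @return List of class `face_fixture`: `image` (`H x W x 3` integer array,
#'   0-255), `skin_mask` (ground-truth logical matrix excluding background,
#'   mouth box, and artifacts), `mouth_box` (`c(row0, col0, row1, col1)`,
#'   inclusive), and `spec`.
#' @export
generate_face <- function(spec) {
  stopifnot(inherits(spec, "face_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n <- h * w

  withr::with_seed(spec$seed, {
    ## geometry: face ellipse, mouth box, lip ellipse
    ## clinical facial photographs are tightly cropped: the face fills most
    ## of the frame, so skin is the dominant pixel mass
    face <- .disk_mask(h, w, c(h / 2, w / 2), c(0.48 * h, 0.40 * w))
    mrow <- round(c(h / 2 + 0.18 * h, h / 2 + 0.30 * h))
    mcol <- round(c(w / 2 - 0.11 * w, w / 2 + 0.11 * w))
    mouth_box <- c(mrow[1], mcol[1], mrow[2], mcol[2])
    lip <- .disk_mask(h, w, c(mean(mrow), w / 2),
                      c(0.35 * diff(mrow), 0.45 * diff(mcol)))

    ## background: dark bluish backdrop with strong luminance texture so its
    ## log-opponent locus is diffuse, unlike the tight skin locus
    lab <- cbind(L = pmin(pmax(rnorm(n, 22, 9), 10), 60),
                 a = rnorm(n, 0, 2), b = rnorm(n, -12, 2))

    ## skin mixture: planted (morbid) vs shared basic chromaticity.
    ## Morbid coloration is spatially coherent (patches, as on real faces),
    ## not per-pixel salt-and-pepper: the minor indicator thresholds a
    ## smoothed random field, so patches survive block-average downscaling.
    ## The threshold is the field quantile, making the fraction exact.
    idx_skin <- which(face & !lip)
    ns <- length(idx_skin)
    sh <- ceiling(h / 8); sw <- ceiling(w / 8)
    field_small <- .smooth2d(matrix(rnorm(sh * sw), sh, sw), 2)
    field <- kronecker(field_small, matrix(1, 8, 8))[seq_len(h), seq_len(w)]
    fvals <- field[idx_skin]
    k_minor <- max(1L, round(spec$minor_fraction * ns))
    minor <- fvals >= sort(fvals, decreasing = TRUE)[k_minor]
    ab_mu <- matrix(rep(.BASIC_AB, each = ns), ns, 2)
    ab_mu[minor, 1] <- spec$planted_ab[1]
    ab_mu[minor, 2] <- spec$planted_ab[2]
    ## clamp to the Lab range renderable in RGB for skin-like chromaticity
    lab[idx_skin, "L"] <- pmin(pmax(
      rnorm(ns, spec$luminance_mean, spec$luminance_sd), 12), 84)
    lab[idx_skin, "a"] <- ab_mu[, 1] + rnorm(ns, 0, spec$ab_spread)
    lab[idx_skin, "b"] <- ab_mu[, 2] + rnorm(ns, 0, spec$ab_spread)

    ## lips: chromaticity overlapping reddish skin, darker than skin
    idx_lip <- which(lip)
    nl <- length(idx_lip)
    lab[idx_lip, ] <- cbind(rnorm(nl, 46, 4), rnorm(nl, 30, 2),
                            rnorm(nl, 16, 2))

    ## artifacts: near-black moles (disks) and hair strands (thin arcs near
    ## the forehead); removed from the ground-truth skin mask
    artifact <- matrix(FALSE, h, w)
    n_moles <- spec$artifact_counts[["moles"]]
    if (n_moles > 0) {
      for (k in seq_len(n_moles)) {
        ctr <- c(runif(1, 0.35 * h, 0.65 * h), runif(1, 0.3 * w, 0.7 * w))
        artifact <- artifact | .disk_mask(h, w, ctr, c(2.5, 2.5))
      }
    }
    n_hairs <- spec$artifact_counts[["hairs"]]
    if (n_hairs > 0) {
      for (k in seq_len(n_hairs)) {
        col0 <- round(runif(1, 0.35 * w, 0.65 * w))
        rows <- round(h / 2 - 0.42 * h + seq_len(round(0.1 * h)))
        cols <- pmin(pmax(col0 + cumsum(sample(-1:1, length(rows), TRUE)), 1), w)
        artifact[cbind(rows, cols)] <- TRUE
      }
    }
    artifact <- artifact & face
    idx_art <- which(artifact)
    na <- length(idx_art)
    lab[idx_art, ] <- cbind(rnorm(na, 13, 2), rnorm(na, 7, 1.5),
                            rnorm(na, 7, 1.5))

    ## rasterize: lab rows here are in column-major pixel order. A pixel
    ## whose Lab color leaves the RGB gamut (chroma noise at luminance
    ## extremes) gets its luminance remapped into range, mimicking
    ## highlight/shadow desaturation, before one silent-clip conversion.
    rgb <- lab_to_rgb(lab)
    oob <- attr(rgb, "clipped")
    if (any(oob)) {
      lab[oob, "L"] <- pmin(pmax(lab[oob, "L"], 16), 76)
      rgb <- lab_to_rgb(lab)
    }
    clip <- attr(rgb, "clip_fraction")
    if (clip > 0.01)
      stop(sprintf(paste0("planted Lab colors leave the RGB gamut for %.1f%%",
                          " of pixels (class %s, L mean %.1f)"),
                   100 * clip, spec$class_label, spec$luminance_mean))
    img <- array(as.integer(round(255 * rgb)), dim = c(h, w, 3))

    in_box <- matrix(FALSE, h, w)
    in_box[mrow[1]:mrow[2], mcol[1]:mcol[2]] <- TRUE
    skin_mask <- face & !lip & !artifact & !in_box

    fixture <- list(image = img, skin_mask = skin_mask,
                    mouth_box = mouth_box, spec = spec)
    class(fixture) <- "face_fixture"
    fixture
  })
}

#' @export
print.face_fixture <- function(x, ...) {
  cat(sprintf("Synthetic face: class %s, %d x %d, %d skin pixels\n",
              x$spec$class_label, nrow(x$skin_mask), ncol(x$skin_mask),
              sum(x$skin_mask)))
  invisible(x)
}

#' Class counts of the reference cohort
#'
#' The per-class sample sizes of the 122-subject facial-color cohort that
#' the synthetic generator emulates.
#'
#' @return Named integer vector over the six classes.
#' @export
reference_cohort_counts <- function() {
  c(normal = 24L, cyan = 15L, red = 18L, yellow = 24L, white = 21L,
    black = 20L)
}

#' Generate a labeled cohort of synthetic faces
#'
#' Produces `class_counts[label]` fixtures per class with distinct seeds.
#' Within each chromatic morbid class (cyan, red, yellow), disease severity
#' varies across subjects: `minor_fraction` follows a linear ramp so that
#' mild cases show the morbid color as the minor pixel cluster while the
#' most severe cases are fully covered by it. Luminance means get a small
#' per-subject jitter (or, with `degree_gradient`, a linear ramp around the
#' class mean so the true gloss ordering is known).
#'
#' @param class_counts Named vector of per-class sizes (subset of
#'   [complexion_classes()]), e.g. [reference_cohort_counts()].
#' @param degree_gradient If `TRUE`, `minor_fraction` ramps linearly over
#'   `0.4..1` (chromatic classes) and `luminance_mean` over class mean
#'   `+/- 10`, so true color/gloss rankings equal the parameter orderings.
#' @param seed Master seed; per-fixture seeds are derived from it.
#' @param image_size Passed to [face_spec()].
#' @return List of `face_fixture` with attribute `manifest`, a data frame
#'   (`id`, `label`, `seed`, `minor_fraction`, `luminance_mean`).
#' @export
generate_cohort <- function(class_counts, degree_gradient = FALSE, seed = 1L,
                            image_size = c(256, 256)) {
  class_counts <- class_counts[class_counts > 0]
  if (length(class_counts) == 0) stop("class_counts must request >= 1 image")
  labs <- names(class_counts)
  if (is.null(labs) || !all(labs %in% .CLASS_LABELS))
    stop("class_counts must be named with labels among: ",
         paste(.CLASS_LABELS, collapse = ", "))

  fixtures <- list()
  manifest <- NULL
  for (lab in labs) {
    n <- as.integer(class_counts[[lab]])
    chromatic <- lab %in% c("cyan", "red", "yellow")
    mf <- if (!chromatic) rep(1, n)
          else if (degree_gradient) seq(0.4, 1, length.out = max(n, 2))[seq_len(n)]
          else pmin(1, seq(0.45, 1.1, length.out = max(n, 2))[seq_len(n)])
    lmu <- if (degree_gradient) {
      .CLASS_L[lab] + seq(-10, 10, length.out = max(n, 2))[seq_len(n)]
    } else {
      cl_seed <- (seed * 17 + match(lab, .CLASS_LABELS)) %% .Machine$integer.max
      .CLASS_L[lab] + withr::with_seed(cl_seed, rnorm(n, 0, 3))
    }
    for (j in seq_len(n)) {
      fx_seed <- (seed * 100003 + match(lab, .CLASS_LABELS) * 1000 + j) %%
        .Machine$integer.max
      sp <- face_spec(lab, minor_fraction = mf[j], luminance_mean = lmu[j],
                      image_size = image_size, seed = fx_seed)
      fx <- generate_face(sp)
      fx$id <- sprintf("%s_%02d", lab, j)
      fixtures[[length(fixtures) + 1L]] <- fx
      manifest <- rbind(manifest, data.frame(
        id = fx$id, label = lab, seed = fx_seed,
        minor_fraction = mf[j], luminance_mean = unname(lmu[j])))
    }
  }
  attr(fixtures, "manifest") <- manifest
  class(fixtures) <- c("face_cohort", "list")
  fixtures
}

#' Write a fixture (or cohort) to disk
#'
#' Each fixture is saved as a PNG plus a JSON sidecar recording the label,
#' mouth box, seed, and planted ground truth; the cohort manifest is a CSV
#' (`path`, `label`, plus ground-truth columns).
#'
#' @param fixtures A `face_fixture` or a list of them (e.g. a cohort).
#' @param dir Output directory, created if missing.
#' @return Invisibly, the manifest data frame.
#' @export
write_fixtures <- function(fixtures, dir) {
  if (inherits(fixtures, "face_fixture")) fixtures <- list(fixtures)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(fixtures), function(i) {
    fx <- fixtures[[i]]
    id <- if (!is.null(fx$id)) fx$id
          else sprintf("%s_%03d", fx$spec$class_label, i)
    png_path <- file.path(dir, paste0(id, ".png"))
    png::writePNG(aperm(array(fx$image / 255, dim(fx$image)), c(1, 2, 3)),
                  png_path)
    png::writePNG(fx$skin_mask * 1, file.path(dir, paste0(id, "_mask.png")))
    sidecar <- list(id = id, label = fx$spec$class_label,
                    mouth_box = fx$mouth_box, seed = fx$spec$seed,
                    planted_ab = fx$spec$planted_ab,
                    minor_fraction = fx$spec$minor_fraction,
                    luminance_mean = fx$spec$luminance_mean)
    jsonlite::write_json(sidecar, file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(path = basename(png_path), label = fx$spec$class_label,
               id = id, seed = fx$spec$seed,
               minor_fraction = fx$spec$minor_fraction,
               luminance_mean = fx$spec$luminance_mean)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an 8-bit RGB image from a PNG file
#'
#' @param path PNG path.
#' @return `H x W x 3` integer array, 0-255.
#' @export
read_image <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3]
  array(as.integer(round(255 * arr)), dim(arr))
}
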