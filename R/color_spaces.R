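## RGB -> CIEXYZ matrix (D65, 2 degree observer), applied to linear RGB in
## [0,1]; XYZ is carried on the 0-100 scale so that ratios against the
## reference white below are dimensionless.
.RGB2XYZ <- matrix(c(
  0.4124, 0.3576, 0.1805,
  0.2126, 0.7152, 0.0722,
  0.0193, 0.1192, 0.9505), nrow = 3, byrow = TRUE)

#' D65 reference white tristimulus values (0-100 scale)
#'
#' @return Named numeric vector with components `X`, `Y`, `Z`.
#' @export
white_point_d65 <- function() c(X = 95.047, Y = 100, Z = 108.883)

.as_pixel_matrix <- function(x, n_col = 3L, what = "pixels") {
  if (is.null(dim(x))) {
    if (length(x) != n_col)
      stop(what, " must be a length-", n_col, " vector or an N x ", n_col,
           " matrix")
    x <- matrix(x, nrow = 1L)
  }
  if (length(dim(x)) == 3L) x <- pixel_matrix(x)
  if (ncol(x) != n_col) stop(what, " must have ", n_col, " columns")
  storage.mode(x) <- "double"
  x
}

#' Flatten an H x W x 3 image array into a row-major pixel matrix
#'
#' Pixels are ordered row by row (all columns of row 1, then row 2, ...),
#' the order promised by [extract_skin_pixels()].
#'
#' @param image An `H x W x 3` numeric array.
#' @return An `(H*W) x 3` matrix.
#' @export
pixel_matrix <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  d <- dim(image)
  m <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  ## as.vector is column-major; reorder to row-major
  idx <- as.vector(t(matrix(seq_len(d[1] * d[2]), nrow = d[1])))
  m[idx, , drop = FALSE]
}

#' Convert linear RGB to CIEXYZ
#'
#' Applies the D65 RGB-to-XYZ matrix row-wise to pixels with channels in
#' `[0, 1]` and scales the result by 100 so that it is directly comparable
#' with [white_point_d65()]. The matrix is applied to the channels as given
#' (no gamma decoding); see `assume_linear_rgb` in [complexion_config()].
#'
#' @param rgb Length-3 vector or `N x 3` matrix of channels in `[0, 1]`.
#' @return `N x 3` matrix with columns `X`, `Y`, `Z` on the 0-100 scale.
#' @export
rgb_to_xyz <- function(rgb) {
  rgb <- .as_pixel_matrix(rgb, what = "rgb")
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 1 + 1e-12)
    stop("rgb channels must lie in [0, 1]")
  xyz <- 100 * (rgb %*% t(.RGB2XYZ))
  colnames(xyz) <- c("X", "Y", "Z")
  xyz
}

## piecewise cube-root companding of the Lab encoding
.lab_f <- function(t) {
  delta3 <- (6 / 29)^3
  ifelse(t > delta3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

.lab_f_inv <- function(ft) {
  delta <- 6 / 29
  ifelse(ft > delta, ft^3, 3 * delta^2 * (ft - 4 / 29))
}

#' Convert CIEXYZ to CIELAB
#'
#' Standard CIELAB encoding: `L* = 116 f(Y/Yn) - 16`,
#' `a* = 500 [f(X/Xn) - f(Y/Yn)]`, `b* = 200 [f(Y/Yn) - f(Z/Zn)]` with the
#' piecewise cube-root `f` and the D65 reference white.
#'
#' @param xyz Length-3 vector or `N x 3` matrix of non-negative tristimulus
#'   values on the 0-100 scale.
#' @return `N x 3` matrix with columns `L`, `a`, `b`.
#' @export
xyz_to_lab <- function(xyz) {
  xyz <- .as_pixel_matrix(xyz, what = "xyz")
  if (anyNA(xyz) || min(xyz) < -1e-9)
    stop("xyz tristimulus values must be non-negative")
  wp <- white_point_d65()
  fx <- .lab_f(xyz[, 1] / wp["X"])
  fy <- .lab_f(xyz[, 2] / wp["Y"])
  fz <- .lab_f(xyz[, 3] / wp["Z"])
  lab <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  rownames(lab) <- NULL
  lab
}

#' Convert RGB to CIELAB
#'
#' Composition of [rgb_to_xyz()] and [xyz_to_lab()]. Integer-like input with
#' any channel above 1 is interpreted as 8-bit (0-255) and rescaled.
#'
#' @param rgb Length-3 vector, `N x 3` matrix, or `H x W x 3` array; channels
#'   either in `[0, 1]` or 8-bit `0..255`.
#' @param bit8 Force 8-bit interpretation; by default inferred from the range.
#' @return `N x 3` matrix with columns `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(rgb, bit8 = NULL) {
  rgb <- .as_pixel_matrix(rgb, what = "rgb")
  if (is.null(bit8)) bit8 <- max(rgb) > 1
  if (bit8) rgb <- rgb / 255
  xyz_to_lab(rgb_to_xyz(rgb))
}

#' Convert CIELAB to linear RGB
#'
#' Analytic inverse of [rgb_to_lab()]; used by the synthetic-face generator.
#' Out-of-gamut values are clipped to `[0, 1]` and the clipped-pixel fraction
#' is attached as attribute `clip_fraction`.
#'
#' @param lab Length-3 vector or `N x 3` matrix of `L`, `a`, `b` values.
#' @return `N x 3` matrix of linear RGB channels in `[0, 1]`.
#' @export
lab_to_rgb <- function(lab) {
  lab <- .as_pixel_matrix(lab, what = "lab")
  wp <- white_point_d65()
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(wp["X"] * .lab_f_inv(fx), wp["Y"] * .lab_f_inv(fy),
               wp["Z"] * .lab_f_inv(fz))
  rgb <- (xyz / 100) %*% t(solve(.RGB2XYZ))
  clipped <- rowSums(rgb < -1e-9 | rgb > 1 + 1e-9) > 0
  rgb[rgb < 0] <- 0
  rgb[rgb > 1] <- 1
  colnames(rgb) <- c("r", "g", "b")
  rownames(rgb) <- NULL
  attr(rgb, "clip_fraction") <- mean(clipped)
  attr(rgb, "clipped") <- clipped
  rgb
}

#' Convert 8-bit RGB to log-opponent chromaticity coordinates
#'
#' Log-opponent (LO) coordinates used by the skin detector:
#' `I = (l(R) + l(G) + l(B)) / 3`, `Rg = l(R) - l(G)`,
#' `By = l(B) - (l(R) + l(G)) / 2`, with `l(x) = log(x + 1)` so that all
#' channels are finite down to black. This is the package's LO dialect; the
#' `+1` offset makes the map total on 8-bit input.
#'
#' @param rgb Length-3 vector, `N x 3` matrix, or `H x W x 3` array of 8-bit
#'   channels `0..255`.
#' @return `N x 3` matrix with columns `I`, `Rg`, `By`.
#' @export
rgb_to_log_opponent <- function(rgb) {
  rgb <- .as_pixel_matrix(rgb, what = "rgb")
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("rgb channels must be 8-bit values in [0, 255]")
  lr <- log(rgb[, 1] + 1)
  lg <- log(rgb[, 2] + 1)
  lb <- log(rgb[, 3] + 1)
  cbind(I = (lr + lg + lb) / 3, Rg = lr - lg, By = lb - (lr + lg) / 2)
}
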