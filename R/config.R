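.CONFIG_DEFAULTS <- list(
  downscale_factor = 8L,
  low_tail = 0.01, high_tail = 0.01,
  histogram_bins = 24L, smoothing_sigma = 2.5, density_threshold = 0.15,
  gmm_posterior_threshold = 0.5, fusion_rule = "OR",
  lum_lo = 25, lum_hi = 95, lum_interval = 14, include_base_bins = TRUE,
  region_weights = c(left_cheek = 0.3, right_cheek = 0.3, forehead = 0.1,
                     nose = 0.1, jaw = 0.2),
  fcm_m = 2, fcm_tol = 1e-5, fcm_max_iter = 300L,
  cost_exponent_step = 2, inner_folds = 3L,
  assume_linear_rgb = TRUE, paper_protocol = FALSE,
  master_seed = 1L
)

#' Pipeline configuration
#'
#' All tunables of the complexion pipeline with their defaults: image
#' downscaling factor 8; 1 percent luminance denoising tails; the skin
#' detector's histogram/GMM parameters; the refined luminance binning
#' (25-95, interval 14, aggregate base bins on); the five region weights
#' (0.3, 0.3, 0.1, 0.1, 0.2); FCM controls (m = 2, tol = 1e-5, 300
#' iterations); the SVM exponent grid step and inner folds; and the master
#' seed. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults by name.
#' @return Validated list of class `complexion_config`.
#' @export
complexion_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- .CONFIG_DEFAULTS
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(downscale_factor >= 1,
              low_tail >= 0, low_tail <= 0.2,
              high_tail >= 0, high_tail <= 0.2,
              lum_hi > lum_lo, lum_interval > 0,
              fcm_m > 1, inner_folds >= 2)
    if (!fusion_rule %in% c("OR", "AND")) stop("fusion_rule must be OR/AND")
    if (abs(sum(region_weights) - 1) > 1e-6)
      stop("region_weights must sum to 1")
  })
  class(cfg) <- "complexion_config"
  cfg
}

#' @export
print.complexion_config <- function(x, ...) {
  cat("complexion pipeline configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", k, paste(format(v, digits = 6),
                                         collapse = " ")))
  }
  invisible(x)
}

#' Luminance binning described by a configuration
#'
#' @param config A [complexion_config()].
#' @return A [luminance_binning()].
#' @export
config_binning <- function(config)
  luminance_binning(config$lum_lo, config$lum_hi, config$lum_interval)

#' Read / write a configuration as flat YAML
#'
#' @param path YAML file path.
#' @param config A [complexion_config()].
#' @return `read_config` a `complexion_config`; `write_config` the path.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$region_weights))
    vals$region_weights <- unlist(vals$region_weights)
  do.call(complexion_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "complexion_config"))
  vals <- unclass(config)
  ## yaml drops names of atomic vectors; keep the weight map explicit
  vals$region_weights <- as.list(vals$region_weights)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Serialize a cohort feature matrix as CSV with a JSON layout header
#'
#' @param features `N x p` feature matrix.
#' @param ids,labels Per-row identifiers and class labels.
#' @param path Output CSV path; the layout JSON goes to `paste0(path,
#'   ".json")`.
#' @param binning,include_base_bins Layout description.
#' @return The CSV path, invisibly.
#' @export
write_histograms <- function(features, ids, labels, path,
                             binning = luminance_binning(),
                             include_base_bins = TRUE) {
  df <- data.frame(id = ids, label = labels, features, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(lum_lo = binning$lo, lum_hi = binning$hi,
         lum_interval = binning$interval, K = binning$K,
         include_base_bins = include_base_bins,
         feature_dim = ncol(features)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
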