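#' Default RBF-SVM parameter grids
#'
#' Powers of two spanning C in `2^-8 .. 2^15` and gamma in `2^-8 .. 2^8`.
#' The default step of 2 in the exponent keeps the grid search affordable
#' inside leave-one-out evaluation; pass `step = 1` for the dense grid.
#'
#' @param step Exponent step.
#' @return List with `C` and `gamma` vectors.
#' @export
svm_grids <- function(step = 2) {
  list(C = 2^seq(-8, 15, by = step), gamma = 2^seq(-8, 8, by = step))
}

.stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Train the facial-color SVM with grid search
#'
#' One-against-one RBF-kernel SVM (libsvm): with `L` classes, `L(L-1)/2`
#' pairwise binary models vote for the predicted label. The penalty `C`
#' and kernel width `gamma` are chosen by stratified inner
#' cross-validation on the training set; ties prefer the smaller `C`,
#' then the smaller `gamma`. Features are used as-is: complexion
#' histograms are already proportions in `[0, 1]`, and per-dimension
#' rescaling would destroy the color-proportion structure.
#'
#' @param features `N x p` numeric matrix.
#' @param labels Factor or character vector of length `N` (>= 2 classes).
#' @param C_grid,gamma_grid Candidate values, e.g. from [svm_grids()].
#' @param inner_folds Inner CV folds (reduced with a warning when a class
#'   is smaller).
#' @param seed Seed for the inner folds.
#' @return Object of class `color_model` with elements `svm`, `C`,
#'   `gamma`, `levels`, and `inner_accuracy`.
#' @export
train_svm <- function(features, labels, C_grid = svm_grids()$C,
                      gamma_grid = svm_grids()$gamma, inner_folds = 3L,
                      seed = 1L) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (length(C_grid) == 0 || length(gamma_grid) == 0)
    stop("parameter grids must be non-empty")
  min_class <- min(table(labels))
  k <- inner_folds
  if (min_class < k) {
    k <- max(2L, min_class)
    warning("inner folds reduced to ", k, " (smallest class has ",
            min_class, " members)")
  }
  fold <- .stratified_folds(labels, k, seed)

  ## iterate C ascending, then gamma ascending; strict improvement only,
  ## so ties resolve to the smaller C, then the smaller gamma
  best <- list(acc = -1, C = NA, gamma = NA)
  for (cc in sort(C_grid)) for (g in sort(gamma_grid)) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      if (nlevels(droplevels(labels[tr])) < 2) next
      m <- e1071::svm(features[tr, , drop = FALSE], droplevels(labels[tr]),
                      kernel = "radial", cost = cc, gamma = g, scale = FALSE)
      pr <- predict(m, features[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pr) == as.character(labels[!tr]))
    }
    acc <- correct / length(labels)
    if (acc > best$acc + 1e-12) best <- list(acc = acc, C = cc, gamma = g)
  }
  final <- e1071::svm(features, labels, kernel = "radial", cost = best$C,
                      gamma = best$gamma, scale = FALSE)
  structure(list(svm = final, C = best$C, gamma = best$gamma,
                 levels = levels(labels), inner_accuracy = best$acc),
            class = "color_model")
}

#' @export
print.color_model <- function(x, ...) {
  cat(sprintf(paste0("one-against-one RBF-SVM: %d classes (%d pairwise ",
                     "models), C = %g, gamma = %g\n"),
              length(x$levels), choose(length(x$levels), 2), x$C, x$gamma))
  invisible(x)
}

#' Predict facial-color labels
#'
#' @param object A `color_model`.
#' @param newdata `N x p` feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Character vector of labels.
#' @export
predict.color_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$svm$SV))
    stop("feature length mismatch: model expects ", ncol(object$svm$SV),
         " features, got ", ncol(newdata))
  as.character(predict(object$svm, newdata))
}

#' Multiclass metrics from a confusion matrix
#'
#' One-versus-all precision and recall per class, micro averages (TP, FP,
#' FN pooled over classes) and macro averages (plain means of per-class
#' values), and the F score `(beta^2 + 1) P R / (beta^2 P + R)` with
#' `beta = 1`. A class never predicted has precision 0 (with a warning
#' suppressed for empty classes by convention).
#'
#' @param matrix Square confusion matrix, rows = actual, columns =
#'   predicted.
#' @param beta F-score weight.
#' @return Object of class `evaluation_report`: confusion matrix,
#'   row-normalized `recall_matrix`, column-normalized `precision_matrix`,
#'   `per_class` data frame, `micro` and `macro` precision/recall/F, and
#'   total `accuracy`.
#' @export
metrics_from_confusion <- function(matrix, beta = 1) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("confusion matrix must be non-negative")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  fscore <- function(p, r) if (p + r == 0) 0 else
    (beta^2 + 1) * p * r / (beta^2 * p + r)
  micro_p <- sum(tp) / sum(tp + fp)
  micro_r <- sum(tp) / sum(tp + fn)
  macro_p <- mean(prec)
  macro_r <- mean(rec)
  rown <- sweep(m, 1, pmax(rowSums(m), 1), "/")
  coln <- sweep(m, 2, pmax(colSums(m), 1), "/")
  structure(list(
    confusion_matrix = m,
    recall_matrix = rown,
    precision_matrix = coln,
    per_class = data.frame(class = if (!is.null(rownames(m))) rownames(m)
                                   else as.character(seq_len(nrow(m))),
                           precision = unname(prec), recall = unname(rec),
                           f = unname(mapply(fscore, prec, rec))),
    micro = c(precision = micro_p, recall = micro_r,
              f = fscore(micro_p, micro_r)),
    macro = c(precision = macro_p, recall = macro_r,
              f = fscore(macro_p, macro_r)),
    accuracy = sum(tp) / sum(m)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("total accuracy %.4f  micro-F %.4f  macro-F %.4f\n",
              x$accuracy, x$micro["f"], x$macro["f"]))
  print(x$confusion_matrix)
  invisible(x)
}

## ---- cohort container -----------------------------------------------------

#' Process a cohort of fixtures into cached skin pixels and dominant pairs
#'
#' Runs the skin pipeline on every fixture (or uses the ground-truth masks
#' when `use_true_mask`) and caches each image's Lab skin pixels together
#' with its pixel-level dominant/subdominant chromaticity pair. The pair
#' depends only on the image itself, so caching it keeps per-fold base
#' reconstruction in leave-one-out evaluation exact.
#'
#' @param fixtures A list of `face_fixture` (e.g. [generate_cohort()]).
#' @param config A [complexion_config()].
#' @param use_true_mask Use the generator's ground-truth mask (downscaled)
#'   instead of running the detector.
#' @param seed Master seed.
#' @return Object of class `complexion_cohort`: list of per-image records
#'   (`id`, `label`, `lab`, `pair`).
#' @export
cohort_pixels <- function(fixtures, config = complexion_config(),
                          use_true_mask = FALSE, seed = 1L) {
  recs <- lapply(seq_along(fixtures), function(i) {
    fx <- fixtures[[i]]
    sp <- if (use_true_mask) {
      f <- config$downscale_factor
      small <- downscale(fx$image, f)
      denoise_mask(small, downscale_mask(fx$skin_mask, f), config)
    } else {
      skin_pixels(fx$image, fx$mouth_box, config, seed = seed + i)
    }
    list(id = if (!is.null(fx$id)) fx$id else as.character(i),
         label = fx$spec$class_label, lab = sp$lab, mask = sp$mask,
         small = sp$small,
         pair = image_dominant_pair(sp$lab, seed = seed + i))
  })
  class(recs) <- "complexion_cohort"
  recs
}

.cohort_labels <- function(cohort)
  vapply(cohort, `[[`, "", "label")

.bases_from_cohort <- function(cohort, include = seq_along(cohort),
                               seed = 1L) {
  labels <- .cohort_labels(cohort)
  class_images <- lapply(.BASE_CLASSES, function(cl) {
    lapply(intersect(include, which(labels == cl)),
           function(i) cohort[[i]]$pair)
  })
  names(class_images) <- .BASE_CLASSES
  build_all_bases(class_images, seed = seed)
}

#' Build the four bases from a processed cohort
#'
#' @param cohort A [cohort_pixels()] result.
#' @param seed FCM seed.
#' @return A `base_set`.
#' @export
cohort_bases <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "complexion_cohort"))
  .bases_from_cohort(cohort, seed = seed)
}

#' Whole-face feature matrix for a processed cohort
#'
#' @param cohort A [cohort_pixels()] result.
#' @param bases A `base_set`.
#' @param binning A [luminance_binning()].
#' @param include_base_bins Passed to [assign_pixels()].
#' @return `N x p` matrix of normalized complexion histograms.
#' @export
cohort_features <- function(cohort, bases, binning = luminance_binning(),
                            include_base_bins = TRUE) {
  t(vapply(cohort, function(rec)
    assign_pixels(rec$lab, bases, binning, include_base_bins)$values,
    numeric(feature_length(binning, include_base_bins))))
}

#' Leave-one-out evaluation of the facial-color model
#'
#' For every held-out image the four chromaticity bases are rebuilt from
#' the training images only, all features are re-extracted against those
#' bases, the SVM is trained with inner grid search, and the held-out
#' image is predicted. Feeding a plain feature matrix skips the per-fold
#' base rebuild and evaluates LOOCV on fixed features.
#'
#' With `paper_protocol = TRUE` the per-fold parameter choice is made by
#' the held-out sample's own outcome (an optimistic protocol kept for
#' comparison); the default is honest inner cross-validation.
#'
#' @param x A `complexion_cohort` or an `N x p` feature matrix.
#' @param labels Class labels (taken from the cohort when `x` is one).
#' @param C_grid,gamma_grid,inner_folds,seed See [train_svm()].
#' @param binning,include_base_bins Feature layout (cohort input only).
#' @param paper_protocol Optimistic per-fold selection switch.
#' @param progress Print per-fold progress.
#' @return An `evaluation_report` with extra fields `predicted` and
#'   `chosen_params`.
#' @export
loocv_evaluate <- function(x, labels = NULL, C_grid = svm_grids()$C,
                           gamma_grid = svm_grids()$gamma, inner_folds = 3L,
                           seed = 1L, binning = luminance_binning(),
                           include_base_bins = TRUE, paper_protocol = FALSE,
                           progress = FALSE) {
  is_cohort <- inherits(x, "complexion_cohort")
  if (is_cohort) labels <- .cohort_labels(x)
  labels <- as.character(labels)
  n <- if (is_cohort) length(x) else nrow(x)
  if (min(table(labels)) < 2) stop("LOOCV needs at least 2 images per class")
  lv <- intersect(.CLASS_LABELS, unique(labels))
  if (length(lv) == 0) lv <- sort(unique(labels))

  preds <- character(n)
  chosen <- data.frame(C = numeric(n), gamma = numeric(n))
  for (i in seq_len(n)) {
    if (is_cohort) {
      bases <- .bases_from_cohort(x, include = setdiff(seq_len(n), i),
                                  seed = seed)
      feats <- cohort_features(x, bases, binning, include_base_bins)
    } else {
      feats <- as.matrix(x)
    }
    tr <- setdiff(seq_len(n), i)
    if (paper_protocol) {
      ## optimistic reading: pick the first (smallest C, gamma) pair that
      ## classifies the held-out image correctly, else the inner-CV choice
      hit <- NULL
      for (g in sort(gamma_grid)) {
        for (cc in sort(C_grid)) {
          m <- e1071::svm(feats[tr, , drop = FALSE], factor(labels[tr]),
                          kernel = "radial", cost = cc, gamma = g,
                          scale = FALSE)
          if (as.character(predict(m, feats[i, , drop = FALSE])) == labels[i]) {
            hit <- list(model = m, C = cc, gamma = g); break
          }
        }
        if (!is.null(hit)) break
      }
      if (is.null(hit)) {
        mod <- train_svm(feats[tr, , drop = FALSE], labels[tr], C_grid,
                         gamma_grid, inner_folds, seed = seed + i)
        preds[i] <- predict(mod, feats[i, , drop = FALSE])
        chosen[i, ] <- c(mod$C, mod$gamma)
      } else {
        preds[i] <- as.character(predict(hit$model,
                                         feats[i, , drop = FALSE]))
        chosen[i, ] <- c(hit$C, hit$gamma)
      }
    } else {
      mod <- train_svm(feats[tr, , drop = FALSE], labels[tr], C_grid,
                       gamma_grid, inner_folds, seed = seed + i)
      preds[i] <- predict(mod, feats[i, , drop = FALSE])
      chosen[i, ] <- c(mod$C, mod$gamma)
    }
    if (progress) message(sprintf("fold %d/%d: true %s pred %s", i, n,
                                  labels[i], preds[i]))
  }
  cm <- table(factor(labels, levels = lv), factor(preds, levels = lv))
  rep <- metrics_from_confusion(unclass(as.matrix(cm)))
  rep$predicted <- preds
  rep$chosen_params <- chosen
  rep
}

#' Classifier-level fusion of five regional models
#'
#' Each regional model predicts a label; a class's score is the sum of the
#' weights of the regions voting for it and the highest score wins. Score
#' ties resolve to the prediction of the highest-weight region among the
#' tied classes (region order breaking equal weights).
#'
#' @param regional_models Named list of five `color_model`s.
#' @param regional_features Named list of five feature row vectors or
#'   single-row matrices.
#' @param weights Region weights.
#' @return Single predicted label.
#' @export
classifier_fusion_predict <- function(regional_models, regional_features,
                                      weights = region_weights_default()) {
  if (!all(.REGION_ORDER %in% names(regional_models)) ||
      !all(.REGION_ORDER %in% names(regional_features)))
    stop("regional models/features must cover all five regions")
  votes <- vapply(.REGION_ORDER, function(rg)
    predict(regional_models[[rg]],
            matrix(unlist(regional_features[[rg]]), nrow = 1)), "")
  score <- tapply(weights[.REGION_ORDER], votes, sum)
  top <- names(score)[score >= max(score) - 1e-12]
  if (length(top) == 1) return(top)
  ## tie: highest-weight region (region order breaks equal weights) that
  ## voted for a tied class decides
  ord <- .REGION_ORDER[order(-weights[.REGION_ORDER])]
  for (rg in ord) if (votes[[rg]] %in% top) return(votes[[rg]])
  top[1]
}

#' Sweep the luminance interval and record LOOCV accuracy
#'
#' Re-evaluates the cohort for each candidate luminance interval over the
#' `lo..hi` range, recording the feature dimension and total accuracy.
#' Invalid intervals are skipped with a warning.
#'
#' @param cohort A `complexion_cohort`.
#' @param intervals Candidate interval widths.
#' @param lo,hi Luminance range.
#' @param ... Passed to [loocv_evaluate()].
#' @return Data frame (`interval`, `feature_dim`, `loocv_accuracy`).
#' @export
interval_sweep <- function(cohort, intervals = c(1, 2, 3, 5, 7, 10, 14, 23, 35),
                           lo = 25, hi = 95, ...) {
  rows <- lapply(intervals, function(iv) {
    if (iv <= 0 || iv > hi - lo) {
      warning("skipping invalid interval ", iv)
      return(NULL)
    }
    bn <- luminance_binning(lo, hi, iv)
    rep <- loocv_evaluate(cohort, binning = bn, ...)
    data.frame(interval = iv, feature_dim = feature_length(bn, TRUE),
               loocv_accuracy = rep$accuracy)
  })
  do.call(rbind, rows)
}
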