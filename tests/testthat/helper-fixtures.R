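# shared, lazily built fixtures (generation is deterministic, so caching
# across test files only saves time, never changes results)
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# a small six-class cohort at reduced resolution for unit tests
mini_cohort <- function() cached("mini_cohort", {
  counts <- setNames(rep(4L, 6), complexion_classes())
  generate_cohort(counts, seed = 11, image_size = c(128, 128))
})

mini_pixels <- function() cached("mini_pixels", {
  cfg <- complexion_config(downscale_factor = 4L)
  cohort_pixels(mini_cohort(), cfg, use_true_mask = TRUE, seed = 11)
})

mini_bases <- function() cached("mini_bases", cohort_bases(mini_pixels(), seed = 3))

# per-class Lab pixel sets with mixed severities, including fully covered
# (unimodal) severe cases, built from ground-truth masks
class_pixel_sets <- function(class_label, n = 8, seed = 5,
                             minor = c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1, 1)) {
  lapply(seq_len(n), function(j) {
    fx <- generate_face(face_spec(class_label, minor_fraction = minor[j],
                                  seed = seed * 1000 + j,
                                  image_size = c(128, 128)))
    small <- downscale(fx$image, 4L)
    extract_skin_pixels(small, downscale_mask(fx$skin_mask, 4L))
  })
}

# independent Lloyd's k-means used as clustering oracle
lloyd_kmeans <- function(x, centers, iters = 100) {
  for (it in seq_len(iters)) {
    d2 <- sapply(seq_len(nrow(centers)), function(k)
      colSums((t(x) - centers[k, ])^2))
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (k in seq_len(nrow(centers)))
      if (any(assign == k))
        new_centers[k, ] <- colMeans(x[assign == k, , drop = FALSE])
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  list(centers = centers, cluster = assign)
}

# brute-force multiclass metrics by direct TP/FP/FN counting
brute_metrics <- function(m) {
  l <- nrow(m)
  tp <- fp <- fn <- numeric(l)
  for (i in seq_len(l)) for (j in seq_len(l)) {
    if (i == j) tp[i] <- tp[i] + m[i, j]
    if (i != j) { fn[i] <- fn[i] + m[i, j]; fp[j] <- fp[j] + m[i, j] }
  }
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  list(precision = prec, recall = rec,
       micro_precision = sum(tp) / sum(tp + fp),
       micro_recall = sum(tp) / sum(tp + fn),
       macro_precision = mean(prec), macro_recall = mean(rec))
}

# separable gaussian-cloud toy problems for classifier tests
toy_features <- function(n_per = 8, classes = 2, sep = 10, seed = 2) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(classes) - 1, function(k)
      matrix(rnorm(2 * n_per, k * sep, 0.3), ncol = 2)))
    list(x = x, y = rep(letters[seq_len(classes)], each = n_per))
  })
}
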