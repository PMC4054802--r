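test_that("the SVM separates a trivial two-class problem", {
  toy <- toy_features()
  mod <- train_svm(toy$x, toy$y, C_grid = 2^(0:4), gamma_grid = 2^(-2:2),
                   seed = 1)
  expect_equal(predict(mod, toy$x), toy$y)
  expect_error(predict(mod, toy$x[, 1, drop = FALSE]), "mismatch")
})

test_that("six classes yield fifteen pairwise models", {
  toy <- toy_features(n_per = 6, classes = 6, sep = 6)
  mod <- train_svm(toy$x, toy$y, C_grid = 2^(0:2), gamma_grid = 2^(-1:1),
                   seed = 1)
  # libsvm stores one offset per one-against-one binary model
  expect_length(mod$svm$rho, 15)
  expect_equal(predict(mod, toy$x), toy$y)
})

test_that("grid search is deterministic and tie-breaks to smaller C, gamma", {
  toy <- toy_features()
  m1 <- train_svm(toy$x, toy$y, C_grid = 2^(0:6), gamma_grid = 2^(-3:3),
                  seed = 9)
  m2 <- train_svm(toy$x, toy$y, C_grid = 2^(0:6), gamma_grid = 2^(-3:3),
                  seed = 9)
  expect_equal(c(m1$C, m1$gamma), c(m2$C, m2$gamma))
  # fully separable at every grid point: the smallest pair must win
  expect_equal(m1$C, 1)
  expect_equal(m1$gamma, 2^-3)
  expect_warning(
    train_svm(toy$x[c(1, 2, 9, 10), ], toy$y[c(1, 2, 9, 10)],
              C_grid = 2, gamma_grid = 1, inner_folds = 5, seed = 1),
    "reduced")
})

test_that("confusion-matrix metrics match hand-derived values", {
  m <- matrix(c(2, 1, 0, 3), 2, 2, byrow = TRUE)
  rep <- metrics_from_confusion(m)
  expect_equal(rep$per_class$precision, c(1, 0.75))
  expect_equal(rep$per_class$recall, c(2 / 3, 1))
  expect_equal(unname(rep$micro["precision"]), 5 / 6)
  expect_equal(unname(rep$micro["recall"]), 5 / 6)
  expect_equal(unname(rep$macro["precision"]), 0.875)
  expect_equal(unname(rep$macro["recall"]), 5 / 6)
  expect_equal(rep$accuracy, 5 / 6)
  expect_equal(rowSums(rep$recall_matrix), c(1, 1), ignore_attr = TRUE)

  perfect <- metrics_from_confusion(diag(c(4, 5, 6)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$micro), c(1, 1, 1))
  expect_equal(unname(perfect$macro), c(1, 1, 1))

  expect_error(metrics_from_confusion(matrix(1, 2, 3)), "square")
})

test_that("metrics agree with brute-force counting on random matrices", {
  set.seed(31)
  for (rep_i in 1:25) {
    l <- sample(2:6, 1)
    m <- matrix(rpois(l * l, 3), l, l)
    if (sum(m) == 0) m[1, 1] <- 1
    got <- metrics_from_confusion(m)
    want <- brute_metrics(m)
    expect_equal(got$per_class$precision, want$precision)
    expect_equal(got$per_class$recall, want$recall)
    expect_equal(unname(got$micro["precision"]), want$micro_precision)
    expect_equal(unname(got$macro["recall"]), want$macro_recall)
    # micro precision, recall and F coincide for single-label confusion
    expect_equal(unname(got$micro["precision"]), unname(got$micro["f"]))
  }
})

test_that("LOOCV on fixed features handles ideal and impossible cohorts", {
  # one-hot features: every fold is perfectly separable
  y <- rep(c("a", "b", "c"), each = 4)
  x <- diag(3)[match(y, c("a", "b", "c")), ]
  rep <- loocv_evaluate(x, y, C_grid = 2^(0:2), gamma_grid = 2^(-1:1),
                        inner_folds = 2, seed = 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(unname(rep$macro["f"]), 1)

  # identical features with conflicting labels: majority always wins the
  # held-out minority, so nothing is ever right
  x2 <- matrix(1, 4, 2)
  y2 <- c("a", "b", "a", "b")
  rep2 <- loocv_evaluate(x2, y2, C_grid = 1, gamma_grid = 1,
                         inner_folds = 2, seed = 1)
  expect_equal(rep2$accuracy, 0)

  expect_error(loocv_evaluate(x2, c("a", "b", "c", "d"), C_grid = 1,
                              gamma_grid = 1), "2 images per class")
})

test_that("per-fold base rebuilding never reads the held-out image", {
  co <- mini_pixels()
  drop1 <- getFromNamespace(".bases_from_cohort", "complexion")
  b_ref <- drop1(co, include = 2:length(co), seed = 5)
  co_perturbed <- co
  co_perturbed[[1]]$lab <- co_perturbed[[1]]$lab + 100
  co_perturbed[[1]]$pair$dominant <- c(999, 999)
  b_pert <- drop1(co_perturbed, include = 2:length(co), seed = 5)
  expect_identical(base_matrix(b_ref), base_matrix(b_pert))
})

test_that("cohort LOOCV rebuilds bases per fold and reports correctly", {
  co <- mini_pixels()
  rep <- loocv_evaluate(co, C_grid = 2^c(0, 4, 8), gamma_grid = 2^c(-4, 0, 4),
                        inner_folds = 2, seed = 3)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(sum(rep$confusion_matrix), length(co))
  labels <- vapply(co, `[[`, "", "label")
  expect_equal(unname(rowSums(rep$confusion_matrix)),
               unname(as.vector(table(factor(labels,
                 levels = complexion_classes())))))
  expect_gte(rep$accuracy, 0.75)
})

test_that("classifier-level fusion weights regional votes", {
  toy <- toy_features(n_per = 6, classes = 2, sep = 8)
  mod <- train_svm(toy$x, toy$y, C_grid = 2, gamma_grid = 0.5, seed = 1)
  regions <- c("left_cheek", "right_cheek", "forehead", "nose", "jaw")
  models <- setNames(rep(list(mod), 5), regions)
  feat_a <- toy$x[1, , drop = FALSE]   # predicts "a"
  feat_b <- toy$x[7, , drop = FALSE]   # predicts "b"

  all_a <- setNames(rep(list(feat_a), 5), regions)
  expect_equal(classifier_fusion_predict(models, all_a), "a")

  # cheeks (0.6) beat the rest (0.4)
  mixed <- setNames(list(feat_a, feat_a, feat_b, feat_b, feat_b), regions)
  expect_equal(classifier_fusion_predict(models, mixed), "a")

  # exact tie 0.5/0.5: the highest-weight region's vote wins, with the
  # fixed region order breaking equal weights (left cheek first)
  tied <- setNames(list(feat_a, feat_b, feat_b, feat_b, feat_a), regions)
  w <- c(left_cheek = 0.3, right_cheek = 0.3, forehead = 0.1, nose = 0.1,
         jaw = 0.2)
  expect_equal(classifier_fusion_predict(models, tied, w), "a")
  expect_error(classifier_fusion_predict(models[-1], tied), "five regions")
})

test_that("the luminance-interval sweep tabulates dimension and accuracy", {
  # three faces per chromatic class plus white/black, so every fold still
  # has two images per base class
  co <- mini_pixels()[c(1:3, 5:7, 9:11, 13:15, 17:18, 21:22)]
  class(co) <- "complexion_cohort"
  expect_warning(
    tab <- interval_sweep(co, c(35, 80), C_grid = 2^c(0, 6),
                          gamma_grid = 2^c(-2, 2), inner_folds = 2, seed = 2),
    "invalid interval")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$feature_dim, 12)

  tab2 <- interval_sweep(co, c(1, 35), C_grid = 2^c(0, 6),
                         gamma_grid = 2^c(-2, 2), inner_folds = 2, seed = 2)
  expect_equal(tab2$feature_dim, c(284, 12))
  expect_true(all(tab2$loocv_accuracy >= 0 & tab2$loocv_accuracy <= 1))
})
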