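# Gradient-boosted noise classifier: training, prediction, filtering,
# confusion matrices.

fast_search <- function(n_iter = 2) {
  space <- default_search_space()
  space$n_estimators <- c(30, 80)
  search_config(n_iter = n_iter, space = space)
}

test_that("training learns a separable fixture and predicts its classes", {
  fm <- separable_fixture(n = 600, seed = 7)
  y <- ifelse(fm[, "TLOD"] > 1.5, "signal", "noise")
  model <- train_noise_classifier(fm, y, fast_search(), seed = 7)
  expect_gte(cv_auc(model), 0.99)
  p <- predict_noise_probability(model, fm)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean((p > 0.5) == (y == "signal")), 0.95)
  # importances: nonnegative, and untouched features get exactly zero
  expect_true(all(model$importances >= 0))
  expect_equal(unname(model$importances["AF"]), 0, tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  fm <- separable_fixture(n = 300, seed = 3)
  y <- ifelse(fm[, "TLOD"] > 1.5, "signal", "noise")
  m1 <- train_noise_classifier(fm, y, fast_search(), seed = 5)
  m2 <- train_noise_classifier(fm, y, fast_search(), seed = 5)
  expect_identical(predict_noise_probability(m1, fm),
                   predict_noise_probability(m2, fm))
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  # scoring twice is bitwise-identical
  expect_identical(predict_noise_probability(m1, fm),
                   predict_noise_probability(m1, fm))
})

test_that("degenerate inputs are contract errors", {
  fm <- separable_fixture(n = 100, seed = 2)
  expect_error(train_noise_classifier(fm, rep("noise", nrow(fm)),
                                      fast_search(), seed = 1),
               "2 rows of each class")
  expect_error(train_noise_classifier(fm, rep("signal", 5), fast_search(),
                                      seed = 1), "length")
  plain <- unclass(fm); attr(plain, "registry") <- NULL
  expect_error(train_noise_classifier(plain, rep("noise", nrow(fm)),
                                      fast_search(), seed = 1), "registry")
})

test_that("prediction refuses a mismatched registry and handles empties", {
  fm <- separable_fixture(n = 200, seed = 4)
  y <- ifelse(fm[, "TLOD"] > 1.5, "signal", "noise")
  model <- train_noise_classifier(fm, y, fast_search(), seed = 4)
  other <- build_feature_matrix(
    toy_callset(data.frame(chrom = "chr1", pos = 1L, ref = "C", alt = "T")))
  expect_error(predict_noise_probability(model, other), "registry")
  empty <- fm[integer(0), , drop = FALSE]
  attr(empty, "registry") <- attr(fm, "registry")
  class(empty) <- class(fm)
  expect_length(predict_noise_probability(model, empty), 0)
})

test_that("ML filtering respects cutoff boundaries and monotonicity", {
  co <- small_cohort()
  wes_f <- lapply(co$wes, filter_wes_matched)
  pooled <- merge_callsets(unname(co$rnaseq))
  lab <- label_by_wes(pooled, wes_f)
  fm <- build_feature_matrix(pooled)
  model <- train_noise_classifier(fm, lab$labels, fast_search(), seed = 9)
  cs <- co$rnaseq[[1]]
  expect_equal(apply_ml_filter(cs, model, 0)$variants, cs$variants)
  sizes <- sapply(c(0, 0.25, 0.5, 0.75, 1),
                  function(ct) n_variants(apply_ml_filter(cs, model, ct)))
  expect_true(all(diff(sizes) <= 0))
  p <- predict_noise_probability(model, build_feature_matrix(cs))
  expect_equal(sizes[[5]], sum(p >= 1))
  expect_error(apply_ml_filter(cs, model, 1.5), "cutoff")
})

test_that("confusion matrix counts the four cells with signal positive", {
  cm <- compute_confusion(c(1, 0, 1, 0), c(1, 0, 0, 0))
  expect_equal(cm[c("TN", "FN", "FP", "TP")],
               list(TN = 2L, FN = 1L, FP = 0L, TP = 1L),
               ignore_attr = TRUE)
  perfect <- compute_confusion(c("signal", "noise"), c("signal", "noise"))
  expect_equal(perfect$FP + perfect$FN, 0)
  expect_error(compute_confusion(c(1, 0), c(1, 0, 1)), "length")
  # cells always partition the classified variants
  set.seed(1)
  y <- runif(50) < 0.3; p <- runif(50) < 0.5
  cm <- compute_confusion(y, p)
  expect_equal(cm$TN + cm$FN + cm$FP + cm$TP, 50)
})

test_that("model save/load round trips and still guards the registry", {
  fm <- separable_fixture(n = 200, seed = 6)
  y <- ifelse(fm[, "TLOD"] > 1.5, "signal", "noise")
  model <- train_noise_classifier(fm, y, fast_search(), seed = 6)
  path <- tempfile(fileext = ".bin")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(predict_noise_probability(back, fm),
                   predict_noise_probability(model, fm))
  expect_identical(back$registry_hash, model$registry_hash)
})
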