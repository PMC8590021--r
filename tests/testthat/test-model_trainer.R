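# dataset whose label is a deterministic step function of one shape feature
step_dataset <- function(n = 2000, seed = 1) {
  set.seed(seed)
  m <- 6L; b <- 4L
  p <- 13L * (m + 2L * b)
  feats <- matrix(runif(n * p), n, p,
                  dimnames = list(NULL, feature_vector_names(m, b)))
  thr <- stats::median(feats[, "roll@1"])
  label <- 200 + 600 * (feats[, "roll@1"] > thr)
  sites <- data.frame(bound = label > 400, label = label, weight = 1,
                      score = rnorm(n), signal = label)
  tf_dataset(sites, feats, m, b, split = split_dataset(sites, seed = seed))
}

test_that("noise-free single-feature signal is recovered almost perfectly", {
  ds <- step_dataset()
  sp <- hyper_space(iterations = 10, folds = 3)
  model <- train(ds, sp, b = 4, seed = 1)
  tr <- ds$split$train
  pred <- predict(model, ds$features[tr, ])
  r2 <- 1 - sum((ds$sites$label[tr] - pred)^2) /
    sum((ds$sites$label[tr] - mean(ds$sites$label[tr]))^2)
  expect_gt(r2, 0.95)
  expect_true(all(pred >= model$label_range[1]))
  expect_true(all(pred <= model$label_range[2]))
  # chosen_params minimizes the reported CV loss
  expect_equal(min(model$cv_report$cv_mse),
               model$cv_report$cv_mse[
                 model$cv_report$n_trees == model$chosen_params$n_trees &
                 model$cv_report$max_features == model$chosen_params$max_features &
                 model$cv_report$max_depth == model$chosen_params$max_depth][1])
})

test_that("training is deterministic under fixed seeds", {
  ds <- step_dataset(n = 400)
  sp <- hyper_space(iterations = 3, folds = 2)
  m1 <- train(ds, sp, b = 2, seed = 7)
  m2 <- train(ds, sp, b = 2, seed = 7)
  expect_identical(m1$chosen_params, m2$chosen_params)
  va <- ds$split$validation
  x <- select_border(ds, 2)[va, ]
  expect_identical(predict(m1, x), predict(m2, x))
  m3 <- train(ds, sp, b = 2, seed = 8)
  expect_false(identical(m1$chosen_params, m3$chosen_params) &&
               identical(predict(m1, x), predict(m3, x)))
})

test_that("the validation split is never touched during model selection", {
  ds <- step_dataset(n = 400)
  # poison the validation rows: any access during selection/refit would
  # propagate NaN into fits or predictions
  ds$features[ds$split$validation, ] <- NaN
  sp <- hyper_space(iterations = 2, folds = 2)
  model <- train(ds, sp, b = 2, seed = 1)
  tr <- ds$split$train
  pred <- predict(model, select_border(ds, 2)[tr, ])
  expect_true(all(is.finite(pred)))
})

test_that("randomized search draws unique combinations within the ranges", {
  sp <- hyper_space(n_trees = c(10, 12), max_features = c("sqrt", "log2"),
                    max_depth = c(4, 5), iterations = 75, folds = 2)
  cand <- shapetf:::sample_hyperparams(sp, seed = 1)
  expect_equal(nrow(cand), 12L)  # grid smaller than iterations
  expect_equal(anyDuplicated(cand), 0L)
  expect_true(all(cand$n_trees %in% 10:12))
  expect_true(all(cand$max_depth %in% 4:5))

  cand2 <- shapetf:::sample_hyperparams(hyper_space(iterations = 20), 1)
  expect_equal(nrow(cand2), 20L)
  expect_equal(anyDuplicated(cand2), 0L)
  expect_true(all(cand2$n_trees >= 10 & cand2$n_trees <= 200))
  expect_true(all(cand2$max_depth >= 4 & cand2$max_depth <= 12))
})

test_that("prediction validates feature names and averages leaf values", {
  ds <- step_dataset(n = 300)
  model <- train(ds, hyper_space(iterations = 1, folds = 2), b = 2,
                 seed = 1)
  x <- select_border(ds, 2)[1:3, ]
  bad <- x
  colnames(bad)[1] <- "oops@1"
  expect_error(predict(model, bad), "oops@1")

  # hand-built ensembles: stump and two constant trees
  stump <- stump_ensemble(0L, 0.5, 0, 1000)
  expect_equal(shapetf:::predict_ensemble(stump, matrix(c(0.9, 0.1), 2, 1)),
               c(1000, 0))
  two_const <- structure(list(trees = c(stump_ensemble(0L, 0.5, 0, 0)$trees,
                                        stump_ensemble(0L, 0.5, 1000, 1000)$trees)),
                         class = "tree_ensemble")
  expect_equal(shapetf:::predict_ensemble(two_const, matrix(0.3, 1, 1)), 500)
})

test_that("pr_curve matches hand-computed values and the confusion-sweep oracle", {
  pr <- pr_curve(c(0.9, 0.8, 0.3, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(pr$auprc, 1 * 0.5 + (2 / 3) * 0.5)

  perfect <- pr_curve(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auprc, 1)

  const <- pr_curve(rep(2, 10), rep(c(TRUE, FALSE), c(3, 7)))
  expect_length(const$precision, 1L)
  expect_equal(const$precision, 0.3)
  expect_equal(const$recall, 1)
  expect_equal(const$auprc, 0.3)

  expect_error(pr_curve(1:3, c(FALSE, FALSE, FALSE)), "no positive")

  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), sample(1:3, 1))  # force ties sometimes
    flags <- runif(n) < 0.4
    if (!any(flags)) flags[1] <- TRUE
    expect_equal(pr_curve(scores, flags)$auprc, naive_auprc(scores, flags))
  }

  # recall is non-decreasing along the threshold sweep
  pr2 <- pr_curve(runif(100), runif(100) < 0.3)
  expect_true(all(diff(pr2$recall) >= 0))
  expect_true(pr2$auprc >= 0 && pr2$auprc <= 1)
})

test_that("motif-only baseline behaves as an uninformative / perfect ranker", {
  flags <- rep(c(TRUE, FALSE), c(10, 40))
  expect_equal(baseline_auprc(rep(3.2, 50), flags)$auprc, 0.2)
  expect_equal(baseline_auprc(ifelse(flags, 2, 1), flags)$auprc, 1)
})

test_that("width sweep trains per border and validates inputs", {
  ds <- step_dataset(n = 400)
  sp <- hyper_space(iterations = 2, folds = 2)
  sw <- width_sweep(ds, c(0, 2), sp, seed = 3)
  expect_equal(sw$b, c(0, 2))
  expect_true(all(sw$auprc >= 0 & sw$auprc <= 1))
  expect_error(width_sweep(ds, 40, sp), "widths")
})

test_that("datasets serialize to a delimited table with a provenance sidecar", {
  ds <- step_dataset(n = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t",
                            check.names = FALSE)
  expect_equal(nrow(back), 50L)
  expect_true(all(c("bound", "label", "weight",
                    feature_vector_names(6L, 4L)) %in% names(back)))
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$motif_length, 6L)
  expect_setequal(c(side$split$train, side$split$validation), 1:50)
})

test_that("serialized predictors reproduce predictions exactly", {
  ds <- step_dataset(n = 300)
  model <- train(ds, hyper_space(iterations = 1, folds = 2), b = 2,
                 seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  save_predictor(model, f)
  back <- load_predictor(f)
  x <- select_border(ds, 2)[1:20, ]
  expect_equal(predict(back, x), predict(model, x))
  expect_equal(back$chosen_params$n_trees, model$chosen_params$n_trees)
})
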