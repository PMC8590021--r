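#' Hyperparameter search space for the random forest regressor
#'
#' The randomized search draws parameter combinations uniformly (without
#' replacement) from the grid of tree counts, feature subsampling rules and
#' tree depths, and scores each by k-fold cross-validated weighted mean
#' squared error.
#'
#' @param n_trees Integer range (min, max) of trees per forest.
#' @param max_features Candidate feature subsampling rules: \code{"all"}
#'   (every feature considered at each split), \code{"sqrt"} or
#'   \code{"log2"}.
#' @param max_depth Integer range (min, max) of tree depth.
#' @param iterations Number of parameter combinations drawn (default 75).
#' @param folds Cross-validation folds (default 5, i.e. an inner 4:1
#'   train/test split).
#' @return Object of class \code{hyper_space}.
#' @export
hyper_space <- function(n_trees = c(10L, 200L),
                        max_features = c("all", "sqrt", "log2"),
                        max_depth = c(4L, 12L),
                        iterations = 75L, folds = 5L) {
  stopifnot(length(n_trees) == 2L, n_trees[1L] >= 1L,
            n_trees[1L] <= n_trees[2L],
            length(max_depth) == 2L, max_depth[1L] >= 1L,
            max_depth[1L] <= max_depth[2L],
            iterations >= 1L, folds >= 2L,
            all(max_features %in% c("all", "sqrt", "log2")))
  structure(list(n_trees = as.integer(n_trees),
                 max_features = max_features,
                 max_depth = as.integer(max_depth),
                 iterations = as.integer(iterations),
                 folds = as.integer(folds)),
            class = "hyper_space")
}

# Uniform draw of parameter combinations without replacement; if the grid is
# smaller than `iterations` the whole grid is used.
sample_hyperparams <- function(space, seed) {
  grid <- expand.grid(
    n_trees = seq.int(space$n_trees[1L], space$n_trees[2L]),
    max_features = space$max_features,
    max_depth = seq.int(space$max_depth[1L], space$max_depth[2L]),
    stringsAsFactors = FALSE)
  k <- min(space$iterations, nrow(grid))
  grid[with_seed(seed, sample(nrow(grid), k)), , drop = FALSE]
}

mtry_for_rule <- function(rule, p) {
  switch(rule,
         all = p,
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         stop("unknown max_features rule: ", rule))
}

fit_ranger <- function(x, y, w, n_trees, max_features, max_depth, seed) {
  ranger::ranger(
    x = as.data.frame(x, check.names = FALSE), y = y,
    case.weights = w, num.trees = n_trees,
    mtry = mtry_for_rule(max_features, ncol(x)),
    max.depth = max_depth, seed = seed, num.threads = 1L,
    verbose = FALSE)
}

#' Train the shape-based random forest affinity regressor
#'
#' Draws \code{iterations} hyperparameter combinations, scores each by
#' k-fold cross-validated weighted MSE on the training split only, refits
#' the best combination on the whole training split and returns the fitted
#' predictor. The validation split is never used during selection.
#'
#' @param dataset A \code{tf_dataset} with both bound and unbound sites and
#'   weights set.
#' @param space A \code{\link{hyper_space}}.
#' @param b Flank width (bases) of shape features to train on (default 4);
#'   must not exceed the dataset's pre-computed \code{b_max}.
#' @param seed Integer seed for the parameter draw, fold assignment and
#'   forest growth.
#' @return Object of class \code{shape_rf}: the ranger forest, extracted
#'   tree structures, \code{chosen_params}, \code{feature_names},
#'   \code{label_range}, a per-candidate \code{cv_report} and the seed.
#' @export
train <- function(dataset, space = hyper_space(), b = 4L, seed = 1L) {
  stopifnot(inherits(dataset, "tf_dataset"), inherits(space, "hyper_space"))
  x_all <- select_border(dataset, b)
  tr <- dataset$split$train
  if (length(unique(dataset$sites$bound[tr])) < 2L) {
    stop("training split contains a single class; cannot train")
  }
  x <- x_all[tr, , drop = FALSE]
  y <- dataset$sites$label[tr]
  w <- dataset$sites$weight[tr]
  if (is.null(w)) stop("sample weights are not set")

  cand <- sample_hyperparams(space, seed)
  folds <- with_seed(seed + 1L,
                     sample(rep_len(seq_len(space$folds), length(tr))))
  cv_loss <- matrix(NA_real_, nrow = nrow(cand), ncol = space$folds)
  for (i in seq_len(nrow(cand))) {
    for (f in seq_len(space$folds)) {
      in_fold <- folds == f
      fit <- fit_ranger(x[!in_fold, , drop = FALSE], y[!in_fold],
                        w[!in_fold], cand$n_trees[i],
                        cand$max_features[i], cand$max_depth[i],
                        seed = seed + 100L + f)
      pred <- stats::predict(
        fit, as.data.frame(x[in_fold, , drop = FALSE],
                           check.names = FALSE),
        num.threads = 1L)$predictions
      cv_loss[i, f] <- sum(w[in_fold] * (y[in_fold] - pred)^2) /
        sum(w[in_fold])
    }
  }
  mean_loss <- rowMeans(cv_loss)
  best <- which.min(mean_loss)
  final <- fit_ranger(x, y, w, cand$n_trees[best], cand$max_features[best],
                      cand$max_depth[best], seed = seed + 1000L)

  cv_report <- cbind(cand, cv_mse = mean_loss)
  rownames(cv_report) <- NULL
  structure(
    list(forest = final,
         trees = ranger_to_ensemble(final),
         chosen_params = list(n_trees = cand$n_trees[best],
                              max_features = cand$max_features[best],
                              max_depth = cand$max_depth[best]),
         feature_names = colnames(x),
         label_range = range(y),
         cv_report = cv_report,
         motif_length = dataset$motif_length, b = b, seed = seed),
    class = "shape_rf")
}

#' @export
print.shape_rf <- function(x, ...) {
  cat("Shape-based random forest regressor\n")
  cat(sprintf("  chosen: n_trees = %d, max_features = '%s', max_depth = %d\n",
              x$chosen_params$n_trees, x$chosen_params$max_features,
              x$chosen_params$max_depth))
  cat(sprintf("  %d features (motif length %d, border %d), labels in [%g, %g]\n",
              length(x$feature_names), x$motif_length, x$b,
              x$label_range[1L], x$label_range[2L]))
  invisible(x)
}

#' Predict binding affinity for shape feature vectors
#'
#' @param object A \code{shape_rf}.
#' @param newdata Feature matrix (or single named vector) whose column
#'   names match the model's features exactly.
#' @param ... Unused.
#' @return Numeric vector of predicted affinities (ensemble-mean leaf
#'   values, always within the training label range).
#' @export
predict.shape_rf <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  nm <- colnames(newdata)
  if (is.null(nm) || !identical(nm, object$feature_names)) {
    bad <- if (is.null(nm)) "(no column names)" else {
      mism <- which(nm != object$feature_names[seq_along(nm)])
      if (length(mism) > 0L) {
        sprintf("'%s' (expected '%s')", nm[mism[1L]],
                object$feature_names[mism[1L]])
      } else "(column count mismatch)"
    }
    stop("feature name mismatch: ", bad)
  }
  stats::predict(object$forest,
                 as.data.frame(newdata, check.names = FALSE),
                 num.threads = 1L)$predictions
}

#' Precision-recall curve and area under it
#'
#' Sweeps every distinct score as a threshold (descending), grouping ties,
#' and integrates by the average-precision convention
#' \code{sum(precision_k * delta_recall_k)}.
#'
#' @param scores Numeric ranking scores (higher = more confidently bound).
#' @param bound_flags Logical truth labels; at least one must be TRUE.
#' @return Object of class \code{pr_curve}: list with \code{thresholds},
#'   \code{precision}, \code{recall}, \code{auprc}, \code{positives}.
#' @export
pr_curve <- function(scores, bound_flags) {
  stopifnot(length(scores) == length(bound_flags))
  bound_flags <- as.logical(bound_flags)
  P <- sum(bound_flags)
  if (P == 0L) stop("no positive examples; precision-recall is undefined")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- bound_flags[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  precision <- tp / n_at
  recall <- tp / P
  d_recall <- diff(c(0, recall))
  auprc <- sum(precision * d_recall)
  structure(list(thresholds = s[grp_end], precision = precision,
                 recall = recall, auprc = auprc, positives = P),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("Precision-recall curve: %d thresholds, %d positives, AUPRC = %.4f\n",
              length(x$thresholds), x$positives, x$auprc))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  graphics::plot(c(0, x$recall), c(1, x$precision), type = "s",
                 xlab = "Recall", ylab = "Precision",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  invisible(x)
}

#' Motif-only baseline precision-recall curve
#'
#' Ranks the same sites by their PWM log-odds score instead of the model's
#' prediction; this is the "motif alone" comparator.
#'
#' @param pwm_scores Log-odds scores of the sites.
#' @param bound_flags Logical truth labels.
#' @return A \code{pr_curve}.
#' @export
baseline_auprc <- function(pwm_scores, bound_flags) {
  pr_curve(pwm_scores, bound_flags)
}

#' Evaluate a trained model on the validation split
#'
#' @param model A \code{shape_rf}.
#' @param dataset The \code{tf_dataset} it was trained on.
#' @return List with the model's \code{pr} curve, the motif-only
#'   \code{baseline} curve on the same validation sites, and the
#'   validation \code{predictions}.
#' @export
evaluate_model <- function(model, dataset) {
  va <- dataset$split$validation
  x <- select_border(dataset, model$b)[va, , drop = FALSE]
  pred <- predict(model, x)
  flags <- dataset$sites$bound[va]
  list(pr = pr_curve(pred, flags),
       baseline = baseline_auprc(dataset$sites$score[va], flags),
       predictions = pred)
}

#' Border width sweep
#'
#' Re-trains the model at each flank width in \code{widths} on the same
#' split with the same seeds and records the validation AUPRC, tracing how
#' much predictive information the flanking shape adds beyond the core
#' motif.
#'
#' @param dataset A \code{tf_dataset} with features pre-computed to
#'   \code{b_max}.
#' @param widths Integer flank widths, all within \code{[0, b_max]}.
#' @param space A \code{\link{hyper_space}}.
#' @param seed Integer seed shared across widths.
#' @return Data frame with columns \code{b}, \code{auprc},
#'   \code{n_trees}, \code{max_features}, \code{max_depth}.
#' @export
width_sweep <- function(dataset, widths, space = hyper_space(), seed = 1L) {
  if (any(widths < 0L) || any(widths > dataset$b_max)) {
    stop("widths must lie within [0, ", dataset$b_max, "]")
  }
  rows <- lapply(widths, function(b) {
    model <- train(dataset, space, b = b, seed = seed)
    ev <- evaluate_model(model, dataset)
    data.frame(b = b, auprc = ev$pr$auprc,
               n_trees = model$chosen_params$n_trees,
               max_features = model$chosen_params$max_features,
               max_depth = model$chosen_params$max_depth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
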