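# Convert a fitted ranger forest into the plain tree-array representation
# used by the C++ Shapley kernel and the serialized model format.
# Each tree: integer vectors left/right (0-based child ids, -1 at leaves),
# feature (0-based split feature, -1 at leaves), numeric split thresholds
# ("x <= threshold" goes left) and leaf values.
ranger_to_ensemble <- function(rf) {
  stopifnot(inherits(rf, "ranger"))
  trees <- lapply(seq_len(rf$num.trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    leaf <- ti$terminal
    list(left = ifelse(leaf, -1L, as.integer(ti$leftChild)),
         right = ifelse(leaf, -1L, as.integer(ti$rightChild)),
         feature = ifelse(leaf, -1L, as.integer(ti$splitvarID)),
         split = ifelse(leaf, 0, as.numeric(ti$splitval)),
         value = ifelse(leaf, as.numeric(ti$prediction), 0))
  })
  structure(list(trees = trees), class = "tree_ensemble")
}

as_tree_ensemble <- function(model) {
  if (inherits(model, "tree_ensemble")) return(model)
  if (inherits(model, "shape_rf")) return(model$trees)
  stop("model must be a shape_rf or tree_ensemble")
}

# Ensemble-mean prediction straight from the extracted tree arrays;
# independent of ranger's own predict path.
predict_ensemble <- function(ensemble, x) {
  ensemble <- as_tree_ensemble(ensemble)
  if (is.null(dim(x))) x <- t(as.matrix(x))
  ensemble_predict_cpp(ensemble$trees, as.matrix(x))
}

#' Exact interventional Shapley attributions for a tree ensemble
#'
#' Computes, for each sample, the exact Shapley value of every feature with
#' respect to an explicit background dataset (interventional feature
#' perturbation): missing features are replaced by background values and
#' the resulting hybrid predictions are averaged over the background. The
#' attributions satisfy local accuracy, i.e.
#' \code{base_value + sum(contributions) == prediction} for every sample,
#' and a feature used by no tree gets attribution 0.
#'
#' @param model A \code{shape_rf} or \code{tree_ensemble}.
#' @param samples Feature matrix of samples to explain (or a single named
#'   vector); columns must match the model's features.
#' @param background Feature matrix of background samples (non-empty).
#' @return Object of class \code{shap_attribution}: list with
#'   \code{values} (samples x features matrix of contributions),
#'   \code{base_value} (expected model output over the background) and
#'   \code{feature_names}.
#' @export
tree_shap <- function(model, samples, background) {
  ensemble <- as_tree_ensemble(model)
  if (is.null(dim(samples))) samples <- t(as.matrix(samples))
  if (is.null(dim(background))) background <- t(as.matrix(background))
  if (nrow(background) == 0L) stop("background must be non-empty")
  if (inherits(model, "shape_rf")) {
    for (nm in list(colnames(samples), colnames(background))) {
      if (!is.null(nm) && !identical(nm, model$feature_names)) {
        stop("feature name mismatch between model and data")
      }
    }
  }
  if (ncol(samples) != ncol(background)) {
    stop("samples and background must have the same number of features")
  }
  res <- treeshap_interventional_cpp(ensemble$trees, as.matrix(samples),
                                     as.matrix(background))
  colnames(res$values) <- colnames(samples)
  structure(list(values = res$values, base_value = res$base_value,
                 feature_names = colnames(samples)),
            class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat(sprintf("Shapley attributions: %d sample(s) x %d features, base value %.3f\n",
              nrow(x$values), ncol(x$values), x$base_value))
  invisible(x)
}

#' Global feature importance from Shapley attributions
#'
#' Ranks features by the mean absolute Shapley contribution over a sample
#' set; ties are broken by the fixed feature-vector order (position-major,
#' the 13 shape features within each position).
#'
#' @param model A \code{shape_rf} (or \code{tree_ensemble}).
#' @param samples Feature matrix of samples to attribute over (non-empty).
#' @param background Background feature matrix.
#' @param k Size of the extracted top list (default 5).
#' @return Object of class \code{importance_report}: list with
#'   \code{ranking} (data frame: feature, mean_abs_shap), \code{top_k}
#'   (character vector) and the attribution object.
#' @export
global_importance <- function(model, samples, background, k = 5L) {
  if (is.null(dim(samples))) samples <- t(as.matrix(samples))
  if (nrow(samples) == 0L) stop("samples must be non-empty")
  att <- tree_shap(model, samples, background)
  mean_abs <- colMeans(abs(att$values))
  nm <- att$feature_names
  if (is.null(nm)) nm <- paste0("f", seq_along(mean_abs))
  ord <- order(-mean_abs, seq_along(mean_abs))
  ranking <- data.frame(feature = nm[ord], mean_abs_shap = mean_abs[ord],
                        stringsAsFactors = FALSE)
  if (k > length(nm)) {
    warning("k = ", k, " exceeds the number of features (", length(nm),
            "); returning the full ranking")
    k <- length(nm)
  }
  structure(list(ranking = ranking, top_k = ranking$feature[seq_len(k)],
                 attribution = att),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Top shape features by mean |Shapley value|:\n")
  print(utils::head(x$ranking, length(x$top_k)), row.names = FALSE)
  invisible(x)
}

# Split "feature@position" names into their parts.
parse_feature_names <- function(names) {
  parts <- regmatches(names, regexec("^(.+)@([+-]?[0-9]+)$", names))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    stop("unparseable feature name(s): ",
         paste(utils::head(names[bad], 3L), collapse = ", "))
  }
  feat <- vapply(parts, `[[`, "", 2L)
  pos <- vapply(parts, `[[`, "", 3L)
  unknown <- setdiff(feat, SHAPE_FEATURES)
  if (length(unknown) > 0L) {
    stop("unknown shape feature(s): ", paste(unknown, collapse = ", "))
  }
  cls <- ifelse(feat == "MGW", "MGW",
                ifelse(feat %in% SHAPE_INTRA_FEATURES, "intra", "inter"))
  region <- ifelse(grepl("^[+-]", pos), "flank", "core")
  data.frame(feature = feat, position = pos, shape_class = cls,
             region = region, stringsAsFactors = FALSE)
}

#' Categorize top features by shape class and motif region
#'
#' Summarizes a top-feature list into the fraction falling inside the core
#' motif versus the flanks, and — among the base-pair shape parameters —
#' the intra- versus inter-base-pair split. Minor groove width is a derived
#' groove geometry, not a base-pair parameter, so it is reported as its own
#' class and excluded from the intra/inter split.
#'
#' @param report An \code{importance_report} or a character vector of
#'   \code{"feature@position"} names.
#' @param motif_length Core motif length (used only for display).
#' @return List with \code{core_fraction}, \code{flank_fraction},
#'   \code{intra_fraction}, \code{inter_fraction} (of non-MGW features),
#'   \code{mgw_fraction} and the per-feature \code{table}.
#' @export
categorize <- function(report, motif_length = NULL) {
  feats <- if (inherits(report, "importance_report")) report$top_k
           else as.character(report)
  if (length(feats) == 0L) {
    warning("empty feature list; all fractions are 0")
    return(list(core_fraction = 0, flank_fraction = 0,
                intra_fraction = 0, inter_fraction = 0,
                mgw_fraction = 0,
                table = parse_feature_names(character())))
  }
  tab <- parse_feature_names(feats)
  n <- nrow(tab)
  non_mgw <- tab$shape_class != "MGW"
  n_nm <- sum(non_mgw)
  list(core_fraction = sum(tab$region == "core") / n,
       flank_fraction = sum(tab$region == "flank") / n,
       intra_fraction = if (n_nm > 0L) sum(tab$shape_class == "intra") / n_nm
                        else 0,
       inter_fraction = if (n_nm > 0L) sum(tab$shape_class == "inter") / n_nm
                        else 0,
       mgw_fraction = sum(tab$shape_class == "MGW") / n,
       table = tab)
}

#' Write an importance report as delimited text
#'
#' @param report An \code{importance_report}.
#' @param path Output path.
#' @export
write_importance <- function(report, path) {
  utils::write.table(report$ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
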