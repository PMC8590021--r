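#' Save a trained predictor as a self-describing JSON archive
#'
#' Writes the extracted tree arrays together with the chosen
#' hyperparameters, feature names, label range and seed. The archive is
#' plain text and re-loadable with \code{\link{load_predictor}}; loaded
#' models predict through the package's own tree walker and reproduce the
#' original predictions exactly.
#'
#' @param model A \code{shape_rf}.
#' @param path Output path (JSON).
#' @export
save_predictor <- function(model, path) {
  stopifnot(inherits(model, "shape_rf"))
  obj <- list(
    format = "shapetf_predictor",
    version = 1L,
    chosen_params = model$chosen_params,
    feature_names = model$feature_names,
    label_range = model$label_range,
    motif_length = model$motif_length,
    b = model$b,
    seed = model$seed,
    trees = model$trees$trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a predictor archive
#'
#' @param path Archive written by \code{\link{save_predictor}}.
#' @return Object of class \code{shape_rf_loaded}; supports
#'   \code{predict()} and \code{\link{tree_shap}}.
#' @export
load_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "shapetf_predictor")) {
    stop(path, " is not a shapetf predictor archive")
  }
  trees <- lapply(obj$trees, function(tr) {
    list(left = as.integer(tr$left), right = as.integer(tr$right),
         feature = as.integer(tr$feature),
         split = as.numeric(tr$split), value = as.numeric(tr$value))
  })
  structure(
    list(trees = structure(list(trees = trees), class = "tree_ensemble"),
         chosen_params = obj$chosen_params,
         feature_names = obj$feature_names,
         label_range = as.numeric(obj$label_range),
         motif_length = obj$motif_length, b = obj$b, seed = obj$seed),
    class = c("shape_rf_loaded"))
}

#' @export
predict.shape_rf_loaded <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  nm <- colnames(newdata)
  if (is.null(nm) || !identical(nm, object$feature_names)) {
    stop("feature name mismatch with the loaded predictor")
  }
  predict_ensemble(object$trees, newdata)
}
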