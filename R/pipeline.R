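#' Assemble a labeled, weighted, balanced, split training dataset
#'
#' Runs the full pre-processing chain on motif hits and ampDAP-seq peaks:
#' FRiP filter, artifact filter, 80-bp summit labeling, homodimer
#' classification, organelle exclusion, shape featurization (strand
#' canonicalized, \code{b_max} flank bases pre-computed so narrower borders
#' can be selected later without re-extraction), ratio balancing, 0-1000
#' label normalization, sample weights and a stratified 80/20 split.
#'
#' @param hits Motif hits from \code{\link{scan_genome}}.
#' @param manifest A \code{\link{dataset_manifest}}; peak files are read
#'   from its paths.
#' @param genome Named character vector of contigs (or \code{DNAStringSet}).
#' @param shape_table A \code{\link{read_shape_table}} result.
#' @param b_max Widest flank (bases) to pre-compute shape features for
#'   (default 32).
#' @param radius Summit labeling radius (default 80).
#' @param validation_fraction Held-out fraction (default 0.2).
#' @param seed Integer seed controlling subsampling and the split.
#' @param organelle_names Contigs excluded from training.
#' @return Object of class \code{tf_dataset}: list with \code{sites} (data
#'   frame: hit fields, \code{bound}, \code{signal}, \code{label},
#'   \code{weight}), \code{features} (matrix, \code{13 * (m + 2 b_max)}
#'   columns), \code{motif_length}, \code{b_max}, \code{homodimer_mode},
#'   \code{split} and \code{provenance}.
#' @export
build_training_dataset <- function(hits, manifest, genome, shape_table,
                                   b_max = 32L, radius = 80L,
                                   validation_fraction = 0.2, seed = 1L,
                                   organelle_names = c("ChrC", "ChrM",
                                                       "chloroplast",
                                                       "mitochondria")) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  m <- attr(hits, "motif_length")
  if (is.null(m)) m <- hits$end[1L] - hits$start[1L]

  manifest <- filter_frip(manifest)
  peak_sets <- lapply(manifest$entries$path, read_narrowpeak)
  names(peak_sets) <- manifest$entries$dataset_id
  target_peaks <- peak_sets[[manifest$target]]
  n_raw_peaks <- nrow(target_peaks)
  target_peaks <- filter_artifacts(target_peaks, peak_sets)

  hits <- label_hits(hits, target_peaks, radius)
  hd <- detect_homodimer(hits, target_peaks, radius)
  hits <- exclude_organelles(hd$hits, organelle_names)

  windows <- canonical_window(hits, genome, b_max)
  feats <- featurize_windows(windows, shape_table, m, b_max)
  ok <- stats::complete.cases(feats)
  hits <- hits[ok, , drop = FALSE]
  feats <- feats[ok, , drop = FALSE]

  rownames(hits) <- NULL
  keep <- balance_ratio(hits, seed = seed)
  idx <- as.integer(rownames(keep))
  sites <- keep
  feats <- feats[idx, , drop = FALSE]
  rownames(sites) <- NULL

  sites <- normalize_signal(sites)
  sites <- compute_sample_weights(sites)
  split <- split_dataset(sites, validation_fraction = validation_fraction,
                         seed = seed + 1L)

  structure(
    list(sites = sites, features = feats, motif_length = m, b_max = b_max,
         homodimer_mode = hd$homodimer_mode, split = split,
         provenance = list(
           target = manifest$target,
           datasets = manifest$entries$dataset_id,
           n_raw_target_peaks = n_raw_peaks,
           n_peaks_after_artifact_filter = nrow(target_peaks),
           radius = radius, seed = seed)),
    class = "tf_dataset")
}

#' Construct a \code{tf_dataset} from pre-computed parts
#'
#' Used by simulations and tests that assemble sites and features directly.
#'
#' @param sites Site data frame with \code{bound}, \code{label},
#'   \code{weight} columns.
#' @param features Feature matrix with one row per site.
#' @param motif_length Core motif length.
#' @param b_max Flank width the features were computed at.
#' @param split Optional split list; made with \code{\link{split_dataset}}
#'   (seed 1) when missing.
#' @param homodimer_mode Logical.
#' @return A \code{tf_dataset}.
#' @export
tf_dataset <- function(sites, features, motif_length, b_max,
                       split = NULL, homodimer_mode = FALSE) {
  stopifnot(nrow(sites) == nrow(features))
  if (is.null(split)) split <- split_dataset(sites, seed = 1L)
  structure(list(sites = sites, features = features,
                 motif_length = motif_length, b_max = b_max,
                 homodimer_mode = homodimer_mode, split = split,
                 provenance = list()),
            class = "tf_dataset")
}

#' @export
print.tf_dataset <- function(x, ...) {
  cat("TF training dataset:", nrow(x$sites), "sites (",
      sum(x$sites$bound), "bound ),", ncol(x$features),
      "shape features, motif length", x$motif_length, "\n")
  cat("homodimer mode:", x$homodimer_mode,
      "| train/validation:", length(x$split$train), "/",
      length(x$split$validation), "\n")
  invisible(x)
}

#' Select the feature columns for a narrower border
#'
#' The dataset stores shape features for flanks up to \code{b_max}; this
#' returns the column subset corresponding to flank width \code{b}.
#'
#' @param dataset A \code{tf_dataset}.
#' @param b Flank width, \code{0 <= b <= b_max}.
#' @return Feature matrix restricted to positions \code{-b ... +b}.
#' @export
select_border <- function(dataset, b) {
  stopifnot(inherits(dataset, "tf_dataset"))
  if (b > dataset$b_max) {
    stop("border ", b, " exceeds the pre-computed maximum ", dataset$b_max)
  }
  want <- feature_vector_names(dataset$motif_length, b)
  dataset$features[, want, drop = FALSE]
}

#' Serialize a dataset to delimited text
#'
#' One row per site: hit fields, bound flag, label, weight, then the shape
#' feature columns. A small JSON sidecar with the provenance is written next
#' to it.
#'
#' @param dataset A \code{tf_dataset}.
#' @param path Output path (tab-delimited).
#' @export
write_dataset <- function(dataset, path) {
  df <- cbind(dataset$sites,
              as.data.frame(dataset$features, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(motif_length = dataset$motif_length, b_max = dataset$b_max,
               homodimer_mode = dataset$homodimer_mode,
               split = dataset$split, provenance = dataset$provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
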