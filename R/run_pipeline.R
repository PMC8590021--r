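#' Run the complete modelling pipeline on study inputs
#'
#' Convenience wrapper tying the modules together: scan the genome with the
#' motif, build the labeled/balanced/split dataset, train the random forest
#' at border \code{b}, evaluate against the motif-only baseline on the
#' validation split, and rank shape features by Shapley importance.
#'
#' @param genome Named character vector of contigs, or a FASTA path.
#' @param motif A \code{pwm}, or a MEME minimal format path.
#' @param manifest A \code{\link{dataset_manifest}}, or a manifest TSV path
#'   (then \code{target} must be supplied).
#' @param shape_table A \code{shape_table}, or a query-table path.
#' @param target Target dataset id (when \code{manifest} is a path).
#' @param b Flank width for training (default 4).
#' @param b_max Widest pre-computed flank (default 32).
#' @param space A \code{\link{hyper_space}}.
#' @param pthresh Motif scan p-value threshold (default 5e-4).
#' @param n_importance_samples Bound-site sample size for the Shapley
#'   importance summary (default 100).
#' @param n_background Background sample size for Shapley values
#'   (default 100).
#' @param seed Integer seed for every stochastic step.
#' @return List with \code{hits}, \code{dataset}, \code{model},
#'   \code{evaluation} (model and baseline \code{pr_curve}s) and
#'   \code{importance}.
#' @export
run_pipeline <- function(genome, motif, manifest, shape_table,
                         target = NULL, b = 4L, b_max = 32L,
                         space = hyper_space(), pthresh = 5e-4,
                         n_importance_samples = 100L,
                         n_background = 100L, seed = 1L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  if (is.character(motif)) motif <- read_meme_motif(motif)
  if (is.character(manifest)) {
    if (is.null(target)) stop("target dataset id required with a manifest path")
    manifest <- read_manifest(manifest, target)
  }
  if (is.character(shape_table)) shape_table <- read_shape_table(shape_table)

  hits <- scan_genome(genome, motif, pthresh = pthresh)
  dataset <- build_training_dataset(hits, manifest, genome, shape_table,
                                    b_max = b_max, seed = seed)
  model <- train(dataset, space, b = b, seed = seed)
  evaluation <- evaluate_model(model, dataset)
  importance <- pipeline_importance(model, dataset,
                                    n_samples = n_importance_samples,
                                    n_background = n_background,
                                    seed = seed)
  list(hits = hits, dataset = dataset, model = model,
       evaluation = evaluation, importance = importance)
}

#' Shapley importance summary for a trained pipeline model
#'
#' Attributes predictions for a seeded sample of training sites (bound and
#' unbound, so the attribution sees the contrast the model exploits)
#' against a seeded background of training sites.
#'
#' @param model A \code{shape_rf}.
#' @param dataset The \code{tf_dataset} it was trained on.
#' @param n_samples Number of training sites to attribute (default 100).
#' @param n_background Background size (default 100).
#' @param k Top-list size (default 5).
#' @param seed Integer seed for the two subsamples.
#' @return An \code{importance_report}.
#' @export
pipeline_importance <- function(model, dataset, n_samples = 100L,
                                n_background = 100L, k = 5L, seed = 1L) {
  x <- select_border(dataset, model$b)
  tr <- dataset$split$train
  with_seed(seed + 7L, {
    si <- if (length(tr) > n_samples) sample(tr, n_samples) else tr
    bi <- if (length(tr) > n_background) sample(tr, n_background) else tr
    global_importance(model, x[si, , drop = FALSE],
                      x[bi, , drop = FALSE], k = k)
  })
}
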