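#' Generate random motif-containing candidate sequences absent from a genome
#'
#' Creates \code{n} unique random sequences of the given length, each
#' carrying the core motif at the centered offset
#' (\code{floor((length - nchar(core)) / 2)}, 0-based), none of which occurs
#' as a substring of any genome contig on either strand.
#'
#' @param genome Named character vector of contigs (or \code{DNAStringSet}).
#' @param core Core motif sequence (default \code{"ACGT"}).
#' @param n Number of candidates (default 100000).
#' @param length Candidate length (default 18).
#' @param seed Integer seed.
#' @param max_rounds Regeneration rounds before giving up.
#' @return Character vector of \code{n} sequences. Attribute
#'   \code{core_offset} carries the 0-based core position.
#' @export
generate_candidates <- function(genome, core = "ACGT", n = 100000L,
                                length = 18L, seed = 1L,
                                max_rounds = 50L) {
  if (!grepl("^[ACGT]+$", core)) stop("core must be over A, C, G, T")
  m <- nchar(core)
  if (length < m) stop("candidate length shorter than the core")
  genome <- as_genome_charvec(genome)
  offset <- (length - m) %/% 2L

  subjects <- lapply(genome, Biostrings::DNAString)
  in_genome <- function(x) {
    if (base::length(x) == 0L) return(logical(0L))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(x))
    counts <- integer(base::length(x))
    for (subj in subjects) {
      if (base::length(subj) < length) next
      counts <- counts + Biostrings::countPDict(pd, subj) +
        Biostrings::countPDict(pd, Biostrings::reverseComplement(subj))
    }
    counts > 0L
  }

  bases <- c("A", "C", "G", "T")
  n_flank <- length - m
  out <- character(0L)
  with_seed(seed, {
    for (round in seq_len(max_rounds)) {
      need <- n - base::length(out)
      if (need <= 0L) break
      draw <- ceiling(need * 1.2)
      flanks <- matrix(sample(bases, draw * n_flank, replace = TRUE),
                       nrow = draw)
      left <- if (offset > 0L) {
        apply(flanks[, seq_len(offset), drop = FALSE], 1L, paste,
              collapse = "")
      } else rep("", draw)
      right <- if (n_flank > offset) {
        apply(flanks[, (offset + 1L):n_flank, drop = FALSE], 1L, paste,
              collapse = "")
      } else rep("", draw)
      cand <- paste0(left, core, right)
      cand <- setdiff(unique(cand), out)
      cand <- cand[!in_genome(cand)]
      out <- c(out, cand)
    }
  })
  if (base::length(out) < n) {
    stop("could only generate ", base::length(out), " of ", n,
         " unique genome-absent candidates")
  }
  out <- out[seq_len(n)]
  attr(out, "core_offset") <- offset
  out
}

#' Shape-featurize designed candidates
#'
#' Candidates provide their own flanking bases as pentamer context, so the
#' candidate length must be at least
#' \code{nchar(core) + 2 * (b + 2)}; the featurized window is centered on
#' the core.
#'
#' @param candidates Character vector from
#'   \code{\link{generate_candidates}}.
#' @param core Core motif sequence.
#' @param b Flank width of the model the features are for.
#' @param table A \code{shape_table}.
#' @return Feature matrix, one row per candidate, columns
#'   \code{13 * (nchar(core) + 2 b)}.
#' @export
featurize_candidates <- function(candidates, core, b, table) {
  m <- nchar(core)
  len <- unique(nchar(candidates))
  if (length(len) != 1L) stop("candidates must all have the same length")
  need <- m + 2L * (b + PENTAMER_CONTEXT)
  if (len < need) {
    stop("candidates of length ", len, " are too short for border ", b,
         " (need ", need, ")")
  }
  offset <- attr(candidates, "core_offset")
  if (is.null(offset)) offset <- (len - m) %/% 2L
  if (any(substr(candidates, offset + 1L, offset + m) != core)) {
    stop("candidate(s) lack the core at the expected offset")
  }
  wstart <- offset + 1L - (b + PENTAMER_CONTEXT)
  if (wstart < 1L || offset + m + b + PENTAMER_CONTEXT > len) {
    stop("core is too close to the candidate edge for border ", b)
  }
  windows <- substr(candidates, wstart, wstart + need - 1L)
  featurize_windows(windows, table, m, b)
}

#' Select predicted high- and low-affinity designed sequences
#'
#' Predicts affinity for every candidate and returns the \code{per_class}
#' most extreme sequences above \code{high} and below \code{low} (in label
#' units, 0-1000). A warning is raised when fewer candidates qualify.
#'
#' @param model A \code{shape_rf}.
#' @param candidates From \code{\link{generate_candidates}}.
#' @param table A \code{shape_table}.
#' @param core Core motif (defaults to the consensus implied by the model's
#'   motif length being \code{nchar(core)}; must be supplied).
#' @param high High-affinity threshold (default 150).
#' @param low Low-affinity threshold (default 15).
#' @param per_class Sequences returned per class (default 3).
#' @return List with \code{high} and \code{low} data frames
#'   (\code{sequence}, \code{prediction}; ordered most extreme first) and
#'   \code{predictions} for all candidates.
#' @export
select_extremes <- function(model, candidates, table, core,
                            high = 150, low = 15, per_class = 3L) {
  stopifnot(inherits(model, "shape_rf"), low < high)
  feats <- featurize_candidates(candidates, core, model$b, table)
  pred <- predict(model, feats)
  all_pred <- data.frame(sequence = as.character(candidates),
                         prediction = pred, stringsAsFactors = FALSE)
  hi <- all_pred[all_pred$prediction > high, , drop = FALSE]
  hi <- hi[order(-hi$prediction), , drop = FALSE]
  lo <- all_pred[all_pred$prediction < low, , drop = FALSE]
  lo <- lo[order(lo$prediction), , drop = FALSE]
  if (nrow(hi) < per_class) {
    warning("only ", nrow(hi), " candidate(s) predicted above ", high)
  }
  if (nrow(lo) < per_class) {
    warning("only ", nrow(lo), " candidate(s) predicted below ", low)
  }
  list(high = utils::head(hi, per_class),
       low = utils::head(lo, per_class),
       predictions = all_pred)
}

#' Write designed sequences as FASTA plus a prediction table
#'
#' @param selection Result of \code{\link{select_extremes}}.
#' @param fasta_path FASTA of the selected high/low sequences.
#' @param table_path Tab-delimited table of all predictions.
#' @export
write_design <- function(selection, fasta_path, table_path) {
  tag <- function(df, cls) {
    if (nrow(df) == 0L) return(NULL)
    cbind(df, class = cls)
  }
  sel <- rbind(tag(selection$high, "high"), tag(selection$low, "low"))
  if (is.null(sel)) {
    sel <- data.frame(sequence = character(), prediction = numeric(),
                      class = character())
  }
  seqs <- Biostrings::DNAStringSet(sel$sequence)
  names(seqs) <- if (nrow(sel) > 0L) {
    sprintf("%s_%d_pred%.1f", sel$class, seq_len(nrow(sel)),
            sel$prediction)
  } else character()
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(selection$predictions, table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
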