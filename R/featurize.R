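#' Reverse complement DNA strings
#'
#' Watson-Crick reverse complement of one or more sequences over
#' \code{A, C, G, T, N}.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("seq must be a character vector")
  if (any(!grepl("^[ACGTN]*$", seq))) {
    stop("sequences must contain only A, C, G, T, N")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Position labels for a motif window
#'
#' Core positions are numbered \code{1...m}; upstream flank positions are
#' \code{-b...-1} and downstream flank positions \code{+1...+b}. Position 0
#' is never used.
#'
#' @param motif_length Core motif length m.
#' @param b Flank width on each side (bases).
#' @return Character vector of length \code{motif_length + 2 * b}.
#' @export
position_labels <- function(motif_length, b) {
  stopifnot(motif_length >= 1L, b >= 0L)
  c(if (b > 0L) as.character(seq(-b, -1L)),
    as.character(seq_len(motif_length)),
    if (b > 0L) paste0("+", seq_len(b)))
}

#' Names of a flattened shape feature vector
#'
#' Position-major: the 13 features (fixed order) at position -b, then at
#' -b+1, and so on through +b. Names have the form \code{"feature@position"},
#' e.g. \code{"roll@-1"} or \code{"helix_twist@5"}.
#'
#' @inheritParams position_labels
#' @return Character vector of length \code{13 * (motif_length + 2 * b)}.
#' @export
feature_vector_names <- function(motif_length, b) {
  pos <- position_labels(motif_length, b)
  as.vector(vapply(pos, function(p) paste0(SHAPE_FEATURES, "@", p),
                   character(length(SHAPE_FEATURES))))
}

#' Extract strand-canonical sequence windows around motif hits
#'
#' For each hit the genomic substring covering the motif plus
#' \code{b + context} bases on each side is extracted; minus-strand hits are
#' reverse complemented so the window always reads in the motif's plus
#' orientation. Hits whose window would cross a contig end are
#' un-featurizable and returned as \code{NA} (callers discard them; no
#' padding is applied).
#'
#' @param hits Data frame with columns \code{contig}, \code{start},
#'   \code{end} (0-based, half-open) and \code{strand}.
#' @param genome Named character vector of contig sequences (or a
#'   \code{DNAStringSet}).
#' @param b Flank width in bases.
#' @param context Pentamer context consumed at each end (fixed at 2).
#' @return Character vector of windows of length
#'   \code{(end - start) + 2 * (b + context)}, \code{NA} where
#'   un-featurizable.
#' @export
canonical_window <- function(hits, genome, b, context = PENTAMER_CONTEXT) {
  genome <- as_genome_charvec(genome)
  stopifnot(b >= 0L)
  unknown <- setdiff(unique(hits$contig), names(genome))
  if (length(unknown) > 0L) {
    stop("hit(s) on unknown contig(s): ", paste(unknown, collapse = ", "))
  }
  pad <- b + context
  clen <- nchar(genome)[match(hits$contig, names(genome))]
  ws <- hits$start - pad            # 0-based window start
  we <- hits$end + pad              # 0-based window end (exclusive)
  ok <- ws >= 0L & we <= clen
  out <- rep(NA_character_, nrow(hits))
  if (any(ok)) {
    out[ok] <- substr(genome[match(hits$contig[ok], names(genome))],
                      ws[ok] + 1L, we[ok])
    minus <- ok & hits$strand == "-"
    if (any(minus)) out[minus] <- reverse_complement(out[minus])
  }
  out
}

#' Translate a sequence window into per-position shape features
#'
#' Each position with full pentamer context (i.e. all but the two outermost
#' bases on each side) is assigned the 13 query-table values of the pentamer
#' centered on it, in 5' to 3' order.
#'
#' @param window DNA string of length >= 5 over A, C, G, T.
#' @param table A \code{\link{read_shape_table}} result.
#' @return Object of class \code{shape_profile}: list with \code{values}
#'   ((len - 4) x 13 matrix), \code{positions} (integer offsets within the
#'   window) and \code{source_window}.
#' @export
featurize <- function(window, table) {
  stopifnot(inherits(table, "shape_table"), length(window) == 1L)
  n <- nchar(window)
  if (n < 5L) stop("window must be at least 5 bases long")
  if (!grepl("^[ACGT]+$", window)) {
    stop("window contains ambiguous bases; hit is un-featurizable")
  }
  centers <- seq.int(PENTAMER_CONTEXT + 1L, n - PENTAMER_CONTEXT)
  pents <- substring(window, centers - 2L, centers + 2L)
  vals <- shape_lookup(table, pents)
  rownames(vals) <- NULL
  structure(list(values = vals, positions = centers,
                 source_window = window),
            class = "shape_profile")
}

#' Flatten a shape profile into a named feature vector
#'
#' @param profile A \code{shape_profile} with exactly
#'   \code{motif_length + 2 * b} positions.
#' @param motif_length Core motif length.
#' @param b Flank width used when the window was extracted.
#' @return Named numeric vector of length \code{13 * (motif_length + 2 * b)};
#'   names as in \code{\link{feature_vector_names}}.
#' @export
flatten <- function(profile, motif_length, b) {
  stopifnot(inherits(profile, "shape_profile"))
  n_pos <- nrow(profile$values)
  if (n_pos != motif_length + 2L * b) {
    stop("profile has ", n_pos, " positions but motif_length + 2b = ",
         motif_length + 2L * b)
  }
  v <- as.vector(t(profile$values))
  names(v) <- feature_vector_names(motif_length, b)
  v
}

#' Featurize many equal-length windows into a feature matrix
#'
#' Vectorized path used by the dataset builder: all windows must have length
#' \code{motif_length + 2 * (b + 2)}. Windows that are \code{NA} or contain
#' ambiguous bases yield all-\code{NA} rows (callers drop them).
#'
#' @param windows Character vector of windows (may contain \code{NA}).
#' @param table A \code{shape_table}.
#' @param motif_length Core motif length.
#' @param b Flank width.
#' @return Numeric matrix, one row per window, columns named as in
#'   \code{\link{feature_vector_names}}.
#' @export
featurize_windows <- function(windows, table, motif_length, b) {
  stopifnot(inherits(table, "shape_table"))
  want_len <- motif_length + 2L * (b + PENTAMER_CONTEXT)
  ok <- !is.na(windows) & grepl("^[ACGT]+$", windows)
  if (any(ok & nchar(windows) != want_len)) {
    stop("all windows must have length ", want_len)
  }
  n_pos <- motif_length + 2L * b
  nf <- length(SHAPE_FEATURES)
  out <- matrix(NA_real_, nrow = length(windows), ncol = nf * n_pos,
                dimnames = list(NULL, feature_vector_names(motif_length, b)))
  if (any(ok)) {
    w <- windows[ok]
    block <- matrix(NA_real_, nrow = length(w), ncol = nf * n_pos)
    for (i in seq_len(n_pos)) {
      pents <- substr(w, i, i + 4L)
      block[, ((i - 1L) * nf + 1L):(i * nf)] <- shape_lookup(table, pents)
    }
    out[ok, ] <- block
  }
  out
}

# Accept a DNAStringSet or a named character vector.
as_genome_charvec <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (!is.character(genome) || is.null(names(genome))) {
    stop("genome must be a named character vector or DNAStringSet")
  }
  toupper(genome)
}

#' Read a multi-contig genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of contig sequences; names are the first
#'   whitespace-delimited token of each FASTA header.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
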