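#' Log-odds score of a k-mer under a PWM
#'
#' Sum over positions of \code{log2(p_i(base) / background(base))}, in bits.
#'
#' @param pwm A \code{pwm}.
#' @param kmer DNA string of the motif's length over A, C, G, T.
#' @return Numeric scalar.
#' @export
log_odds_score <- function(pwm, kmer) {
  stopifnot(inherits(pwm, "pwm"))
  m <- nrow(pwm$probs)
  if (nchar(kmer) != m) {
    stop("kmer length ", nchar(kmer), " does not match motif length ", m)
  }
  if (!grepl("^[ACGT]+$", kmer)) stop("kmer contains ambiguous bases")
  lod <- pwm_log_odds(pwm)
  idx <- match(strsplit(kmer, "")[[1L]], c("A", "C", "G", "T"))
  sum(lod[cbind(seq_len(m), idx)])
}

# m x 4 log2 odds matrix
pwm_log_odds <- function(pwm) {
  log2(sweep(pwm$probs, 2L, pwm$background, `/`))
}

# Discretized score distribution under the background: integer score matrix
# (granularity = grid step in bits), probability over attainable integer
# sums, and its upper tail. The same grid is used both for the null
# distribution and for scoring genomic windows, so reported p-values are
# exact on the grid.
pwm_score_distribution <- function(pwm, granularity = 1e-3) {
  lod <- pwm_log_odds(pwm)
  I <- round(lod / granularity)
  # zero-probability cells (-Inf log-odds) are floored 100 bits below the
  # lowest finite cell: windows using them can never reach a reportable
  # score, so tail probabilities at finite scores are unchanged
  if (any(!is.finite(I))) {
    I[!is.finite(I)] <- min(I[is.finite(I)]) - ceiling(100 / granularity)
  }
  storage.mode(I) <- "integer"
  m <- nrow(I)
  min_int <- sum(apply(I, 1L, min))
  max_int <- sum(apply(I, 1L, max))
  width <- max_int - min_int + 1L
  # dist[k] = P(sum of first j rows == min_so_far + k - 1)
  dist <- 1
  min_so_far <- 0L
  for (j in seq_len(m)) {
    row <- I[j, ]
    rmin <- min(row)
    new_len <- length(dist) + max(row) - rmin
    new <- numeric(new_len)
    for (b in 1:4) {
      off <- row[b] - rmin
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + dist * pwm$background[b]
    }
    dist <- new
    min_so_far <- min_so_far + rmin
  }
  stopifnot(length(dist) == width)
  tail <- rev(cumsum(rev(dist)))
  list(int_scores = I, granularity = granularity,
       min_int = min_int, max_int = max_int, prob = dist, tail = tail)
}

#' Exact p-value of a PWM score
#'
#' Probability that a random background-distributed m-mer scores at least
#' \code{score}, computed by dynamic programming over a discretized score
#' grid (default step 0.001 bits). The p-value at the minimum attainable
#' score is 1.
#'
#' @param pwm A \code{pwm}.
#' @param score Log-odds score in bits.
#' @param granularity Grid step in bits.
#' @return Numeric p-value in \code{[0, 1]}.
#' @export
score_pvalue <- function(pwm, score, granularity = 1e-3) {
  stopifnot(is.finite(score))
  dp <- pwm_score_distribution(pwm, granularity)
  s_int <- round(score / granularity)
  if (s_int <= dp$min_int) return(1)
  if (s_int > dp$max_int) return(0)
  dp$tail[[s_int - dp$min_int + 1L]]
}

#' Scan a genome with a PWM at a p-value threshold
#'
#' Scores every window on both strands and reports the positions whose
#' p-value is at most \code{pthresh}. When plus- and minus-strand hits
#' occupy the same interval (palindromic matches) only the better-scoring
#' one is kept, ties going to the plus strand, so a palindrome is counted
#' once per locus. Windows containing ambiguous bases are skipped.
#'
#' Scores are reported on the discretization grid (step \code{granularity}
#' bits); p-values are exact for the gridded scores.
#'
#' @param genome Named character vector of contigs (or \code{DNAStringSet}).
#' @param pwm A \code{pwm}.
#' @param pthresh P-value threshold (default 5e-4, the usual motif-scan
#'   cut-off).
#' @param max_per_locus Maximum hits reported per locus (only 1 is
#'   supported: one strand per interval).
#' @param granularity Score grid step in bits.
#' @return Data frame of hits with columns \code{contig}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}, \code{score} (bits),
#'   \code{pvalue}, \code{matched_seq} (plus orientation of the motif),
#'   sorted by contig then start. Attribute \code{motif_length} carries m.
#' @export
scan_genome <- function(genome, pwm, pthresh = 5e-4, max_per_locus = 1L,
                        granularity = 1e-3) {
  stopifnot(inherits(pwm, "pwm"))
  if (max_per_locus != 1L) stop("only max_per_locus = 1 is supported")
  genome <- as_genome_charvec(genome)
  if (length(genome) == 0L) stop("genome is empty")
  m <- nrow(pwm$probs)
  dp <- pwm_score_distribution(pwm, granularity)

  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), pvalue = numeric(),
                      matched_seq = character(), stringsAsFactors = FALSE)
  attr(empty, "motif_length") <- m

  # smallest integer score whose tail probability passes the threshold
  pass <- which(dp$tail <= pthresh)
  if (length(pass) == 0L) return(empty)
  t_int <- dp$min_int + pass[1L] - 1L

  Iplus <- dp$int_scores
  Iminus <- Iplus[m:1, 4:1, drop = FALSE]  # reverse complement orientation

  base_map <- rep(NA_integer_, 128L)
  base_map[utf8ToInt("A")] <- 1L
  base_map[utf8ToInt("C")] <- 2L
  base_map[utf8ToInt("G")] <- 3L
  base_map[utf8ToInt("T")] <- 4L

  res <- list()
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    L <- nchar(s)
    if (L < m) next
    codes <- base_map[utf8ToInt(s)]
    n_win <- L - m + 1L
    sp <- numeric(n_win)
    sm <- numeric(n_win)
    for (j in seq_len(m)) {
      cj <- codes[j:(j + n_win - 1L)]
      sp <- sp + Iplus[j, ][cj]
      sm <- sm + Iminus[j, ][cj]
    }
    hp <- which(!is.na(sp) & sp >= t_int)
    hm <- which(!is.na(sm) & sm >= t_int)
    # same-interval collision: keep the better score, ties to plus
    both <- intersect(hp, hm)
    if (length(both) > 0L) {
      drop_minus <- both[sp[both] >= sm[both]]
      drop_plus <- both[sp[both] < sm[both]]
      hm <- setdiff(hm, drop_minus)
      hp <- setdiff(hp, drop_plus)
    }
    if (length(hp) + length(hm) == 0L) next
    starts <- c(hp, hm) - 1L  # to 0-based
    strands <- rep(c("+", "-"), c(length(hp), length(hm)))
    ints <- c(sp[hp], sm[hm])
    seqs <- substring(s, starts + 1L, starts + m)
    if (any(strands == "-")) {
      seqs[strands == "-"] <- reverse_complement(seqs[strands == "-"])
    }
    res[[ctg]] <- data.frame(
      contig = ctg, start = as.integer(starts),
      end = as.integer(starts + m), strand = strands,
      score = ints * granularity,
      pvalue = dp$tail[ints - dp$min_int + 1L],
      matched_seq = seqs, stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(empty)
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$contig, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "motif_length") <- m
  hits
}

#' Write motif hits to disk
#'
#' @param hits Hit data frame from \code{\link{scan_genome}}.
#' @param path Output path.
#' @param format \code{"tsv"} writes a FIMO-style tab-delimited table
#'   (1-based inclusive coordinates); \code{"bed"} writes BED6 plus score
#'   and p-value columns (0-based half-open).
#' @param motif_id Motif identifier for the tsv format.
#' @export
write_motif_hits <- function(hits, path, format = c("tsv", "bed"),
                             motif_id = "motif") {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- data.frame(
      motif_id = motif_id, motif_alt_id = "",
      sequence_name = hits$contig,
      start = hits$start + 1L, stop = hits$end,
      strand = hits$strand, score = hits$score,
      `p-value` = hits$pvalue, `q-value` = "",
      matched_sequence = hits$matched_seq,
      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    out <- data.frame(hits$contig, hits$start, hits$end,
                      paste0("hit", seq_len(nrow(hits))),
                      hits$score, hits$strand, hits$pvalue)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
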