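#' Build a dataset manifest
#'
#' @param entries Data frame with columns \code{dataset_id}, \code{path}
#'   (narrowPeak file) and \code{frip} (fraction of reads in peaks, in
#'   [0, 1]).
#' @param target Dataset id of the transcription factor being modelled; must
#'   be one of the entries.
#' @return Object of class \code{dataset_manifest}.
#' @export
dataset_manifest <- function(entries, target) {
  stopifnot(is.data.frame(entries),
            all(c("dataset_id", "path", "frip") %in% names(entries)))
  if (any(entries$frip < 0 | entries$frip > 1)) {
    stop("FRiP values must lie in [0, 1]")
  }
  if (!target %in% entries$dataset_id) {
    stop("target dataset '", target, "' is not in the manifest")
  }
  structure(list(entries = entries, target = target),
            class = "dataset_manifest")
}

#' Read a manifest from delimited text
#'
#' Tab- or comma-delimited, header \code{dataset_id}, \code{path},
#' \code{frip}. Relative peak paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest file.
#' @param target Target dataset id.
#' @return A \code{dataset_manifest}.
#' @export
read_manifest <- function(path, target) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  rel <- !grepl("^/", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  dataset_manifest(df, target)
}

#' Drop low-quality datasets by FRiP
#'
#' Only datasets with a fraction of reads in peaks strictly above
#' \code{min_frip} are retained.
#'
#' @param manifest A \code{dataset_manifest}.
#' @param min_frip Threshold (default 0.05, i.e. 5\%).
#' @return Filtered \code{dataset_manifest}.
#' @export
filter_frip <- function(manifest, min_frip = 0.05) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  keep <- manifest$entries$frip > min_frip
  dropped <- manifest$entries$dataset_id[!keep]
  if (manifest$target %in% dropped) {
    stop("target dataset '", manifest$target, "' has FRiP <= ", min_frip,
         "; cannot proceed")
  }
  dataset_manifest(manifest$entries[keep, , drop = FALSE], manifest$target)
}

#' Remove artifact peaks recurring across datasets
#'
#' A target peak is considered an experimental artifact and discarded when
#' it occurs in more than \code{max_fraction} of all datasets (including the
#' target itself). Two peaks in different datasets count as the same peak
#' when their summits lie within \code{max_summit_dist} bases on the same
#' contig. With fewer than 3 datasets the filter is skipped with a warning
#' (every peak would trivially exceed the fraction).
#'
#' @param target_peaks Peak data frame of the target dataset.
#' @param all_peak_sets Named list of peak data frames, one per dataset in
#'   the manifest (the target included).
#' @param max_fraction Occurrence fraction above which a peak is discarded
#'   (default 1/3).
#' @param max_summit_dist Summit-to-summit distance defining peak identity
#'   across datasets (default 100 bp, half the peak width).
#' @return Filtered peak data frame.
#' @export
filter_artifacts <- function(target_peaks, all_peak_sets,
                             max_fraction = 1 / 3, max_summit_dist = 100L) {
  n_ds <- length(all_peak_sets)
  if (n_ds < 3L) {
    warning("artifact filter skipped: only ", n_ds, " dataset(s)")
    return(target_peaks)
  }
  counts <- integer(nrow(target_peaks))
  for (ds in all_peak_sets) {
    hit <- logical(nrow(target_peaks))
    for (ctg in unique(target_peaks$contig)) {
      ti <- which(target_peaks$contig == ctg)
      ds_summits <- sort(ds$summit[ds$contig == ctg])
      if (length(ds_summits) == 0L) next
      # nearest dataset summit to each target summit
      pos <- findInterval(target_peaks$summit[ti], ds_summits)
      lo <- pmax(pos, 1L)
      hi <- pmin(pos + 1L, length(ds_summits))
      near <- pmin(abs(target_peaks$summit[ti] - ds_summits[lo]),
                   abs(target_peaks$summit[ti] - ds_summits[hi]))
      hit[ti] <- near <= max_summit_dist
    }
    counts <- counts + hit
  }
  keep <- counts / n_ds <= max_fraction
  target_peaks[keep, , drop = FALSE]
}

#' Label motif hits with peak-derived binding evidence
#'
#' A hit is an experimentally validated binding event (\code{bound}) when
#' the distance from a peak summit to the nearest base of the motif interval
#' is at most \code{radius} bases. Bound hits carry the signal of the
#' assigned peak; a hit within radius of several summits takes the peak with
#' the highest signal.
#'
#' @param hits Hit data frame (\code{\link{scan_genome}}).
#' @param peaks Peak data frame (\code{\link{read_narrowpeak}}).
#' @param radius Distance threshold in bases (default 80).
#' @return \code{hits} with added columns \code{bound}, \code{signal}
#'   (\code{NA} when unbound) and \code{peak_id} (row index into
#'   \code{peaks}, \code{NA} when unbound).
#' @export
label_hits <- function(hits, peaks, radius = 80L) {
  hits$bound <- FALSE
  hits$signal <- NA_real_
  hits$peak_id <- NA_integer_
  if (nrow(peaks) == 0L || nrow(hits) == 0L) return(hits)
  for (ctg in unique(hits$contig)) {
    hi <- which(hits$contig == ctg)
    pi <- which(peaks$contig == ctg)
    if (length(pi) == 0L) next
    # summit within radius of the motif interval <=> summit point overlaps
    # the interval extended by radius on each side
    ext <- IRanges::IRanges(start = hits$start[hi] - radius,
                            end = hits$end[hi] - 1L + radius)
    summits <- IRanges::IRanges(start = peaks$summit[pi], width = 1L)
    ov <- IRanges::findOverlaps(ext, summits)
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    sig <- peaks$signal[pi[sh]]
    best <- tapply(seq_along(qh), qh, function(ii) ii[which.max(sig[ii])])
    best <- unlist(best, use.names = TRUE)
    rows <- hi[as.integer(names(best))]
    hits$bound[rows] <- TRUE
    hits$signal[rows] <- sig[best]
    hits$peak_id[rows] <- pi[sh[best]]
  }
  hits
}

#' Count in-radius motif occurrences per peak
#'
#' @inheritParams label_hits
#' @return Integer vector, one count per row of \code{peaks}.
#' @export
peak_hit_counts <- function(hits, peaks, radius = 80L) {
  counts <- integer(nrow(peaks))
  if (nrow(peaks) == 0L || nrow(hits) == 0L) return(counts)
  for (ctg in unique(peaks$contig)) {
    pi <- which(peaks$contig == ctg)
    hi <- which(hits$contig == ctg)
    if (length(hi) == 0L) next
    ext <- IRanges::IRanges(start = hits$start[hi] - radius,
                            end = hits$end[hi] - 1L + radius)
    summits <- IRanges::IRanges(start = peaks$summit[pi], width = 1L)
    counts[pi] <- IRanges::countOverlaps(summits, ext)
  }
  counts
}

#' Classify a TF as homodimeric and retain the matching binding events
#'
#' Counts peaks with at least two in-radius motif occurrences against peaks
#' with exactly one. If multi-occurrence peaks are the strict majority the
#' TF is treated as binding as a homodimer and bound hits from
#' single-occurrence peaks are dropped; otherwise (ties included) bound hits
#' from multi-occurrence peaks are dropped. Unbound genomic occurrences are
#' never dropped by this rule.
#'
#' @param labeled_hits Output of \code{\link{label_hits}}.
#' @param peaks The peak data frame the hits were labeled with.
#' @param radius Same radius as used for labeling.
#' @return List with \code{homodimer_mode} (logical) and \code{hits} (the
#'   filtered hit data frame).
#' @export
detect_homodimer <- function(labeled_hits, peaks, radius = 80L) {
  counts <- peak_hit_counts(labeled_hits, peaks, radius)
  multi <- sum(counts >= 2L)
  single <- sum(counts == 1L)
  homodimer <- multi > single
  drop_counts <- if (homodimer) 1L else 2L
  bad_peaks <- if (homodimer) which(counts == 1L) else which(counts >= 2L)
  drop <- labeled_hits$bound & labeled_hits$peak_id %in% bad_peaks
  list(homodimer_mode = homodimer,
       hits = labeled_hits[!drop, , drop = FALSE])
}

#' Remove hits on organellar contigs
#'
#' Chloroplast and mitochondrial sequences are not part of the in vitro
#' binding experiment, so motif occurrences on them are discarded.
#'
#' @param hits Hit data frame.
#' @param organelle_names Contig names to exclude.
#' @return Filtered hit data frame.
#' @export
exclude_organelles <- function(hits,
                               organelle_names = c("ChrC", "ChrM",
                                                   "chloroplast",
                                                   "mitochondria")) {
  hits[!hits$contig %in% organelle_names, , drop = FALSE]
}

#' Balance bound against unbound sites
#'
#' If the unbound-to-bound ratio exceeds \code{max_ratio} (1:5), unbound
#' sites are uniformly subsampled to exactly \code{max_ratio} times the
#' bound count. If the resulting total still exceeds \code{cap} (120,000)
#' sites, the ratio is forced further down to \code{fallback_ratio} (1:3).
#' Bound sites are never removed.
#'
#' @param sites Data frame with a logical \code{bound} column.
#' @param max_ratio Maximum unbound/bound ratio (default 5).
#' @param cap Maximum total sites tolerated at \code{max_ratio}
#'   (default 120000).
#' @param fallback_ratio Ratio enforced when the cap is exceeded
#'   (default 3).
#' @param seed Integer seed for the subsampling.
#' @return Subsampled data frame (original row order preserved).
#' @export
balance_ratio <- function(sites, max_ratio = 5, cap = 120000,
                          fallback_ratio = 3, seed = 1L) {
  n_bound <- sum(sites$bound)
  n_unbound <- sum(!sites$bound)
  if (n_bound == 0L) {
    stop("no bound sites; cannot train a binding model")
  }
  if (n_unbound <= max_ratio * n_bound) return(sites)
  ratio <- max_ratio
  if (n_bound + max_ratio * n_bound > cap) ratio <- fallback_ratio
  keep_n <- ratio * n_bound
  unbound_idx <- which(!sites$bound)
  keep <- sort(with_seed(seed, sample(unbound_idx, keep_n)))
  sites[sort(c(which(sites$bound), keep)), , drop = FALSE]
}

#' Normalize peak signal to the 0-1000 label range
#'
#' Min-max scales the signals of bound sites onto [0, 1000]; unbound sites
#' get label 0. If all bound signals are equal every bound label is 1000.
#'
#' @param sites Data frame with \code{bound} and \code{signal} columns.
#' @return \code{sites} with an added numeric \code{label} column.
#' @export
normalize_signal <- function(sites) {
  sites$label <- 0
  b <- sites$bound
  if (any(b)) {
    s <- sites$signal[b]
    rng <- range(s)
    if (diff(rng) == 0) {
      sites$label[b] <- 1000
    } else {
      sites$label[b] <- (s - rng[1L]) / diff(rng) * 1000
    }
  }
  sites
}

#' Compute sample weights against false-negative bias
#'
#' Bound sites are up-weighted by the unbound/bound ratio of the (balanced)
#' dataset; unbound sites get weight 1.
#'
#' @param sites Data frame with a \code{bound} column.
#' @return \code{sites} with an added \code{weight} column.
#' @export
compute_sample_weights <- function(sites) {
  n_bound <- sum(sites$bound)
  n_unbound <- sum(!sites$bound)
  w_bound <- if (n_bound > 0L && n_unbound > 0L) n_unbound / n_bound else 1
  sites$weight <- ifelse(sites$bound, w_bound, 1)
  sites
}

#' Stratified train/validation split
#'
#' Splits site indices into a training and a validation set, stratifying on
#' the bound flag so the validation set's per-stratum counts are within one
#' site of the exact proportion.
#'
#' @param n_sites Number of sites, or a data frame with a \code{bound}
#'   column.
#' @param bound Logical vector (ignored when \code{n_sites} is a data
#'   frame).
#' @param validation_fraction Fraction held out (default 0.2).
#' @param seed Integer seed.
#' @return List with integer index vectors \code{train} and
#'   \code{validation}.
#' @export
split_dataset <- function(n_sites, bound = NULL, validation_fraction = 0.2,
                          seed = 1L) {
  if (is.data.frame(n_sites)) {
    bound <- n_sites$bound
    n_sites <- nrow(n_sites)
  }
  stopifnot(length(bound) == n_sites)
  if (validation_fraction == 0) {
    warning("validation_fraction = 0: empty validation set")
    return(list(train = seq_len(n_sites), validation = integer()))
  }
  val <- with_seed(seed, {
    unlist(lapply(split(seq_len(n_sites), bound), function(idx) {
      k <- round(length(idx) * validation_fraction)
      if (k == 0L) integer() else sample(idx, k)
    }), use.names = FALSE)
  })
  list(train = setdiff(seq_len(n_sites), val), validation = sort(val))
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
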