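#' Configuration of a synthetic binding study
#'
#' Defines the generative model used to emulate an ampDAP-seq study at desk
#' scale: a multi-contig genome (nuclear plus organelle-named contigs),
#' planted motif instances whose true affinity is a linear function of
#' standardized local shape features plus Gaussian noise, 200-bp peaks for
#' the bound instances, and several pseudo-datasets carrying shared
#' artifact peaks for the recurrence filter.
#'
#' @param contigs Named integer vector of contig lengths. The defaults give
#'   a 1-Mb genome with two nuclear chromosomes and small organelle contigs.
#' @param gc GC content of the background sequence (0.36, Arabidopsis-like).
#' @param consensus Planted core motif consensus.
#' @param consensus_prob Per-position probability of the consensus base in
#'   the planting PWM (near-deterministic by default).
#' @param n_instances Number of planted motif instances (default 1000).
#' @param min_spacing Minimum distance in bases between planted instance
#'   starts (default 250, a little over one peak width, so each instance's
#'   peak and labeling radius involve exactly one instance and the planted
#'   ground truth stays identifiable).
#' @param organelle_fraction Fraction of instances planted on
#'   organelle-named contigs (exercises the exclusion filter).
#' @param causal Named numeric vector of effect weights on standardized
#'   shape features, names \code{"feature@position"}. The defaults place
#'   the two causal features in the flanks (\code{MGW@-3}, \code{roll@+3}),
#'   where the underlying pentamers consist of variable background bases:
#'   a feature centered on the near-deterministic core is a function of at
#'   most one or two variable bases, collapses to a handful of values
#'   shared with every other feature reading the same bases, and is
#'   therefore not attributable even in principle.
#' @param intercept Baseline affinity a0 in label units.
#' @param noise_sd Gaussian noise standard deviation in label units
#'   (default 50).
#' @param bound_threshold Affinity above which an instance is bound
#'   (default 400 label units).
#' @param n_datasets Number of pseudo-datasets including the target
#'   (default 6).
#' @param artifact_fraction Artifact peaks as a fraction of the target's
#'   true peaks (default 0.1); artifacts recur in every dataset.
#' @param frips Per-dataset FRiP values, target first. The default includes
#'   one failing dataset (0.04) to exercise the FRiP filter.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(contigs = c(Chr1 = 600000L, Chr2 = 350000L,
                                   ChrC = 30000L, ChrM = 20000L),
                       gc = 0.36,
                       consensus = "TGACGT",
                       consensus_prob = 0.97,
                       n_instances = 1000L,
                       min_spacing = 250L,
                       organelle_fraction = 0.02,
                       causal = c("MGW@-3" = 150, "roll@+3" = 150),
                       intercept = 300,
                       noise_sd = 50,
                       bound_threshold = 400,
                       n_datasets = 6L,
                       artifact_fraction = 0.1,
                       frips = c(0.25, 0.18, 0.22, 0.12, 0.15, 0.04)) {
  stopifnot(length(frips) == n_datasets, gc > 0, gc < 1,
            bound_threshold > 0, bound_threshold < 1000,
            grepl("^[ACGT]+$", consensus))
  structure(as.list(environment()), class = "sim_config")
}

#' Symmetry-respecting random shape-table fixture
#'
#' Draws loosely realistic values for every pentamer (minor groove width
#' 3-7 Angstrom, base-pair displacements within about 1 Angstrom, rise near
#' 3.3 Angstrom, angles within 15 degrees, helix twist 30-40 degrees), then
#' symmetrizes so that the reverse-complement symmetry classes hold exactly:
#' shear, buckle, shift and tilt flip sign between a pentamer and its
#' reverse complement, the other features are equal.
#'
#' @param seed Integer seed.
#' @return A \code{shape_table}.
#' @export
make_shape_table_fixture <- function(seed = 1L) {
  pents <- all_pentamers()
  n <- length(pents)
  ranges <- list(
    MGW = c(3, 7), shear = c(-1, 1), stretch = c(-0.5, 0.5),
    stagger = c(-0.8, 0.8), buckle = c(-15, 15),
    propeller_twist = c(-15, 15), opening = c(-6, 6),
    shift = c(-1, 1), slide = c(-1.5, 1.5), rise = c(3.1, 3.6),
    tilt = c(-8, 8), roll = c(-10, 10), helix_twist = c(30, 40))
  vals <- with_seed(seed, {
    m <- sapply(SHAPE_FEATURES, function(f) {
      stats::runif(n, ranges[[f]][1L], ranges[[f]][2L])
    })
    rownames(m) <- pents
    m
  })
  rc <- reverse_complement(pents)
  # symmetrize each pair once, from its lexicographically smaller member
  first <- pents < rc
  flip <- ifelse(SHAPE_FEATURES %in% SHAPE_ODD_FEATURES, -1, 1)
  partner <- vals[match(rc[first], pents), , drop = FALSE]
  even_mean <- (vals[first, , drop = FALSE] + partner) / 2
  odd_half <- (vals[first, , drop = FALSE] - partner) / 2
  sym <- sweep(even_mean, 2L, as.numeric(flip == 1), `*`) +
    sweep(odd_half, 2L, as.numeric(flip == -1), `*`)
  vals[first, ] <- sym
  vals[match(rc[first], pents), ] <- sweep(sym, 2L, flip, `*`)
  structure(list(values = vals, feature_names = SHAPE_FEATURES,
                 provenance = list(path = NA_character_,
                                   dialect = "synthetic")),
            class = "shape_table")
}

#' Simulate a multi-contig background genome
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed.
#' @return Named character vector of contig sequences with i.i.d. bases at
#'   the configured GC content.
#' @export
simulate_genome <- function(config, seed = 1L) {
  probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
  with_seed(seed, {
    vapply(config$contigs, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1L))
  })
}

# PWM used both to sample planted instances and as the scanning motif.
planting_pwm <- function(config) {
  bases <- strsplit(config$consensus, "")[[1L]]
  p <- config$consensus_prob
  probs <- matrix((1 - p) / 3, nrow = length(bases), ncol = 4L,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  probs[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- p
  bg <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
          (1 - config$gc) / 2)
  make_pwm(probs, background = bg, name = "planted")
}

#' Plant motif instances into a genome
#'
#' Overwrites non-overlapping positions with instances sampled from the
#' planting PWM, on both strands with equal probability. Instances keep a
#' 110-base margin from contig ends so they remain shape-featurizable and
#' a 200-bp peak around them fits inside the contig.
#'
#' @param genome Named character vector (from
#'   \code{\link{simulate_genome}}).
#' @param config A \code{sim_config}.
#' @param seed Integer seed.
#' @return List with the modified \code{genome} and \code{loci}, a data
#'   frame of planted positions (\code{contig}, \code{start}, \code{end},
#'   \code{strand}, \code{seq}; the instance as it reads on its strand).
#' @export
plant_motifs <- function(genome, config, seed = 1L) {
  m <- nchar(config$consensus)
  margin <- 110L  # keeps 200-bp peaks around planted motifs inside contigs
  n_org <- round(config$n_instances * config$organelle_fraction)
  organelles <- intersect(names(genome),
                          c("ChrC", "ChrM", "chloroplast", "mitochondria"))
  nuclear <- setdiff(names(genome), organelles)

  with_seed(seed, {
    pick_loci <- function(ctgs, n) {
      if (n == 0L || length(ctgs) == 0L) {
        return(data.frame(contig = character(), start = integer()))
      }
      lens <- nchar(genome[ctgs])
      ctg <- sample(ctgs, n, replace = TRUE, prob = lens)
      start <- vapply(ctg, function(cc) {
        sample.int(nchar(genome[[cc]]) - 2L * margin - m, 1L) + margin
      }, integer(1L))
      data.frame(contig = ctg, start = start, stringsAsFactors = FALSE)
    }
    loci <- rbind(pick_loci(nuclear, config$n_instances - n_org),
                  pick_loci(organelles, n_org))
    # enforce the configured minimum spacing within each contig
    keep <- unlist(lapply(split(seq_len(nrow(loci)), loci$contig),
                          function(idx) {
      o <- idx[order(loci$start[idx])]
      sel <- o[1L]
      last <- loci$start[o[1L]]
      for (i in o[-1L]) {
        if (loci$start[i] - last >= config$min_spacing) {
          sel <- c(sel, i)
          last <- loci$start[i]
        }
      }
      sel
    }), use.names = FALSE)
    loci <- loci[sort(keep), , drop = FALSE]
    n <- nrow(loci)
    loci$end <- loci$start + m
    loci$strand <- sample(c("+", "-"), n, replace = TRUE)
    # sample instances from the raw planting probabilities (the consensus
    # base with probability consensus_prob), in motif orientation
    raw <- matrix((1 - config$consensus_prob) / 3, nrow = m, ncol = 4L)
    raw[cbind(seq_len(m), match(strsplit(config$consensus, "")[[1L]],
                                c("A", "C", "G", "T")))] <-
      config$consensus_prob
    inst <- vapply(seq_len(n), function(i) {
      paste(c("A", "C", "G", "T")[
        vapply(seq_len(m), function(j) {
          sample.int(4L, 1L, prob = raw[j, ])
        }, integer(1L))], collapse = "")
    }, character(1L))
    loci$seq <- inst
    genomic <- ifelse(loci$strand == "+", inst, reverse_complement(inst))
    for (i in seq_len(n)) {
      s <- genome[[loci$contig[i]]]
      substr(s, loci$start[i] + 1L, loci$end[i]) <- genomic[i]
      genome[[loci$contig[i]]] <- s
    }
    rownames(loci) <- NULL
    list(genome = genome, loci = loci)
  })
}

#' Assign shape-driven true affinities to planted loci
#'
#' True affinity is \code{clip(a0 + sum_j w_j z_ij + e_i, 0, 1000)} where
#' \code{z_ij} is the locus's value of causal shape feature j, standardized
#' across loci, and \code{e_i} is Gaussian noise. A locus is bound when its
#' affinity exceeds the bound threshold.
#'
#' @param loci Planted loci (\code{\link{plant_motifs}}).
#' @param genome The motif-planted genome.
#' @param table A \code{shape_table}.
#' @param config A \code{sim_config}.
#' @param seed Integer seed.
#' @return \code{loci} with added \code{affinity} and \code{bound} columns.
#' @export
assign_affinity <- function(loci, genome, table, config, seed = 1L) {
  m <- nchar(config$consensus)
  b_needed <- causal_border(config)
  windows <- canonical_window(loci, genome, b_needed)
  feats <- featurize_windows(windows, table, m, b_needed)
  ok <- stats::complete.cases(feats)
  loci <- loci[ok, , drop = FALSE]
  feats <- feats[ok, , drop = FALSE]
  missing_causal <- setdiff(names(config$causal), colnames(feats))
  if (length(missing_causal) > 0L) {
    stop("causal feature(s) outside the featurization window: ",
         paste(missing_causal, collapse = ", "))
  }
  z <- scale(feats[, names(config$causal), drop = FALSE])
  lin <- config$intercept + as.vector(z %*% config$causal)
  noise <- with_seed(seed, stats::rnorm(nrow(loci), 0, config$noise_sd))
  loci$affinity <- pmin(pmax(lin + noise, 0), 1000)
  loci$bound <- loci$affinity > config$bound_threshold
  rownames(loci) <- NULL
  loci
}

# smallest border containing every causal feature position
causal_border <- function(config) {
  pos <- sub("^.*@", "", names(config$causal))
  flank <- grepl("^[+-]", pos)
  b <- if (any(flank)) max(abs(as.integer(pos[flank]))) else 0L
  max(b, 4L)
}

#' Emit narrowPeak pseudo-datasets and a manifest
#'
#' The target dataset receives a 200-bp peak for every bound locus (summit
#' at the motif midpoint, signalValue = true affinity) plus the shared
#' artifact peaks; every other pseudo-dataset receives the same artifact
#' peaks (which therefore recur in all datasets) and its own random unique
#' peaks. Peak files are written into \code{dir} and listed in a manifest
#' with the configured FRiP values.
#'
#' @param loci Loci with affinities (\code{\link{assign_affinity}}).
#' @param genome The planted genome (for contig bounds).
#' @param config A \code{sim_config}.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return List with \code{manifest} (a \code{dataset_manifest}, target
#'   \code{"target"}) and \code{truth} (list: bound loci and artifact peak
#'   summits).
#' @export
emit_peaks <- function(loci, genome, config, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- as_genome_charvec(genome)
  nuclear <- setdiff(names(genome),
                     c("ChrC", "ChrM", "chloroplast", "mitochondria"))
  bound <- loci[loci$bound, , drop = FALSE]
  mid <- (bound$start + bound$end) %/% 2L

  make_peaks <- function(contig, summit, signal) {
    data.frame(contig = contig, start = summit - 100L,
               end = summit + 100L,
               name = paste0("peak", seq_along(summit)),
               strand = ".", signal = signal, summit = summit,
               stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    # artifact peaks at motif-free positions, shared across all datasets
    n_art <- round(nrow(bound) * config$artifact_fraction)
    art <- random_free_summits(n_art, genome, nuclear, loci)
    art_signal <- stats::runif(n_art, 5, 50)

    random_peaks <- function(n) {
      sm <- random_free_summits(n, genome, nuclear, loci)
      make_peaks(sm$contig, sm$summit, stats::runif(n, 5, 200))
    }

    paths <- character(config$n_datasets)
    ids <- c("target", paste0("other", seq_len(config$n_datasets - 1L)))
    for (d in seq_len(config$n_datasets)) {
      peaks <- if (d == 1L) {
        rbind(make_peaks(bound$contig, mid, bound$affinity),
              make_peaks(art$contig, art$summit, art_signal))
      } else {
        rbind(make_peaks(art$contig, art$summit, art_signal),
              random_peaks(nrow(bound) %/% 2L))
      }
      peaks$name <- paste0(ids[d], "_peak", seq_len(nrow(peaks)))
      paths[d] <- file.path(dir, paste0(ids[d], ".narrowPeak"))
      write_narrowpeak(peaks, paths[d])
    }
    manifest <- dataset_manifest(
      data.frame(dataset_id = ids, path = paths, frip = config$frips,
                 stringsAsFactors = FALSE),
      target = "target")
    utils::write.table(manifest$entries, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(manifest = manifest,
         truth = list(bound_loci = bound, artifact_summits = art))
  })
}

# summits at least 150 bp away from any planted motif and inside contigs
random_free_summits <- function(n, genome, contigs, loci) {
  if (n == 0L) {
    return(data.frame(contig = character(), summit = integer()))
  }
  lens <- nchar(genome[contigs])
  out <- data.frame(contig = character(), summit = integer())
  guard <- 0L
  while (nrow(out) < n && guard < 50L) {
    guard <- guard + 1L
    ctg <- sample(contigs, n, replace = TRUE, prob = lens)
    summit <- vapply(ctg, function(cc) {
      sample.int(nchar(genome[[cc]]) - 220L, 1L) + 110L
    }, integer(1L))
    cand <- data.frame(contig = ctg, summit = summit,
                       stringsAsFactors = FALSE)
    free <- vapply(seq_len(n), function(i) {
      near <- loci$contig == cand$contig[i] &
        abs((loci$start + loci$end) %/% 2L - cand$summit[i]) <= 150L
      !any(near)
    }, logical(1L))
    out <- rbind(out, cand[free, , drop = FALSE])
  }
  utils::head(out, n)
}

#' Run the full synthetic study generator
#'
#' Genome, planted motifs, shape table fixture, affinities, peak files,
#' manifest and ground truth, all written under \code{dir} (FASTA, MEME
#' motif, shape table, narrowPeak files, manifest, truth table).
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Output directory.
#' @param seed Integer seed; sub-seeds for each step are derived from it.
#' @return List with \code{genome}, \code{loci}, \code{shape_table},
#'   \code{pwm}, \code{manifest}, \code{truth} and file \code{paths}.
#' @export
simulate_study <- function(config = sim_config(), dir = tempfile("simstudy"),
                           seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  table <- make_shape_table_fixture(seed)
  genome0 <- simulate_genome(config, seed + 1L)
  planted <- plant_motifs(genome0, config, seed + 2L)
  loci <- assign_affinity(planted$loci, planted$genome, table, config,
                          seed + 3L)
  peaks <- emit_peaks(loci, planted$genome, config, dir, seed + 4L)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    motif = file.path(dir, "motif.meme"),
    shape_table = file.path(dir, "shape_table.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_genome(planted$genome, paths$genome)
  pwm <- planting_pwm(config)
  write_meme_motif(pwm, paths$motif)
  write_shape_table(table, paths$shape_table)
  utils::write.table(loci, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(genome = planted$genome, loci = loci, shape_table = table,
       pwm = pwm, manifest = peaks$manifest, truth = peaks$truth,
       config = config, paths = paths)
}
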