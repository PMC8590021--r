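test_that("simulated genomes honour lengths, GC content and the seed", {
  cfg <- tiny_sim_config()
  g <- simulate_genome(cfg, seed = 1)
  expect_equal(unname(nchar(g)), unname(as.integer(cfg$contigs)))
  expect_named(g, names(cfg$contigs))
  bases <- table(strsplit(paste(g, collapse = ""), "")[[1]])
  n <- sum(bases)
  gc <- (bases[["G"]] + bases[["C"]]) / n
  # binomial bound: observed GC within 3 sd of the target
  expect_lt(abs(gc - cfg$gc), 3 * sqrt(cfg$gc * (1 - cfg$gc) / n))
  expect_identical(simulate_genome(cfg, seed = 1), g)
  expect_false(identical(simulate_genome(cfg, seed = 2), g))
})

test_that("planted motifs are on-genome, non-overlapping and both-stranded", {
  cfg <- tiny_sim_config(consensus_prob = 1)  # exact consensus instances
  g0 <- simulate_genome(cfg, seed = 2)
  pl <- plant_motifs(g0, cfg, seed = 3)
  loci <- pl$loci
  expect_gt(nrow(loci), 120)
  # every planted locus reads the consensus in its strand orientation
  for (i in sample(nrow(loci), 25)) {
    sub <- substr(pl$genome[[loci$contig[i]]], loci$start[i] + 1,
                  loci$end[i])
    seen <- if (loci$strand[i] == "+") sub else naive_revcomp(sub)
    expect_equal(seen, cfg$consensus)
  }
  # no overlaps within a contig
  by_ctg <- split(loci, loci$contig)
  for (d in by_ctg) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(diff(d$start) > nchar(cfg$consensus)))
  }
  # both strands used, roughly evenly (binomial 3-sd bound)
  frac_plus <- mean(loci$strand == "+")
  expect_lt(abs(frac_plus - 0.5), 3 * sqrt(0.25 / nrow(loci)))
})

test_that("affinity assignment follows the linear shape model", {
  cfg <- tiny_sim_config(consensus_prob = 1)
  tab <- make_shape_table_fixture(4)
  g0 <- simulate_genome(cfg, seed = 5)
  pl <- plant_motifs(g0, cfg, seed = 6)

  # zero weights, zero noise: every affinity equals the intercept
  cfg0 <- tiny_sim_config(causal = c("roll@2" = 0), noise_sd = 0)
  a0 <- assign_affinity(pl$loci, pl$genome, tab, cfg0, seed = 7)
  expect_true(all(a0$affinity == cfg0$intercept))

  # single positive weight, zero noise: affinity monotone in the feature
  cfg1 <- tiny_sim_config(causal = c("MGW@1" = 100), noise_sd = 0)
  a1 <- assign_affinity(pl$loci, pl$genome, tab, cfg1, seed = 7)
  w <- canonical_window(a1, pl$genome, b = 4)
  f <- featurize_windows(w, tab, nchar(cfg$consensus), 4L)
  expect_gt(stats::cor(a1$affinity, f[, "MGW@1"]), 0.999)

  # threshold at the median: bound fraction near one half
  med_cfg <- tiny_sim_config(noise_sd = 50)
  a2 <- assign_affinity(pl$loci, pl$genome, tab, med_cfg, seed = 8)
  med_cfg$bound_threshold <- stats::median(a2$affinity)
  a3 <- assign_affinity(pl$loci, pl$genome, tab, med_cfg, seed = 8)
  expect_lt(abs(mean(a3$bound) - 0.5), 0.05)
})

test_that("emitted peaks are well-formed and the artifact filter removes artifacts", {
  cfg <- tiny_sim_config(artifact_fraction = 0.3)
  dir <- withr::local_tempdir()
  study <- simulate_study(cfg, dir = dir, seed = 9)
  target <- read_narrowpeak(study$manifest$entries$path[1])
  expect_true(all(target$end - target$start == 200L))
  expect_true(all(target$summit >= target$start & target$summit < target$end))

  # round trip preserved all fields
  rt <- withr::local_tempfile()
  write_narrowpeak(target, rt)
  expect_equal(read_narrowpeak(rt)$summit, target$summit)

  # artifacts recur in every dataset and are removed; true peaks survive
  kept_sets <- lapply(filter_frip(study$manifest)$entries$path,
                      read_narrowpeak)
  filtered <- filter_artifacts(target, kept_sets)
  art <- study$truth$artifact_summits
  expect_gt(nrow(art), 0)
  expect_length(intersect(filtered$summit, art$summit), 0L)
  true_summits <- (study$truth$bound_loci$start +
                   study$truth$bound_loci$end) %/% 2L
  expect_gt(mean(true_summits %in% filtered$summit), 0.95)
})

test_that("dataset construction recovers the planted bound set", {
  cfg <- tiny_sim_config(consensus_prob = 1)
  dir <- withr::local_tempdir()
  study <- simulate_study(cfg, dir = dir, seed = 10)
  hits <- scan_genome(study$genome, study$pwm)
  ds <- build_training_dataset(hits, study$manifest, study$genome,
                               study$shape_table, seed = 10)

  # independent labeling oracle: brute-force distance from every hit to
  # every artifact-filtered peak summit, monomer-mode retention by loop
  peak_sets <- lapply(filter_frip(study$manifest)$entries$path,
                      read_narrowpeak)
  peaks <- filter_artifacts(peak_sets[[1]], peak_sets)
  dist_to <- function(h, s) {
    if (s >= h$start && s < h$end) 0 else min(abs(h$start - s),
                                              abs(h$end - 1L - s))
  }
  n_in_radius <- integer(nrow(peaks))
  hit_bound <- logical(nrow(hits))
  hit_peak <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    best <- NA_integer_
    for (j in which(peaks$contig == hits$contig[i])) {
      if (dist_to(hits[i, ], peaks$summit[j]) <= 80) {
        n_in_radius[j] <- n_in_radius[j] + 1L
        if (is.na(best) || peaks$signal[j] > peaks$signal[best]) best <- j
      }
    }
    hit_bound[i] <- !is.na(best)
    hit_peak[i] <- best
  }
  expect_lt(sum(n_in_radius >= 2), sum(n_in_radius == 1))  # monomer TF
  oracle_bound <- hits[hit_bound & n_in_radius[hit_peak] == 1L &
                         !hits$contig %in% c("ChrC", "ChrM"), ]
  got <- ds$sites[ds$sites$bound, ]
  expect_setequal(paste(got$contig, got$start, got$strand),
                  paste(oracle_bound$contig, oracle_bound$start,
                        oracle_bound$strand))
  # nearly all planted nuclear bound loci come through; the few that do
  # not are dropped by the homodimer rule when a chance background match
  # lands inside their peak radius
  truth <- study$truth$bound_loci
  truth <- truth[!truth$contig %in% c("ChrC", "ChrM"), ]
  expect_gt(mean(paste(truth$contig, truth$start) %in%
                   paste(got$contig, got$start)), 0.85)
  # bound labels span [0, 1000]; unbound are 0
  expect_equal(range(ds$sites$label[ds$sites$bound]), c(0, 1000))
  expect_true(all(ds$sites$label[!ds$sites$bound] == 0))
  # deterministic reconstruction
  ds2 <- build_training_dataset(scan_genome(study$genome, study$pwm),
                                study$manifest, study$genome,
                                study$shape_table, seed = 10)
  expect_identical(ds$sites, ds2$sites)
  expect_identical(ds$features, ds2$features)
})

test_that("the pipeline recovers causal features and beats the motif baseline", {
  cfg <- sim_config(contigs = c(Chr1 = 300000L, Chr2 = 150000L,
                                ChrC = 15000L),
                    n_instances = 600L, n_datasets = 5L,
                    frips = c(0.2, 0.15, 0.1, 0.25, 0.04))
  dir <- withr::local_tempdir()
  study <- simulate_study(cfg, dir = dir, seed = 12)
  hits <- scan_genome(study$genome, study$pwm)
  ds <- build_training_dataset(hits, study$manifest, study$genome,
                               study$shape_table, seed = 12)
  model <- train(ds, hyper_space(iterations = 4, folds = 3), b = 4,
                 seed = 12)
  ev <- evaluate_model(model, ds)
  expect_gt(ev$pr$auprc, ev$baseline$auprc)
  imp <- pipeline_importance(model, ds, n_samples = 40, n_background = 40,
                             seed = 12)
  expect_true(all(names(cfg$causal) %in% imp$ranking$feature[1:5]))
})

test_that("study files on disk reproduce the in-memory objects", {
  cfg <- tiny_sim_config()
  dir <- withr::local_tempdir()
  study <- simulate_study(cfg, dir = dir, seed = 13)
  expect_identical(read_genome(study$paths$genome), study$genome)
  tab <- read_shape_table(study$paths$shape_table)
  expect_equal(tab$values, study$shape_table$values)
  pwm <- read_meme_motif(study$paths$motif, pseudocount = 0)
  expect_equal(pwm$probs, study$pwm$probs, tolerance = 1e-4)
  mf <- read_manifest(study$paths$manifest, target = "target")
  expect_equal(mf$entries$frip, cfg$frips)
})
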