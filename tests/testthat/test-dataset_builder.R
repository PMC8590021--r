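make_peak <- function(contig, summit, signal, name = "p") {
  data.frame(contig = contig, start = summit - 100L, end = summit + 100L,
             name = name, strand = ".", signal = signal, summit = summit,
             stringsAsFactors = FALSE)
}

make_hit <- function(contig, start, m = 6L, strand = "+", score = 10) {
  data.frame(contig = contig, start = start, end = start + m,
             strand = strand, score = score, pvalue = 1e-4,
             matched_seq = strrep("A", m), stringsAsFactors = FALSE)
}

test_that("narrowPeak parsing computes summits and applies fallbacks", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t1000\t1200\tp1\t0\t.\t37.5\t-1\t-1\t100",
               "chr1\t5000\t5200\tp2\t0\t.\t12\t-1\t-1\t50"), f)
  pk <- read_narrowpeak(f)
  expect_equal(pk$summit, c(1100L, 5050L))
  expect_equal(pk$signal, c(37.5, 12))

  writeLines("chr1\t1000\t1200\tp1\t0\t.\t37.5\t-1\t-1\t-1", f)
  expect_warning(pk2 <- read_narrowpeak(f), "midpoint")
  expect_equal(pk2$summit, 1100L)

  writeLines("chr1\t1000\t1150\tp1\t0\t.\t5\t-1\t-1\t10", f)
  expect_warning(read_narrowpeak(f), "200 bp")

  writeLines("chr1\t1000\t1200\tp1\t0\t.\t37.5\t-1\t-1", f)
  expect_error(suppressWarnings(read_narrowpeak(f)))

  # round trip
  f2 <- withr::local_tempfile()
  write_narrowpeak(pk, f2)
  expect_equal(read_narrowpeak(f2)[, c("contig", "start", "end", "signal",
                                       "summit")],
               pk[, c("contig", "start", "end", "signal", "summit")])
})

test_that("FRiP filter is strictly greater-than and protects the target", {
  dir <- withr::local_tempdir()
  pk <- make_peak("chr1", 1000L, 10)
  mf <- manifest_fixture(list(a = pk, b = pk, c = pk),
                         frips = c(0.04, 0.051, 0.05), dir, target = "b")
  kept <- filter_frip(mf)
  expect_equal(kept$entries$dataset_id, "b")

  mf2 <- manifest_fixture(list(a = pk, b = pk), frips = c(0.2, 0.3), dir)
  expect_equal(filter_frip(mf2)$entries$dataset_id, c("a", "b"))

  mf3 <- manifest_fixture(list(a = pk, b = pk), frips = c(0.03, 0.3), dir,
                          target = "a")
  expect_error(filter_frip(mf3), "target")
})

test_that("artifact filter discards peaks recurring in > 1/3 of datasets", {
  # target has two peaks; the first co-occurs (summit within 100 bp) in 4 of
  # 10 datasets, the second in 3 of 10
  target <- rbind(make_peak("chr1", 10000L, 50, "a"),
                  make_peak("chr1", 50000L, 60, "b"))
  others <- lapply(1:9, function(i) {
    p <- make_peak("chr2", 7000L + 1000L * i, 5)
    if (i <= 3) p <- rbind(p, make_peak("chr1", 10000L + 10L * i, 5))
    if (i <= 2) p <- rbind(p, make_peak("chr1", 50050L, 5))
    p
  })
  all_sets <- c(list(target = target), setNames(others, paste0("d", 1:9)))
  kept <- filter_artifacts(target, all_sets)
  expect_equal(kept$name, "b")

  # 3 of 10 (fraction 0.3 <= 1/3) is kept: drop one co-occurrence of peak a
  all_sets2 <- all_sets
  all_sets2$d3 <- make_peak("chr2", 10000L, 5)
  expect_equal(filter_artifacts(target, all_sets2)$name, c("a", "b"))

  expect_warning(out <- filter_artifacts(target, all_sets[1:2]), "skipped")
  expect_equal(nrow(out), 2L)
})

test_that("80-bp summit labeling follows the nearest-base distance rule", {
  peaks <- make_peak("chr1", 1000L, 42)
  bound <- label_hits(make_hit("chr1", 1078L), peaks)   # distance 78
  expect_true(bound$bound)
  expect_equal(bound$signal, 42)
  unbound <- label_hits(make_hit("chr1", 1081L), peaks) # distance 81
  expect_false(unbound$bound)

  # motif overlapping the summit: distance 0
  expect_true(label_hits(make_hit("chr1", 998L), peaks)$bound)

  # several peaks in radius: highest signal wins
  two <- rbind(make_peak("chr1", 1000L, 10, "lo"),
               make_peak("chr1", 1010L, 99, "hi"))
  lab <- label_hits(make_hit("chr1", 1005L), two)
  expect_equal(lab$signal, 99)
  expect_equal(lab$peak_id, 2L)

  # no peaks: everything unbound
  none <- label_hits(make_hit("chr1", 500L), peaks[0, , drop = FALSE])
  expect_false(none$bound)
})

test_that("homodimer classification follows the strict majority rule", {
  build <- function(n_multi, n_single) {
    peaks <- do.call(rbind, lapply(seq_len(n_multi + n_single), function(i) {
      make_peak("chr1", 10000L * i, 10 + i, paste0("pk", i))
    }))
    hits <- do.call(rbind, lapply(seq_len(n_multi + n_single), function(i) {
      h <- make_hit("chr1", 10000L * i - 20L)
      if (i <= n_multi) h <- rbind(h, make_hit("chr1", 10000L * i + 30L))
      h
    }))
    list(peaks = peaks, hits = label_hits(hits, peaks))
  }
  # 6 multi vs 4 single: homodimer mode, single-occurrence hits dropped
  s <- build(6, 4)
  res <- detect_homodimer(s$hits, s$peaks)
  expect_true(res$homodimer_mode)
  expect_equal(sum(res$hits$bound), 12L)

  # 4 multi vs 6 single: monomer mode, multi-occurrence hits dropped
  s <- build(4, 6)
  res <- detect_homodimer(s$hits, s$peaks)
  expect_false(res$homodimer_mode)
  expect_equal(sum(res$hits$bound), 6L)

  # 5 vs 5 tie: monomer mode
  s <- build(5, 5)
  res <- detect_homodimer(s$hits, s$peaks)
  expect_false(res$homodimer_mode)

  # unbound hits are never dropped
  s <- build(6, 4)
  with_unbound <- rbind(s$hits, label_hits(make_hit("chr1", 999000L),
                                           s$peaks))
  res <- detect_homodimer(with_unbound, s$peaks)
  expect_equal(sum(!res$hits$bound), 1L)
})

test_that("organelle exclusion honours the default and custom name sets", {
  hits <- rbind(make_hit("Chr1", 100L), make_hit("ChrC", 100L),
                make_hit("ChrM", 100L))
  expect_equal(exclude_organelles(hits)$contig, "Chr1")
  expect_equal(nrow(exclude_organelles(make_hit("Chr1", 5L))), 1L)
  expect_equal(exclude_organelles(hits, organelle_names = "Chr1")$contig,
               c("ChrC", "ChrM"))
})

test_that("ratio balancing reproduces the 1:5 / 120,000 / 1:3 rule", {
  mk <- function(n_bound, n_unbound) {
    data.frame(bound = rep(c(TRUE, FALSE), c(n_bound, n_unbound)))
  }
  b1 <- balance_ratio(mk(100, 1000), seed = 1)
  expect_equal(c(sum(b1$bound), sum(!b1$bound)), c(100L, 500L))

  b2 <- balance_ratio(mk(30000, 600000), seed = 1)
  expect_equal(c(sum(b2$bound), sum(!b2$bound)), c(30000L, 90000L))
  expect_equal(nrow(b2), 120000L)

  b3 <- balance_ratio(mk(100, 300), seed = 1)
  expect_equal(nrow(b3), 400L)

  expect_error(balance_ratio(mk(0, 10), seed = 1), "no bound")

  # determinism under the seed
  expect_identical(rownames(balance_ratio(mk(50, 1000), seed = 9)),
                   rownames(balance_ratio(mk(50, 1000), seed = 9)))
  expect_false(identical(rownames(balance_ratio(mk(50, 1000), seed = 9)),
                         rownames(balance_ratio(mk(50, 1000), seed = 10))))
})

test_that("signal normalization and sample weights follow the stated rules", {
  sites <- data.frame(bound = c(TRUE, TRUE, TRUE, FALSE),
                      signal = c(10, 20, 30, NA))
  n <- normalize_signal(sites)
  expect_equal(n$label, c(0, 500, 1000, 0))

  one <- normalize_signal(data.frame(bound = c(TRUE, FALSE),
                                     signal = c(7, NA)))
  expect_equal(one$label, c(1000, 0))

  w <- compute_sample_weights(
    data.frame(bound = rep(c(TRUE, FALSE), c(100, 500))))
  expect_equal(unique(w$weight[w$bound]), 5)
  expect_equal(unique(w$weight[!w$bound]), 1)
  w2 <- compute_sample_weights(
    data.frame(bound = rep(c(TRUE, FALSE), c(10, 10))))
  expect_true(all(w2$weight == 1))
  expect_true(all(w$weight > 0))
})

test_that("stratified split keeps proportions and is seed-reproducible", {
  sites <- data.frame(bound = rep(c(TRUE, FALSE), c(20, 80)))
  sp <- split_dataset(sites, seed = 4)
  expect_length(sp$validation, 20L)
  expect_equal(sum(sites$bound[sp$validation]), 4L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_setequal(c(sp$train, sp$validation), 1:100)

  sp2 <- split_dataset(sites, seed = 5)
  expect_false(identical(sp$validation, sp2$validation))
  expect_equal(sum(sites$bound[sp2$validation]), 4L)

  expect_warning(sp0 <- split_dataset(sites, validation_fraction = 0),
                 "empty validation")
  expect_length(sp0$validation, 0L)
})
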