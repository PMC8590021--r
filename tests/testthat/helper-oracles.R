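# Independent oracles and fixture builders shared across tests.
# Everything here is deliberately naive: direct enumeration, per-element
# loops, hand arithmetic — never the vectorized package code paths.

# random DNA string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive reverse complement via lookup loop
naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# exhaustive PWM scan: every window, both strands, exact grid p-values from
# full 4^m enumeration; same-locus collision resolved by score then plus
naive_scan <- function(genome, pwm, pthresh, eps = 1e-3) {
  m <- nrow(pwm$probs)
  lod <- log2(sweep(pwm$probs, 2, pwm$background, `/`))
  I <- round(lod / eps)
  grids <- expand.grid(rep(list(1:4), m))
  ints <- as.matrix(grids)
  sc <- vapply(seq_len(nrow(ints)), function(i) {
    sum(I[cbind(seq_len(m), ints[i, ])])
  }, numeric(1))
  w <- apply(ints, 1, function(r) prod(pwm$background[r]))
  kmers <- apply(ints, 1, function(r) {
    paste(c("A", "C", "G", "T")[r], collapse = "")
  })
  pv <- vapply(sc, function(s) sum(w[sc >= s]), numeric(1))
  lut <- new.env(hash = TRUE, size = 2L * length(kmers))
  for (i in seq_along(kmers)) {
    assign(kmers[i], c(sc[i], pv[i]), envir = lut)
  }
  rows <- list()
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    L <- nchar(s)
    if (L < m) next
    for (i in seq_len(L - m + 1)) {
      kp <- substr(s, i, i + m - 1)
      if (grepl("[^ACGT]", kp)) next
      km <- naive_revcomp(kp)
      vp <- get(kp, envir = lut)
      vm <- get(km, envir = lut)
      cand <- list()
      if (vp[2] <= pthresh) {
        cand$p <- data.frame(contig = ctg, start = i - 1L, strand = "+",
                             int = vp[1], pvalue = vp[2])
      }
      if (vm[2] <= pthresh) {
        cand$m <- data.frame(contig = ctg, start = i - 1L, strand = "-",
                             int = vm[1], pvalue = vm[2])
      }
      if (length(cand) == 2) {
        cand <- if (cand$p$int >= cand$m$int) cand["p"] else cand["m"]
      }
      rows <- c(rows, cand)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      strand = character(), int = numeric(),
                      pvalue = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force precision-recall sweep: confusion matrix at every threshold
naive_auprc <- function(scores, flags) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(flags)
  prev_recall <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & flags)
    precision <- tp / sum(pred)
    recall <- tp / P
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# evaluate one plain tree on a feature vector (1-based wrapper over the
# 0-based node arrays)
eval_tree <- function(tr, v) {
  node <- 1L
  while (tr$feature[node] >= 0L) {
    node <- if (v[tr$feature[node] + 1L] <= tr$split[node]) {
      tr$left[node] + 1L
    } else {
      tr$right[node] + 1L
    }
  }
  tr$value[node]
}

# exact interventional Shapley values by subset enumeration
brute_shap <- function(trees, x, bg) {
  p <- length(x)
  f <- function(v) mean(vapply(trees, eval_tree, numeric(1), v = v))
  vfun <- function(S) {
    mean(apply(bg, 1, function(z) {
      h <- z
      h[S] <- x[S]
      f(h)
    }))
  }
  phi <- numeric(p)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  for (i in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      S <- subsets[r, ]
      if (S[i]) next
      wgt <- factorial(sum(S)) * factorial(p - sum(S) - 1) / factorial(p)
      Si <- S
      Si[i] <- TRUE
      phi[i] <- phi[i] + wgt * (vfun(Si) - vfun(S))
    }
  }
  phi
}

# random regression tree in the package's 0-based array format
random_tree <- function(p, depth, split_prob = 0.8) {
  nodes <- list(left = integer(), right = integer(), feature = integer(),
                split = numeric(), value = numeric())
  build <- function(d) {
    id <- length(nodes$feature) + 1L
    nodes$feature[id] <<- -1L
    nodes$left[id] <<- -1L
    nodes$right[id] <<- -1L
    nodes$split[id] <<- 0
    nodes$value[id] <<- 0
    if (d > 0 && stats::runif(1) < split_prob) {
      nodes$feature[id] <<- sample.int(p, 1) - 1L
      nodes$split[id] <<- stats::runif(1)
      nodes$left[id] <<- build(d - 1)
      nodes$right[id] <<- build(d - 1)
    } else {
      nodes$value[id] <<- stats::runif(1, 0, 1000)
    }
    id - 1L
  }
  build(depth)
  nodes
}

# single decision stump as a tree_ensemble
stump_ensemble <- function(feature0, split, left_value, right_value) {
  structure(list(trees = list(list(
    left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
    feature = c(feature0, -1L, -1L), split = c(split, 0, 0),
    value = c(0, left_value, right_value)))), class = "tree_ensemble")
}

# small in-memory narrowPeak writer for fixture files
write_peak_fixture <- function(df, path) {
  write_narrowpeak(df, path)
  path
}

# minimal manifest on disk from peak data frames
manifest_fixture <- function(peak_sets, frips, dir, target = names(peak_sets)[1]) {
  paths <- vapply(names(peak_sets), function(id) {
    p <- file.path(dir, paste0(id, ".narrowPeak"))
    write_narrowpeak(peak_sets[[id]], p)
    p
  }, character(1))
  dataset_manifest(
    data.frame(dataset_id = names(peak_sets), path = paths, frip = frips,
               stringsAsFactors = FALSE),
    target = target)
}

# a small, fast synthetic study configuration for unit tests
tiny_sim_config <- function(...) {
  sim_config(contigs = c(Chr1 = 120000L, Chr2 = 60000L, ChrC = 15000L),
             n_instances = 250L, n_datasets = 5L,
             frips = c(0.2, 0.15, 0.1, 0.25, 0.04), ...)
}

# uniform-value shape table (every pentamer maps to the same vector)
constant_shape_table <- function(value = 1) {
  tab <- make_shape_table_fixture(1)
  tab$values[, ] <- value
  tab
}
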