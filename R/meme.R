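#' Construct a position weight matrix
#'
#' @param probs m x 4 matrix of per-position base probabilities, columns in
#'   A, C, G, T order. Each row must sum to 1 (tolerance 0.01 before
#'   pseudocount regularization).
#' @param background Length-4 vector of background base probabilities
#'   (default uniform).
#' @param name Motif name.
#' @param pseudocount Pseudocount added per cell, weighted by the
#'   background, before renormalization: p' = (p + c * bg) / (1 + c).
#' @return Object of class \code{pwm}.
#' @export
make_pwm <- function(probs, background = rep(0.25, 4), name = "motif",
                     pseudocount = 0.1) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("probs must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1L) stop("motif must have at least one position")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 0.01)) {
    stop("PWM row(s) do not sum to 1 within tolerance: row ",
         which(abs(rowSums(probs) - 1) > 0.01)[1L])
  }
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 probabilities summing to 1")
  }
  background <- background / sum(background)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount > 0) {
    probs <- sweep(probs, 2L, background * pseudocount, `+`) /
      (1 + pseudocount)
  }
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(probs = probs, background = background,
                 pseudocount = pseudocount, name = name),
            class = "pwm")
}

#' Read a motif from a MEME minimal format file
#'
#' Parses the letter-probability matrix of the \code{index}-th motif in a
#' MEME minimal format file; the first motif is MEME's best-ranked one. The
#' file's background letter frequencies are used when present, otherwise a
#' uniform background. A background-weighted pseudocount is applied.
#'
#' @param path Path to the MEME file.
#' @param index Which motif to read (1-based; default the first).
#' @param pseudocount See \code{\link{make_pwm}}.
#' @return Object of class \code{pwm}.
#' @export
read_meme_motif <- function(path, index = 1L, pseudocount = 0.1) {
  if (!file.exists(path)) stop("MEME file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)

  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0L) {
    i <- bg_at[1L] + 1L
    while (i <= length(lines) && lines[i] == "") i <- i + 1L
    if (i <= length(lines)) {
      toks <- strsplit(lines[i], "\\s+")[[1L]]
      if (length(toks) >= 8L) {
        bases <- toks[seq(1L, 7L, by = 2L)]
        vals <- suppressWarnings(as.numeric(toks[seq(2L, 8L, by = 2L)]))
        if (!anyNA(vals) && setequal(bases, c("A", "C", "G", "T"))) {
          background <- vals[match(c("A", "C", "G", "T"), bases)]
          background <- background / sum(background)
        }
      }
    }
  }

  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0L) stop("no MOTIF record found in ", path)
  if (index < 1L || index > length(motif_at)) {
    stop("motif index ", index, " out of range; file has ",
         length(motif_at), " motif(s)")
  }
  start <- motif_at[index]
  stop_at <- if (index < length(motif_at)) motif_at[index + 1L] - 1L
             else length(lines)
  block <- lines[start:stop_at]
  name <- sub("^MOTIF\\s+", "", block[1L])
  name <- strsplit(name, "\\s+")[[1L]][1L]

  lp_at <- grep("^letter-probability matrix", block)
  if (length(lp_at) == 0L) {
    stop("malformed MEME motif: no letter-probability matrix header")
  }
  hdr <- block[lp_at[1L]]
  w <- NA_integer_
  wm <- regmatches(hdr, regexec("w=\\s*(\\d+)", hdr))[[1L]]
  if (length(wm) == 2L) w <- as.integer(wm[2L])
  am <- regmatches(hdr, regexec("alength=\\s*(\\d+)", hdr))[[1L]]
  if (length(am) == 2L && as.integer(am[2L]) != 4L) {
    stop("only alength = 4 (DNA) motifs are supported")
  }

  rows <- list()
  i <- lp_at[1L] + 1L
  while (i <= length(block) && length(rows) < max(w, 0L, na.rm = TRUE) ||
         (is.na(w) && i <= length(block))) {
    ln <- block[i]
    if (ln == "" || grepl("^(URL|MOTIF)", ln)) break
    toks <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
    if (anyNA(toks) || length(toks) != 4L) {
      if (is.na(w)) break
      stop("malformed letter-probability matrix row: '", ln, "'")
    }
    rows[[length(rows) + 1L]] <- toks
    i <- i + 1L
  }
  if (length(rows) == 0L) stop("empty letter-probability matrix")
  if (!is.na(w) && length(rows) != w) {
    stop("letter-probability matrix has ", length(rows),
         " rows but header declares w = ", w)
  }
  probs <- do.call(rbind, rows)
  make_pwm(probs, background = background, name = name,
           pseudocount = pseudocount)
}

#' Write a motif in MEME minimal format
#'
#' @param pwm A \code{pwm} (the stored, pseudocount-regularized
#'   probabilities are written).
#' @param path Output path.
#' @export
write_meme_motif <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm"))
  bg <- sprintf("A %.5f C %.5f G %.5f T %.5f", pwm$background[1L],
                pwm$background[2L], pwm$background[3L], pwm$background[4L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 5", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies", bg, "",
               paste("MOTIF", pwm$name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(pwm$probs)),
               apply(pwm$probs, 1L, function(r)
                 sprintf(" %.6f %.6f %.6f %.6f", r[1L], r[2L], r[3L], r[4L]))),
             con)
  invisible(path)
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$name, "': ", nrow(x$probs), " positions, consensus ",
      pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm A \code{pwm}.
#' @return The per-position most probable base as a string.
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$probs, 1L, which.max)],
        collapse = "")
}
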