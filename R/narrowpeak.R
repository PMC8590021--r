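#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand,
#' signalValue, pValue, qValue, summit offset. The summit is returned as an
#' absolute 0-based coordinate (\code{start + offset}); an offset of -1
#' (unknown summit) falls back to the interval midpoint with a warning.
#' Intervals whose width is not the canonical 200 bp are accepted with a
#' warning.
#'
#' @param path Path to the narrowPeak file.
#' @return Data frame with columns \code{contig}, \code{start}, \code{end}
#'   (0-based half-open), \code{name}, \code{strand}, \code{signal},
#'   \code{summit} (absolute 0-based).
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  df <- utils::read.table(path, sep = "", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character",
                                         "numeric", "numeric", "numeric",
                                         "integer")[1:10],
                          fill = FALSE)
  if (ncol(df) != 10L) {
    stop("narrowPeak requires 10 columns (BED6+4), found ", ncol(df))
  }
  names(df) <- c("contig", "start", "end", "name", "score", "strand",
                 "signal", "pvalue", "qvalue", "summit_offset")
  if (any(df$signal < 0)) stop("negative signalValue in ", path)
  no_summit <- df$summit_offset < 0L
  summit <- df$start + df$summit_offset
  if (any(no_summit)) {
    warning(sum(no_summit), " peak(s) without summit offset; ",
            "using the interval midpoint")
    summit[no_summit] <- (df$start[no_summit] + df$end[no_summit]) %/% 2L
  }
  if (any(df$end - df$start != 200L)) {
    warning(sum(df$end - df$start != 200L),
            " peak(s) are not 200 bp wide")
  }
  out <- data.frame(contig = df$contig, start = df$start, end = df$end,
                    name = df$name, strand = df$strand,
                    signal = df$signal, summit = summit,
                    stringsAsFactors = FALSE)
  if (any(out$summit < out$start | out$summit >= out$end)) {
    stop("summit outside peak interval in ", path)
  }
  out
}

#' Write peaks as a narrowPeak file
#'
#' @param peaks Peak data frame as returned by \code{\link{read_narrowpeak}}.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(peaks$contig, peaks$start, peaks$end,
                    if (is.null(peaks$name)) "." else peaks$name,
                    0L,
                    if (is.null(peaks$strand)) "." else peaks$strand,
                    peaks$signal, -1, -1,
                    peaks$summit - peaks$start)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
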