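#' @useDynLib shapetf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The 13 DNA shape features, in fixed order
#'
#' Minor groove width first, then the six intra-base-pair parameters
#' (displacements of the two bases of a pair relative to each other), then the
#' six inter-base-pair step parameters (displacements of consecutive pairs).
#' Every feature matrix and feature vector in the package uses this order.
#'
#' @format Character vector of length 13.
#' @export
SHAPE_FEATURES <- c(
  "MGW",
  "shear", "stretch", "stagger", "buckle", "propeller_twist", "opening",
  "shift", "slide", "rise", "tilt", "roll", "helix_twist"
)

# Features whose sign flips when a duplex is read from the complementary
# strand; the remaining nine (and MGW) are invariant. Used only to expand
# reverse-complement-collapsed query tables and in symmetry audits: windows
# themselves are always canonicalized to the motif's plus orientation before
# lookup, so downstream code never applies these rules.
SHAPE_ODD_FEATURES <- c("shear", "buckle", "shift", "tilt")

SHAPE_INTRA_FEATURES <- c("shear", "stretch", "stagger", "buckle",
                          "propeller_twist", "opening")
SHAPE_INTER_FEATURES <- c("shift", "slide", "rise", "tilt", "roll",
                          "helix_twist")

# number of context bases consumed at each end of a window by pentamer lookup
PENTAMER_CONTEXT <- 2L

#' All 1024 DNA pentamers
#'
#' @return Character vector of the 4^5 strings over A, C, G, T in
#'   lexicographic order.
#' @export
all_pentamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p5 = b, p4 = b, p3 = b, p2 = b, p1 = b,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3, g$p4, g$p5))
}

#' Read a pentamer shape query table
#'
#' Loads the query table that maps each DNA pentamer to 13 shape feature
#' values (the value describes the central base/base-pair step of the
#' pentamer). Two dialects are accepted: a full table with one row per
#' pentamer (1024 rows) and a collapsed table with one row per
#' pentamer/reverse-complement pair (512 rows). Collapsed tables are expanded
#' using the strand symmetry of the parameters: shear, buckle, shift and tilt
#' change sign on the complementary strand, the other nine values are copied.
#'
#' The file is delimited text (tab or comma, auto-detected from the header
#' line) with a header row; the first column holds the pentamer and the
#' remaining columns must be named after the 13 features in
#' \code{\link{SHAPE_FEATURES}} (any column order).
#'
#' @param path Path to the table.
#' @param dialect \code{"auto"} (default; decided from the row count),
#'   \code{"full"} or \code{"collapsed"}.
#' @return An object of class \code{shape_table}: a list with \code{values}
#'   (1024 x 13 numeric matrix, rownames = pentamers), \code{feature_names}
#'   and \code{provenance}.
#' @export
read_shape_table <- function(path, dialect = c("auto", "full", "collapsed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("shape table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) != 14L) {
    stop("shape table must have a pentamer column plus 13 feature columns, ",
         "found ", ncol(df), " columns")
  }
  keys <- toupper(as.character(df[[1L]]))
  bad <- keys[!grepl("^[ACGT]{5}$", keys)]
  if (length(bad) > 0L) {
    stop("non-ACGT pentamer key(s) in shape table: ",
         paste(utils::head(bad, 3L), collapse = ", "))
  }
  feat_cols <- names(df)[-1L]
  missing_feat <- setdiff(SHAPE_FEATURES, feat_cols)
  if (length(missing_feat) > 0L) {
    stop("shape table is missing feature column(s): ",
         paste(missing_feat, collapse = ", "))
  }
  vals <- as.matrix(df[, SHAPE_FEATURES, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("shape table contains missing or non-finite values")
  }
  rownames(vals) <- keys

  # collapse exact duplicates, reject conflicting ones
  if (anyDuplicated(keys)) {
    for (k in unique(keys[duplicated(keys)])) {
      rows <- vals[keys == k, , drop = FALSE]
      if (max(apply(rows, 2L, function(x) diff(range(x)))) > 1e-9) {
        stop("duplicate pentamer '", k, "' with conflicting values")
      }
    }
    vals <- vals[!duplicated(keys), , drop = FALSE]
    keys <- rownames(vals)
  }

  if (dialect == "auto") {
    dialect <- if (nrow(vals) <= 512L) "collapsed" else "full"
  }

  if (dialect == "collapsed") {
    vals <- expand_collapsed_table(vals)
  }

  pents <- all_pentamers()
  missing_keys <- setdiff(pents, rownames(vals))
  if (length(missing_keys) > 0L) {
    stop("shape table is missing pentamer(s): ",
         paste(utils::head(missing_keys, 3L), collapse = ", "),
         if (length(missing_keys) > 3L) sprintf(" (and %d more)",
                                                length(missing_keys) - 3L))
  }
  vals <- vals[pents, , drop = FALSE]

  structure(
    list(values = vals,
         feature_names = SHAPE_FEATURES,
         provenance = list(path = path, dialect = dialect)),
    class = "shape_table"
  )
}

# Expand a table keyed by one member of each pentamer/revcomp pair to all
# 1024 pentamers: odd features flip sign, even features are copied. A key
# whose reverse complement is also present must agree with the implied
# values.
expand_collapsed_table <- function(vals) {
  keys <- rownames(vals)
  rc <- reverse_complement(keys)
  flip <- rep(1, length(SHAPE_FEATURES))
  flip[SHAPE_FEATURES %in% SHAPE_ODD_FEATURES] <- -1
  rc_vals <- sweep(vals, 2L, flip, `*`)
  rownames(rc_vals) <- rc
  both <- intersect(keys, rc)
  if (length(both) > 0L) {
    if (max(abs(vals[both, , drop = FALSE] -
                rc_vals[both, , drop = FALSE])) > 1e-9) {
      stop("collapsed shape table contains a pentamer and its reverse ",
           "complement with values that violate the symmetry rules")
    }
    rc_vals <- rc_vals[setdiff(rc, keys), , drop = FALSE]
  }
  rbind(vals, rc_vals)
}

#' Look up pentamer shape values
#'
#' @param table A \code{shape_table}.
#' @param pentamers Character vector of 5-mers over A, C, G, T.
#' @return Numeric matrix, one row per pentamer, 13 columns.
#' @export
shape_lookup <- function(table, pentamers) {
  stopifnot(inherits(table, "shape_table"))
  idx <- match(pentamers, rownames(table$values))
  if (anyNA(idx)) {
    stop("unknown pentamer(s): ",
         paste(utils::head(pentamers[is.na(idx)], 3L), collapse = ", "))
  }
  table$values[idx, , drop = FALSE]
}

#' Write a shape table to delimited text
#'
#' Writes the full (1024-row) dialect, tab-delimited, re-readable with
#' \code{\link{read_shape_table}}.
#'
#' @param table A \code{shape_table}.
#' @param path Output path.
#' @export
write_shape_table <- function(table, path) {
  stopifnot(inherits(table, "shape_table"))
  df <- data.frame(pentamer = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.shape_table <- function(x, ...) {
  cat("Pentamer shape query table:", nrow(x$values), "pentamers x",
      ncol(x$values), "features\n")
  cat("dialect:", x$provenance$dialect, "\n")
  invisible(x)
}
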