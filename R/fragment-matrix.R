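#' Fragment matrix over heterozygous SNP positions
#'
#' Builds the m x n ternary fragment matrix M used by the wMEC model: one
#' row per sequencing read, one column per heterozygous SNP position.
#' Entries are 0 (reference allele), 1 (alternative allele) or `NA` (site
#' not covered by the read).  A parallel weight matrix W carries a
#' phred-scaled confidence for every defined entry.
#'
#' Columns covered by no read are dropped at construction (the majority
#' vote of an empty column is undefined) and reported with a message.
#'
#' @param entries integer matrix with values in \{0, 1, NA\}.
#' @param weights numeric matrix of the same dimension; must be > 0 exactly
#'   where `entries` is defined.  Defaults to unit weights.
#' @param positions strictly increasing 1-based genomic coordinates, one
#'   per column.  Defaults to `1:n`.
#' @param read_ids unique identifiers, one per row.
#' @return an object of class `fragment_matrix` with fields `entries`,
#'   `weights`, `positions`, `read_ids` and `spans` (per-read first/last
#'   covered column index).
#' @export
fragment_matrix <- function(entries, weights = NULL, positions = NULL,
                            read_ids = NULL) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "integer"
  if (!all(entries %in% c(0L, 1L, NA_integer_)))
    stop("entries must be 0, 1 or NA")
  m <- nrow(entries)
  n <- ncol(entries)
  if (m < 1L) stop("fragment matrix needs at least one read")
  if (is.null(weights)) {
    weights <- matrix(0, m, n)
    weights[!is.na(entries)] <- 1
  }
  weights <- as.matrix(weights)
  if (!identical(dim(weights), dim(entries)))
    stop("weights dimension mismatch")
  if (any(weights[!is.na(entries)] <= 0))
    stop("weights must be positive where entries are defined")
  if (any(weights[is.na(entries)] != 0))
    stop("weights must be zero where entries are missing")
  if (is.null(positions)) positions <- seq_len(n)
  if (length(positions) != n) stop("positions length mismatch")
  if (n > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (is.null(read_ids)) read_ids <- paste0("read", seq_len(m))
  if (anyDuplicated(read_ids)) stop("read_ids must be unique")

  covered <- colSums(!is.na(entries)) > 0L
  if (!all(covered)) {
    message(sum(!covered), " column(s) covered by no read dropped: positions ",
            paste(positions[!covered], collapse = ", "))
    entries <- entries[, covered, drop = FALSE]
    weights <- weights[, covered, drop = FALSE]
    positions <- positions[covered]
    n <- ncol(entries)
  }
  if (any(rowSums(!is.na(entries)) == 0L))
    stop("every read must cover at least one column")

  structure(list(entries = entries, weights = weights,
                 positions = as.integer(positions),
                 read_ids = as.character(read_ids),
                 spans = .row_spans(entries)),
            class = "fragment_matrix")
}

.row_spans <- function(entries) {
  t(vapply(seq_len(nrow(entries)), function(i) {
    jj <- which(!is.na(entries[i, ]))
    c(first = jj[1L], last = jj[length(jj)])
  }, integer(2)))
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat(sprintf("fragment_matrix: %d reads x %d SNP columns, positions %d..%d\n",
              nrow(x$entries), ncol(x$entries),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' @export
dim.fragment_matrix <- function(x) dim(x$entries)

#' Restrict a fragment matrix to a subset of reads and/or columns
#'
#' Used by the divide-et-impera decomposition; columns left uncovered by
#' the kept reads are dropped silently (they belong to other sub-problems).
#'
#' @param M a [fragment_matrix()].
#' @param rows,cols index vectors (defaults keep everything).
#' @return a `fragment_matrix` plus attribute `col_map`, the kept columns'
#'   indices in the parent matrix.
#' @export
subset_fragment_matrix <- function(M, rows = seq_len(nrow(M$entries)),
                                   cols = seq_len(ncol(M$entries))) {
  e <- M$entries[rows, cols, drop = FALSE]
  keep <- colSums(!is.na(e)) > 0L
  cols <- cols[keep]
  out <- suppressMessages(fragment_matrix(
    M$entries[rows, cols, drop = FALSE],
    M$weights[rows, cols, drop = FALSE],
    M$positions[cols],
    M$read_ids[rows]))
  attr(out, "col_map") <- cols
  out
}
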