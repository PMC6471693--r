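#' Extended Hamming distance between two ternary strings
#'
#' Counts the positions where both vectors are defined (0/1) and differ.
#' Missing entries (`NA`) never contribute, so a masked haplotype site can
#' never create a phantom error.
#'
#' @param f,g vectors over \{0, 1, NA\} of equal length (fragment rows or
#'   haplotypes; `NA` stands for both "not covered" and "masked").
#' @return a non-negative integer count.
#' @export
extended_hamming <- function(f, g) {
  if (length(f) != length(g)) stop("length mismatch")
  sum(f != g, na.rm = TRUE)
}

#' Are two fragments in conflict?
#'
#' Two fragments conflict when some position is covered by both with
#' different alleles, i.e. their extended Hamming distance is positive.
#'
#' @inheritParams extended_hamming
#' @return logical scalar.
#' @export
fragments_in_conflict <- function(f, g) extended_hamming(f, g) > 0L

#' Classify a column of the fragment matrix
#'
#' A column is homozygous when its defined values are all 0 or all 1
#' (values in \{0, -\} or \{1, -\}), heterozygous when both alleles occur.
#' A column with no defined value cannot arise: such columns are dropped
#' at construction.
#'
#' @param M a [fragment_matrix()].
#' @param j column index.
#' @return `"homozygous"` or `"heterozygous"`.
#' @export
column_kind <- function(M, j) {
  if (j < 1L || j > ncol(M$entries)) stop("column index out of range")
  v <- M$entries[, j]
  v <- v[!is.na(v)]
  if (any(v == 0L) && any(v == 1L)) "heterozygous" else "homozygous"
}

#' Infer the two haplotypes from a read bipartition
#'
#' For each part k and column j the allele is 1 iff the (weight) mass of
#' 1-alleles is at least the mass of 0-alleles; the ">=" convention makes
#' every tie, including empty columns, resolve to 1 deterministically.
#'
#' @param M a [fragment_matrix()].
#' @param partition integer vector over \{1, 2\}, one label per read.
#' @param weighted use phred weights (default) or plain counts.
#' @return list with `h1`, `h2` (0/1 vectors of length n) and `tally`, the
#'   per-part column sums `n0`, `n1` (2 x n matrices).
#' @export
infer_haplotypes <- function(M, partition, weighted = TRUE) {
  e <- M$entries
  if (length(partition) != nrow(e)) stop("partition length mismatch")
  if (!all(partition %in% c(1L, 2L))) stop("partition labels must be 1 or 2")
  w <- if (weighted) M$weights else (!is.na(e)) * 1
  n <- ncol(e)
  n0 <- matrix(0, 2L, n)
  n1 <- matrix(0, 2L, n)
  is0 <- !is.na(e) & e == 0L
  is1 <- !is.na(e) & e == 1L
  for (k in 1:2) {
    rows <- partition == k
    n0[k, ] <- colSums((w * is0)[rows, , drop = FALSE])
    n1[k, ] <- colSums((w * is1)[rows, , drop = FALSE])
  }
  hap <- (n1 >= n0) * 1L
  list(h1 = hap[1L, ], h2 = hap[2L, ], tally = list(n0 = n0, n1 = n1))
}

#' wMEC cost of a bipartition
#'
#' The number of allele corrections needed to make every read agree with
#' its part's haplotype: the sum over both parts of the extended Hamming
#' distance between each member read and that part's haplotype.  Zero iff
#' the matrix is conflict-free under this bipartition.
#'
#' @param M a [fragment_matrix()].
#' @param partition integer vector over \{1, 2\}.
#' @param h1,h2 haplotype vectors over \{0, 1, NA\} of width n (`NA` =
#'   masked, never counted).
#' @return non-negative integer.
#' @export
wmec_cost <- function(M, partition, h1, h2) {
  e <- M$entries
  if (length(h1) != ncol(e) || length(h2) != ncol(e))
    stop("haplotype width mismatch")
  if (length(partition) != nrow(e)) stop("partition length mismatch")
  hap <- rbind(h1, h2)[partition, , drop = FALSE]
  sum(e != hap, na.rm = TRUE)
}
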