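#' Haplotype error rate (HE)
#'
#' The percentage of SNP alleles assigned differently from the ground
#' truth, counted over both haplotypes.  Because each block is phased
#' independently and a haplotype pair is only defined up to a label swap,
#' the mismatch count is minimized over the two label assignments per
#' block.  Masked (`X`) positions are abstentions, not assignments: they
#' are excluded from numerator and denominator and reported separately so
#' abstention cannot hide errors.
#'
#' @param pred a `hap_assembly` from [assemble()], or a list of blocks
#'   with `positions`, `h1`, `h2` (as from [parse_haplotypes()]).
#' @param truth list with `h1`, `h2`, `positions` (unmasked).
#' @return list: `pooled` HE in percent (position-weighted over blocks),
#'   `per_block` HE vector, `masked` masked-allele count, `evaluated`
#'   allele count entering the denominator.
#' @export
haplotype_error_rate <- function(pred, truth) {
  blocks <- if (inherits(pred, "hap_assembly")) pred$blocks else pred
  per_block <- numeric(length(blocks))
  masked_total <- 0L
  eval_total <- 0L
  mism_total <- 0L
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    ti <- match(blk$positions, truth$positions)
    if (anyNA(ti))
      stop("block ", b, " has positions absent from the truth")
    t1 <- truth$h1[ti]; t2 <- truth$h2[ti]
    masked <- sum(is.na(blk$h1)) + sum(is.na(blk$h2))
    evaluated <- 2L * length(ti) - masked
    mm_id <- sum(blk$h1 != t1, na.rm = TRUE) + sum(blk$h2 != t2, na.rm = TRUE)
    mm_sw <- sum(blk$h1 != t2, na.rm = TRUE) + sum(blk$h2 != t1, na.rm = TRUE)
    mm <- min(mm_id, mm_sw)
    per_block[b] <- if (evaluated > 0L) 100 * mm / evaluated else 0
    masked_total <- masked_total + masked
    eval_total <- eval_total + evaluated
    mism_total <- mism_total + mm
  }
  list(pooled = if (eval_total > 0L) 100 * mism_total / eval_total else 0,
       per_block = per_block, masked = masked_total, evaluated = eval_total)
}

#' Agreement between two block-structured solutions
#'
#' The percentage of (block, haplotype, position) allele triples on which
#' the two solutions agree, with the label assignment chosen per block to
#' maximize agreement.  Positions are intersected per block; a pair of
#' triples with any masked member counts as a disagreement unless both
#' are masked.
#'
#' @param a,b `hap_assembly` objects or block lists with matching block
#'   structure (paired in order).
#' @return agreement in percent.
#' @export
block_agreement <- function(a, b) {
  ba <- if (inherits(a, "hap_assembly")) a$blocks else a
  bb <- if (inherits(b, "hap_assembly")) b$blocks else b
  if (length(ba) != length(bb)) stop("block count mismatch")
  agree <- 0L
  total <- 0L
  eqv <- function(x, y) sum((is.na(x) & is.na(y)) |
                              (!is.na(x) & !is.na(y) & x == y))
  for (k in seq_along(ba)) {
    common <- intersect(ba[[k]]$positions, bb[[k]]$positions)
    if (length(common) == 0L) stop("block ", k, " shares no positions")
    ia <- match(common, ba[[k]]$positions)
    ib <- match(common, bb[[k]]$positions)
    a1 <- ba[[k]]$h1[ia]; a2 <- ba[[k]]$h2[ia]
    b1 <- bb[[k]]$h1[ib]; b2 <- bb[[k]]$h2[ib]
    agree <- agree + max(eqv(a1, b1) + eqv(a2, b2),
                         eqv(a1, b2) + eqv(a2, b1))
    total <- total + 2L * length(common)
  }
  100 * agree / total
}

#' Average best fitness (ABF) curve
#'
#' Per-iteration mean of the best individual's fitness over a set of GA
#' runs; shorter runs are right-padded with their final value (their best
#' no longer changes after termination).  Non-increasing whenever every
#' input curve is (elitism).
#'
#' @param stats_list list of `ga_stats` (or of numeric curves).
#' @return numeric vector of per-iteration means.
#' @export
abf_curve <- function(stats_list) {
  if (length(stats_list) == 0L) stop("no GA runs supplied")
  curves <- lapply(stats_list, function(s)
    if (inherits(s, "ga_stats")) s$best_fitness_per_iteration else s)
  len <- max(lengths(curves))
  padded <- vapply(curves, function(cv)
    c(cv, rep(cv[length(cv)], len - length(cv))), numeric(len))
  rowMeans(matrix(padded, nrow = len))
}
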