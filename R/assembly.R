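#' Detect haplotype blocks
#'
#' A block is a maximal set of SNP columns connected by read co-coverage:
#' two columns belong to the same block iff some chain of reads links
#' them.  Computed as the connected components of the bipartite
#' read-column coverage graph; blocks are ordered by leftmost column.
#' Columns in different blocks carry no phase information relative to
#' each other.
#'
#' @param M a [fragment_matrix()].
#' @return list of blocks, each a list with `columns` (column indices),
#'   `reads` (row indices of reads covering the block) and
#'   `mean_coverage` (average reads per column).
#' @export
detect_blocks <- function(M) {
  e <- M$entries
  m <- nrow(e); n <- ncol(e)
  # union-find over columns; each read welds together all columns it covers
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  cov <- !is.na(e)
  for (i in seq_len(m)) {
    jj <- which(cov[i, ])
    if (length(jj) > 1L) {
      r <- find(jj[1L])
      for (j in jj[-1L]) parent[find(j)] <- r
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ids <- unique(comp)                      # first occurrence = leftmost column
  lapply(ids, function(id) {
    columns <- which(comp == id)
    reads <- which(rowSums(cov[, columns, drop = FALSE]) > 0L)
    list(columns = columns, reads = reads,
         mean_coverage = sum(cov[reads, columns]) / length(columns))
  })
}

#' Sub-problem chunk size for a block
#'
#' gamma is the block's mean coverage, rounded half-up and floored at 2:
#' with chunks of roughly one coverage-worth of position-sorted reads,
#' consecutive sub-problems share overlapping columns, which is what makes
#' the merge step well-posed.
#'
#' @param block one element of [detect_blocks()].
#' @return integer gamma >= 2.
#' @export
compute_gamma <- function(block) {
  max(2L, as.integer(floor(block$mean_coverage + 0.5)))
}

#' Split a block's reads into sub-problems of gamma reads
#'
#' Reads are sorted by (leftmost column, rightmost column, row index) and
#' cut into Pi = floor(m / gamma) consecutive chunks.  A remainder smaller
#' than gamma / 2 is appended to the last chunk (so the last sub-matrix
#' simply has more reads); a larger remainder forms its own smaller final
#' chunk.
#'
#' @param M a [fragment_matrix()] scoped to the block.
#' @param gamma chunk size.
#' @return list of integer vectors of row indices into `M`; their union is
#'   all rows, pairwise disjoint, in genomic order.
#' @export
split_block <- function(M, gamma) {
  m <- nrow(M$entries)
  ord <- order(M$spans[, 1L], M$spans[, 2L], seq_len(m))
  if (m <= gamma) return(list(ord))
  n_full <- m %/% gamma
  rem <- m %% gamma
  sizes <- rep(gamma, n_full)
  if (rem > 0L) {
    if (rem < gamma / 2) sizes[n_full] <- gamma + rem
    else sizes <- c(sizes, rem)
  }
  split(ord, rep(seq_along(sizes), sizes))
}

#' Solve one sub-problem with the GA
#'
#' Restricts the block matrix to the chunk's reads and their covered
#' columns (during the optimization every phased position is treated as
#' heterozygous), runs the GA, and returns the sub-haplotypes together
#' with the per-part column coverage needed by the merge step.
#'
#' @param M block-scoped [fragment_matrix()].
#' @param rows chunk row indices into `M`.
#' @param config a [ga_config()]; its `seed` is used as-is.
#' @return list: `rows`, `cols` (block column indices covered), `h1`,
#'   `h2`, `partition` (per chunk read), `cov` (2 x length(cols) read
#'   counts per part), `cost`, `stats`.
#' @export
solve_subproblem <- function(M, rows, config = ga_config()) {
  sub <- subset_fragment_matrix(M, rows = rows)
  res <- run_ga(sub, config)
  covered <- !is.na(sub$entries)
  cov <- rbind(colSums(covered[res$partition == 1L, , drop = FALSE]),
               colSums(covered[res$partition == 2L, , drop = FALSE]))
  # a column no read of part k covers carries no evidence for that
  # sub-haplotype: mark it NA so it cannot vote during the merge
  h1 <- res$h1; h1[cov[1L, ] == 0L] <- NA_integer_
  h2 <- res$h2; h2[cov[2L, ] == 0L] <- NA_integer_
  list(rows = rows, cols = attr(sub, "col_map"),
       h1 = h1, h2 = h2, partition = res$partition,
       cov = cov, cost = res$cost, stats = res$stats)
}

#' Orient and merge consecutive sub-solutions
#'
#' Sub-haplotype pairs are only defined up to a label swap, so each
#' sub-solution is pasted onto the growing pair either as-is or swapped,
#' whichever minimizes the summed disagreement on the columns already
#' merged, with every column's vote weighted by the read coverage behind
#' it (ties and empty overlaps keep the identity; an empty overlap is a
#' genuine phase ambiguity and is flagged with a warning).
#' Where two sub-solutions overlap, each haplotype keeps the allele from
#' the sub-partition covering the column with more reads, earlier
#' sub-problem on ties.
#'
#' @param subsols list from [solve_subproblem()], in sub-problem order.
#' @param n_cols width of the block.
#' @return list: `h1`, `h2` (may contain `NA` where the GA saw no read —
#'   resolved downstream), `swapped` logical per sub-solution.
#' @export
orient_and_merge <- function(subsols, n_cols) {
  h1 <- rep(NA_integer_, n_cols)
  h2 <- rep(NA_integer_, n_cols)
  support <- matrix(0, 2L, n_cols)
  swapped <- logical(length(subsols))
  for (s in seq_along(subsols)) {
    ss <- subsols[[s]]
    sh1 <- ss$h1; sh2 <- ss$h2; scov <- ss$cov
    ov <- !is.na(h1[ss$cols]) | !is.na(h2[ss$cols])
    if (s > 1L && !any(ov))
      warning("empty overlap between consecutive sub-problems; ",
              "phase between them is ambiguous")
    if (any(ov)) {
      jo <- ss$cols[ov]
      # each overlap column votes with the read support behind the weaker
      # of the two estimates being compared, so thinly covered chunk-edge
      # columns cannot outvote well-supported ones
      dd <- function(a, b, w) sum(w * (a != b), na.rm = TRUE)
      d_id <- dd(h1[jo], sh1[ov], pmin(support[1L, jo], scov[1L, ov])) +
        dd(h2[jo], sh2[ov], pmin(support[2L, jo], scov[2L, ov]))
      d_sw <- dd(h1[jo], sh2[ov], pmin(support[1L, jo], scov[2L, ov])) +
        dd(h2[jo], sh1[ov], pmin(support[2L, jo], scov[1L, ov]))
      if (d_sw < d_id) {
        swapped[s] <- TRUE
        tmp <- sh1; sh1 <- sh2; sh2 <- tmp
        scov <- scov[2:1, , drop = FALSE]
      }
    }
    take1 <- scov[1L, ] > support[1L, ss$cols]
    take2 <- scov[2L, ] > support[2L, ss$cols]
    h1[ss$cols[take1]] <- sh1[take1]
    h2[ss$cols[take2]] <- sh2[take2]
    support[1L, ss$cols[take1]] <- scov[1L, take1]
    support[2L, ss$cols[take2]] <- scov[2L, take2]
  }
  list(h1 = h1, h2 = h2, swapped = swapped)
}

#' Repair switch errors by coordinate descent
#'
#' Greedy block-level refinement of the merged solution under the wMEC
#' objective.  Each sweep first relabels reads to their better-fitting
#' part and re-infers the haplotype pair by weighted column majority
#' until stable, then scores one switch move per junction column j —
#' flip the part label of every read starting at or after j — exactly,
#' by re-inferring haplotypes and recounting corrections.  The most
#' promising switch candidates are themselves refined (relabel +
#' re-infer to convergence) before judging, because a switch anchored
#' at a thin junction only shows its gain once nearby reads are
#' relabeled.  The best strictly improving move is applied and the
#' sweep repeats; the total cost never increases and the procedure
#' terminates at a local optimum of this move set.
#'
#' @param pair list with `h1`, `h2` (starting point; may contain `NA`).
#' @param partition block-wide read bipartition over \{1, 2\}.
#' @param M block-scoped [fragment_matrix()].
#' @param weighted use phred weights for haplotype inference.
#' @return list with polished `h1`, `h2`, `partition` and the number of
#'   switch moves applied (`n_flips`).
#' @export
polish_switches <- function(pair, partition, M, weighted = TRUE) {
  e <- M$entries
  m <- nrow(e); n <- ncol(e)
  first <- M$spans[, 1L]
  if (n < 2L || m < 2L)
    return(list(h1 = pair$h1, h2 = pair$h2, partition = partition,
                n_flips = 0L))
  r0 <- relabel_refine(e, M$weights, partition - 1L, weighted)
  bits <- r0$bits
  base <- r0$cost
  n_flips <- 0L
  for (sweep in 1:50) {
    if (base == 0L) break
    # shortlist junctions by the O(entries) fixed-haplotype screen, then
    # score the shortlist exactly (haplotypes re-inferred per candidate)
    screen <- switch_screen(e, M$weights, bits, weighted)
    cand_j <- order(screen)[seq_len(min(40L, n - 1L))]
    cand_j <- cand_j[is.finite(screen[cand_j])]
    flipmat <- outer(cand_j, first, `<=`)
    pop <- matrix(bits, length(cand_j), m, byrow = TRUE)
    pop[flipmat] <- 1L - pop[flipmat]
    costs <- wmec_fitness_batch(e, M$weights, pop, weighted)
    improved <- FALSE
    for (k in order(costs)[seq_len(min(25L, length(costs)))]) {
      rk <- relabel_refine(e, M$weights, pop[k, ], weighted)
      if (rk$cost < base) {
        bits <- rk$bits
        base <- rk$cost
        n_flips <- n_flips + 1L
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  partition <- bits + 1L
  h <- infer_haplotypes(M, partition, weighted = weighted)
  list(h1 = h$h1, h2 = h$h2, partition = partition, n_flips = n_flips)
}

#' Resolve columns with no allele contrast
#'
#' The GA assumes every phased position heterozygous.  A column whose
#' defined matrix values are all identical carries no phase information
#' and its heterozygosity is unobservable (in a fragment matrix over
#' heterozygous SNP sites this is a coverage artifact: all covering
#' reads happened to sample one chromosome copy).  Following the
#' majority rule, the observed value is assigned to the sub-haplotype
#' whose part covers the column with more reads; the other haplotype is
#' masked, since every covering read carries the same allele and lends
#' it no independent support.  With no majority (tied coverage) both
#' haplotypes abstain.
#'
#' @param pair list with `h1`, `h2`.
#' @param M block-scoped [fragment_matrix()].
#' @param partition block-wide read bipartition over \{1, 2\}.
#' @return corrected pair.
#' @export
correct_homozygous_sites <- function(pair, M, partition) {
  e <- M$entries
  cov1 <- colSums(!is.na(e[partition == 1L, , drop = FALSE]))
  cov2 <- colSums(!is.na(e[partition == 2L, , drop = FALSE]))
  for (j in seq_len(ncol(e))) {
    v <- e[, j][!is.na(e[, j])]
    if (all(v == v[1L])) {
      if (cov1[j] > cov2[j]) {
        pair$h1[j] <- v[1L]
        pair$h2[j] <- NA_integer_
      } else if (cov2[j] > cov1[j]) {
        pair$h2[j] <- v[1L]
        pair$h1[j] <- NA_integer_
      } else {
        # no majority: the assignment is genuinely ambiguous, abstain
        pair$h1[j] <- NA_integer_
        pair$h2[j] <- NA_integer_
      }
    }
  }
  pair
}

#' Mask ambiguous positions
#'
#' An ambiguous position is one covered only by the reads of one part:
#' the data carry no evidence for the other haplotype there, so that
#' haplotype's allele is replaced by the ambiguity symbol (`NA`
#' internally, rendered `X`).  Applied after homozygous correction, this
#' turns the copied allele at a one-sidedly covered column into an
#' abstention instead of a fabricated assignment.
#'
#' @param pair list with `h1`, `h2`.
#' @param partition block-wide read bipartition over \{1, 2\}.
#' @param M block-scoped [fragment_matrix()].
#' @return masked pair.
#' @export
mask_ambiguous <- function(pair, partition, M) {
  covered <- !is.na(M$entries)
  cov1 <- colSums(covered[partition == 1L, , drop = FALSE])
  cov2 <- colSums(covered[partition == 2L, , drop = FALSE])
  pair$h1[cov1 == 0L] <- NA_integer_
  pair$h2[cov2 == 0L] <- NA_integer_
  pair
}

#' Assemble the two haplotypes from a fragment matrix
#'
#' The full divide-et-impera pipeline: detect haplotype blocks, and for
#' each block set gamma to its mean coverage, split the position-sorted
#' reads into Pi = floor(m / gamma) sub-problems, solve each with an
#' independent GA instance (dispatched to a worker pool; results are
#' merged in sub-problem order, so the output is identical for any worker
#' count given the same seed), orient and merge the sub-haplotypes,
#' correct homozygous sites, and mask ambiguous positions.
#'
#' @param M a [fragment_matrix()].
#' @param config a [ga_config()]; `config$seed` is the master seed from
#'   which every sub-problem's RNG stream is derived (a random master is
#'   drawn if `NULL`).
#' @param workers size of the worker pool (forked processes; 1 = serial).
#' @return object of class `hap_assembly`: per block `positions`,
#'   `columns`, `h1`, `h2` (0/1/`NA`, `NA` = masked `X`), `partition`
#'   (named by read id), `cost`, `gamma`, `n_subproblems`, `stats` (list
#'   of per-sub-problem `ga_stats`); plus `total_cost` and `config`.
#' @export
assemble <- function(M, config = ga_config(), workers = 1L) {
  master <- config$seed %||% sample.int(2147483646L, 1L)
  blocks <- detect_blocks(M)
  apply_fun <- if (workers > 1L && .Platform$OS.type == "unix") {
    function(xs, f) parallel::mclapply(xs, f, mc.cores = workers)
  } else {
    function(xs, f) lapply(xs, f)
  }

  out_blocks <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    Mb <- subset_fragment_matrix(M, rows = blk$reads, cols = blk$columns)
    gamma <- compute_gamma(blk)
    chunks <- split_block(Mb, gamma)
    subsols <- apply_fun(seq_along(chunks), function(s) {
      cfg <- config
      cfg$seed <- derive_seed(master, b, s)
      solve_subproblem(Mb, chunks[[s]], cfg)
    })
    if (any(vapply(subsols, function(x) !is.list(x) || is.null(x$h1),
                   logical(1))))
      stop("sub-problem worker failed in block ", b)

    pair <- orient_and_merge(subsols, ncol(Mb$entries))

    partition <- integer(nrow(Mb$entries))
    for (s in seq_along(subsols)) {
      p <- subsols[[s]]$partition
      if (pair$swapped[s]) p <- 3L - p
      partition[subsols[[s]]$rows] <- p
    }

    polished <- polish_switches(pair, partition, Mb)
    pair$h1 <- polished$h1
    pair$h2 <- polished$h2
    partition <- polished$partition

    pair <- correct_homozygous_sites(pair, Mb, partition)
    pair <- mask_ambiguous(pair, partition, Mb)
    # unmerged columns (no sub-problem claimed them) cannot remain: every
    # block column is covered by some read, hence by some chunk
    cost <- wmec_cost(Mb, partition, pair$h1, pair$h2)
    names(partition) <- Mb$read_ids
    out_blocks[[b]] <- list(positions = Mb$positions,
                            columns = blk$columns,
                            h1 = pair$h1, h2 = pair$h2,
                            partition = partition, cost = cost,
                            gamma = gamma,
                            n_subproblems = length(chunks),
                            stats = lapply(subsols, `[[`, "stats"))
  }
  structure(list(blocks = out_blocks,
                 total_cost = sum(vapply(out_blocks, `[[`, numeric(1),
                                         "cost")),
                 seed = master, config = config),
            class = "hap_assembly")
}

#' @export
print.hap_assembly <- function(x, ...) {
  cat(sprintf("hap_assembly: %d block(s), total wMEC cost %d\n",
              length(x$blocks), as.integer(x$total_cost)))
  for (b in seq_along(x$blocks)) {
    blk <- x$blocks[[b]]
    cat(sprintf(
      "  block %d: %d SNPs (%d..%d), %d reads, gamma=%d, Pi=%d, cost=%d, masked=%d\n",
      b, length(blk$positions), min(blk$positions), max(blk$positions),
      length(blk$partition), blk$gamma, blk$n_subproblems,
      as.integer(blk$cost), sum(is.na(blk$h1)) + sum(is.na(blk$h2))))
  }
  invisible(x)
}
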