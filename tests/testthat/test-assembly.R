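test_that("block detection finds co-coverage components", {
  M <- fm(list(c(0L, 1L, NA, NA),
               c(NA, 1L, 0L, NA),
               c(NA, NA, NA, 1L)))
  blocks <- detect_blocks(M)
  expect_length(blocks, 2L)
  expect_identical(blocks[[1L]]$columns, 1:3)
  expect_identical(blocks[[2L]]$columns, 4L)
  expect_identical(blocks[[1L]]$reads, 1:2)

  # one read covering everything gives a single block
  expect_length(detect_blocks(fm(list(c(0L, 1L, 0L)))), 1L)

  # a chain of pairwise-overlapping reads is one block
  chain <- fm(list(c(0L, 1L, NA, NA),
                   c(NA, 1L, 0L, NA),
                   c(NA, NA, 0L, 1L)))
  expect_length(detect_blocks(chain), 1L)
  expect_identical(detect_blocks(chain)[[1L]]$columns, 1:4)
})

test_that("gamma is the rounded mean coverage floored at 2", {
  M <- fm(list(c(0L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 0L), c(1L, 0L, 1L)))
  b <- detect_blocks(M)[[1L]]
  expect_equal(b$mean_coverage, 4)
  expect_identical(compute_gamma(b), 4L)

  # coverages 3 and 4 -> mean 3.5 -> round-half-up 4
  M2 <- fm(list(c(0L, 1L), c(1L, 0L), c(0L, 1L), c(NA, 0L)))
  expect_identical(compute_gamma(detect_blocks(M2)[[1L]]), 4L)

  # single-read block floors at 2
  expect_identical(compute_gamma(detect_blocks(fm(list(c(0L, 1L))))[[1L]]), 2L)
})

test_that("block splitting preserves reads and respects Pi = floor(m/gamma)", {
  set.seed(14)
  mk <- function(m, n = 40) {
    entries <- matrix(NA_integer_, m, n)
    for (i in seq_len(m)) {
      a <- sample.int(n - 3L, 1L)
      entries[i, a:(a + 3L)] <- sample(c(0L, 1L), 4L, replace = TRUE)
    }
    keep <- colSums(!is.na(entries)) > 0L
    fragment_matrix(entries[, keep, drop = FALSE])
  }
  M100 <- mk(100)
  ch <- split_block(M100, 30L)
  expect_length(ch, 3L)                    # remainder 10 < 15 folds in
  expect_identical(lengths(ch, use.names = FALSE), c(30L, 30L, 40L))
  expect_setequal(unlist(ch), 1:100)

  M90 <- mk(90)
  expect_identical(lengths(split_block(M90, 30L), use.names = FALSE),
                   rep(30L, 3L))

  M7 <- mk(7, n = 12)
  ch7 <- split_block(M7, 3L)
  expect_setequal(unlist(ch7), 1:7)
  expect_identical(sum(lengths(ch7)), 7L)

  # chunks are in genomic order
  firsts <- vapply(ch, function(r) min(M100$spans[r, 1L]), numeric(1))
  expect_true(all(diff(firsts) >= 0))
})

test_that("sub-problem solving recovers planted sub-haplotypes", {
  set.seed(15)
  inst <- random_instance(m = 12, n = 8, error_rate = 0)
  ss <- solve_subproblem(inst$M, rows = 1:12, config = ga_config(seed = 3L))
  expect_identical(ss$cost, 0L)
  keep1 <- !is.na(ss$h1)
  keep2 <- !is.na(ss$h2)
  id_ok <- all(ss$h1[keep1] == inst$h1[ss$cols][keep1]) &&
    all(ss$h2[keep2] == inst$h2[ss$cols][keep2])
  sw_ok <- all(ss$h1[keep1] == inst$h2[ss$cols][keep1]) &&
    all(ss$h2[keep2] == inst$h1[ss$cols][keep2])
  expect_true(id_ok || sw_ok)

  # single-read sub-problem: that read becomes one sub-haplotype, the
  # other one carries no evidence anywhere
  one <- solve_subproblem(inst$M, rows = 1L, config = ga_config(seed = 4L))
  covered <- !is.na(inst$M$entries[1L, one$cols])
  hs <- if (all(is.na(one$h2))) one$h1 else one$h2
  expect_identical(hs[covered], inst$M$entries[1L, one$cols][covered])
})

test_that("merge orientation follows the overlap agreement", {
  # identical overlap -> identity pairing, plain concatenation
  s1 <- list(rows = 1:2, cols = 1:3, h1 = c(0L, 1L, 0L), h2 = c(1L, 0L, 1L),
             partition = c(1L, 2L), cov = rbind(rep(2L, 3), rep(2L, 3)))
  s2 <- list(rows = 3:4, cols = 3:5, h1 = c(0L, 1L, 1L), h2 = c(1L, 0L, 0L),
             partition = c(1L, 2L), cov = rbind(rep(1L, 3), rep(1L, 3)))
  mg <- orient_and_merge(list(s1, s2), 5L)
  expect_false(any(mg$swapped))
  expect_identical(mg$h1, c(0L, 1L, 0L, 1L, 1L))
  expect_identical(mg$h2, c(1L, 0L, 1L, 0L, 0L))

  # second sub-solution equal to the swap of the first on the overlap
  s2sw <- list(rows = 3:4, cols = 3:5, h1 = c(1L, 0L, 0L),
               h2 = c(0L, 1L, 1L), partition = c(1L, 2L),
               cov = rbind(rep(1L, 3), rep(1L, 3)))
  mg2 <- orient_and_merge(list(s1, s2sw), 5L)
  expect_identical(mg2$swapped, c(FALSE, TRUE))
  expect_identical(mg2$h1, c(0L, 1L, 0L, 1L, 1L))

  # an empty overlap warns about phase ambiguity
  s3 <- list(rows = 5L, cols = 5L, h1 = 1L, h2 = 0L, partition = 1L,
             cov = rbind(1L, 0L))
  expect_warning(orient_and_merge(list(s1, s3), 5L), "ambiguous")
})

test_that("switch polish never increases cost and repairs planted switches", {
  set.seed(16)
  for (rep in 1:10) {
    inst <- random_instance(m = 14, n = 10, error_rate = 0.15)
    p <- sample(1:2, 14, replace = TRUE)
    h <- infer_haplotypes(inst$M, p)
    before <- wmec_cost(inst$M, p, h$h1, h$h2)
    pol <- polish_switches(list(h1 = h$h1, h2 = h$h2), p, inst$M)
    expect_lte(wmec_cost(inst$M, pol$partition, pol$h1, pol$h2), before)
  }

  # a deliberate phase switch at the middle of an error-free instance
  set.seed(17)
  inst <- random_instance(m = 20, n = 12, error_rate = 0)
  p_sw <- inst$partition
  right <- inst$M$spans[, 1L] > 6L
  p_sw[right] <- 3L - p_sw[right]
  h_sw <- infer_haplotypes(inst$M, p_sw)
  pol <- polish_switches(list(h1 = h_sw$h1, h2 = h_sw$h2), p_sw, inst$M)
  expect_identical(wmec_cost(inst$M, pol$partition, pol$h1, pol$h2), 0L)
})

test_that("no-contrast columns go to the majority-covered haplotype", {
  M <- fm(list(c(1L, 0L, 0L), c(1L, NA, 1L), c(1L, 0L, NA)))
  pair <- correct_homozygous_sites(list(h1 = c(1L, 0L, 0L),
                                        h2 = c(0L, 1L, 1L)), M,
                                   partition = c(1L, 1L, 2L))
  expect_identical(pair$h1[1L], 1L)   # column {1,1,1}: part 1 covers 2 of 3
  expect_identical(pair$h2[1L], NA_integer_)
  expect_identical(pair$h1[2L], NA_integer_)  # column {0,-,0}: 1-1 tie,
  expect_identical(pair$h2[2L], NA_integer_)  # no majority, both abstain
  expect_identical(pair$h2[3L], 1L)   # heterozygous column untouched
  expect_identical(pair$h1[3L], 0L)

  # after correction no column is called differently on both haplotypes
  # where both are defined (property over random instances)
  set.seed(24)
  for (rep in 1:10) {
    inst <- random_instance(m = 10, n = 8, error_rate = 0.2)
    p <- sample(1:2, 10, replace = TRUE)
    h <- infer_haplotypes(inst$M, p)
    pair <- correct_homozygous_sites(list(h1 = h$h1, h2 = h$h2), inst$M, p)
    for (j in seq_len(8)) {
      v <- inst$M$entries[, j][!is.na(inst$M$entries[, j])]
      if (all(v == v[1L])) {
        both <- c(pair$h1[j], pair$h2[j])
        expect_true(all(both[!is.na(both)] == v[1L]))
        expect_gte(sum(is.na(both)), 1L)
      }
    }
  }
})

test_that("ambiguous positions are masked per part coverage", {
  M <- fm(list(c(0L, 0L), c(1L, NA), c(0L, 1L)))
  # column 2 is covered by reads 1 and 3 only
  pair <- mask_ambiguous(list(h1 = c(0L, 0L), h2 = c(1L, 1L)),
                         partition = c(1L, 2L, 1L), M)
  expect_identical(pair$h2[2L], NA_integer_)   # no part-2 read covers col 2
  expect_identical(pair$h1[2L], 0L)
  expect_identical(pair$h1[1L], 0L)            # both parts cover col 1

  # all reads in one part: the other haplotype is fully masked on
  # heterozygous columns
  pair2 <- mask_ambiguous(list(h1 = c(0L, 0L), h2 = c(1L, 1L)),
                          partition = c(1L, 1L, 1L), M)
  expect_true(all(is.na(pair2$h2)))
})

test_that("assembly is deterministic, worker-invariant and zero on clean data", {
  set.seed(20)
  scfg <- sim_config(n_snps = 40, f_snps = 100, cov = 8,
                     profile = "roche454", error_rate = 0, seed = 5L)
  truth <- generate_truth(scfg)
  M <- simulate_reads(truth, scfg)
  cfg <- ga_config(seed = 77L)
  r1 <- assemble(M, cfg, workers = 1L)
  r4 <- assemble(M, cfg, workers = 4L)
  expect_identical(r1$blocks, r4$blocks)
  expect_identical(r1$total_cost, 0)
  he <- haplotype_error_rate(r1, truth)
  expect_identical(he$pooled, 0)
  expect_identical(length(r1$blocks), length(detect_blocks(M)))
})

test_that("blocks are phased independently", {
  set.seed(22)
  # two disjoint groups of columns joined in one matrix
  e <- matrix(NA_integer_, 8, 8)
  for (i in 1:4) e[i, 1:4] <- c(0L, 1L, 0L, 1L)
  for (i in 5:8) e[i, 5:8] <- c(1L, 1L, 0L, 0L)
  e[2, 1:4] <- 1L - e[2, 1:4]
  e[6, 5:8] <- 1L - e[6, 5:8]
  M <- fragment_matrix(e)
  res <- assemble(M, ga_config(seed = 13L))
  expect_length(res$blocks, 2L)
  expect_identical(res$total_cost, 0)
  # permuting reads across blocks leaves each block's haplotypes unchanged
  perm <- c(5:8, 1:4)
  res_p <- assemble(fragment_matrix(e[perm, ]), ga_config(seed = 13L))
  expect_identical(res_p$blocks[[1L]]$h1, res$blocks[[1L]]$h1)
  expect_identical(res_p$blocks[[2L]]$h2, res$blocks[[2L]]$h2)
})
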