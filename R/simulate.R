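#' Simulation configuration
#'
#' The generator plants a fully heterozygous haplotype pair on a genome of
#' length `f_snps * n_snps` and samples single-end reads from it.  Two
#' built-in profiles mirror the sequencing technologies the assembler
#' targets: `"roche454"` (600 bp reads, low error, per-base error rate
#' 0.01) and `"pacbio"` (5000 bp reads, high error, 0.13).  The read count
#' follows `cov * len(genome) / len(read)`.
#'
#' @param n_snps number of heterozygous SNPs (>= 2).
#' @param f_snps mean distance between SNPs in bp (1 SNP per `f_snps` bp).
#' @param cov target mean coverage.
#' @param read_len read length in bp; set by `profile` when omitted.
#' @param error_rate per-covered-SNP allele flip probability; set by
#'   `profile` when omitted.
#' @param profile `"roche454"`, `"pacbio"`, or `NULL` for fully manual.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 500L, f_snps = 100L, cov = 30L,
                       read_len = NULL, error_rate = NULL,
                       profile = c("roche454", "pacbio"), seed = 1L) {
  if (!is.null(profile)) {
    profile <- match.arg(profile)
    defaults <- switch(profile,
                       roche454 = list(read_len = 600L, error_rate = 0.01),
                       pacbio = list(read_len = 5000L, error_rate = 0.13))
    read_len <- read_len %||% defaults$read_len
    error_rate <- error_rate %||% defaults$error_rate
  }
  stopifnot(n_snps >= 2L, cov >= 1, f_snps >= 1L,
            read_len >= 1L, error_rate >= 0, error_rate < 0.5)
  if (read_len < f_snps)
    warning("read_len < f_snps: reads will rarely span 2 SNPs")
  structure(list(n_snps = as.integer(n_snps), f_snps = as.integer(f_snps),
                 cov = cov, read_len = as.integer(read_len),
                 error_rate = error_rate,
                 profile = if (is.null(profile)) "custom" else profile,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Plant a ground-truth haplotype pair
#'
#' SNP positions are drawn uniformly without replacement from the genome
#' `1..f_snps * n_snps` (mean spacing f_snps); every site is heterozygous:
#' h1 is Bernoulli(0.5) per site and h2 its complement.
#'
#' @param config a [sim_config()].
#' @return list with `positions`, `h1`, `h2`, `genome_len`.
#' @export
generate_truth <- function(config) {
  g <- config$f_snps * config$n_snps
  positions <- sort(sample.int(g, config$n_snps))
  h1 <- as.integer(stats::runif(config$n_snps) < 0.5)
  list(positions = positions, h1 = h1, h2 = 1L - h1, genome_len = g)
}

#' Number of reads for a target coverage
#'
#' `ceiling(cov * len(genome) / len(read))` with
#' `len(genome) = f_snps * n_snps`.
#'
#' @param config a [sim_config()].
#' @return integer read count.
#' @export
num_reads <- function(config) {
  as.integer(ceiling(config$cov * (config$f_snps * config$n_snps) /
                       config$read_len))
}

#' Sample reads over a planted haplotype pair
#'
#' Each read starts uniformly on the genome, has length `read_len`, copies
#' the covered SNP alleles from h1 or h2 with probability 1/2 each, and
#' flips each covered allele independently with `error_rate`.  The phred
#' weight of an entry is `round(-10 log10 e')` where `e'` is the entry's
#' error rate jittered by +/-20% (floored at 1e-6, so error-free runs get
#' weight 60).  Reads covering no SNP are discarded and resampled until
#' the target count is reached.
#'
#' @param truth from [generate_truth()].
#' @param config a [sim_config()].
#' @return a [fragment_matrix()]; attribute `provenance` records the
#'   source haplotype and flipped sites per read.
#' @export
simulate_reads <- function(truth, config) {
  n_target <- num_reads(config)
  g <- truth$genome_len
  max_start <- max(1L, g - config$read_len + 1L)
  rows <- vector("list", n_target)
  src <- integer(n_target)
  flips <- 0L
  i <- 0L
  attempts <- 0L
  while (i < n_target) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_target)
      stop("could not sample reads covering SNPs; check config")
    start <- sample.int(max_start, 1L)
    lo <- findInterval(start - 1L, truth$positions) + 1L
    hi <- findInterval(start + config$read_len - 1L, truth$positions)
    if (hi < lo) next
    jj <- lo:hi
    i <- i + 1L
    hap <- if (stats::runif(1) < 0.5) 1L else 2L
    alleles <- if (hap == 1L) truth$h1[jj] else truth$h2[jj]
    err <- stats::runif(length(jj)) < config$error_rate
    alleles[err] <- 1L - alleles[err]
    flips <- flips + sum(err)
    e_real <- pmax(config$error_rate * stats::runif(length(jj), 0.8, 1.2),
                   1e-6)
    rows[[i]] <- list(cols = jj, alleles = alleles,
                      phred = round(-10 * log10(e_real)))
    src[i] <- hap
  }
  entries <- matrix(NA_integer_, n_target, config$n_snps)
  weights <- matrix(0, n_target, config$n_snps)
  for (r in seq_len(n_target)) {
    entries[r, rows[[r]]$cols] <- rows[[r]]$alleles
    weights[r, rows[[r]]$cols] <- rows[[r]]$phred
  }
  M <- fragment_matrix(entries, weights, truth$positions)
  attr(M, "provenance") <- list(source_hap = src, n_flips = flips,
                                n_entries = sum(!is.na(entries)))
  M
}

#' Generate a full simulated instance on disk
#'
#' Seeds the RNG from `config$seed`, plants the truth, samples the reads,
#' and writes `<prefix>.wif`, `<prefix>.truth` and `<prefix>.json`
#' (provenance: all config fields plus realized counts).  Identical seeds
#' give identical files.
#'
#' @param config a [sim_config()].
#' @param prefix output path prefix.
#' @return invisibly, list with `M`, `truth` and the three paths.
#' @export
simulate_instance <- function(config, prefix) {
  set.seed(config$seed)
  truth <- generate_truth(config)
  M <- simulate_reads(truth, config)
  paths <- paste0(prefix, c(".wif", ".truth", ".json"))
  write_wif(M, paths[1L])
  write_truth(truth, paths[2L])
  prov <- c(unclass(config),
            list(n_reads = nrow(M$entries),
                 n_entries = attr(M, "provenance")$n_entries,
                 n_flips = attr(M, "provenance")$n_flips,
                 note = paste("synthetic planted-haplotype instance;",
                              "error rates are platform stand-ins")))
  jsonlite::write_json(prov, paths[3L], auto_unbox = TRUE, digits = NA)
  invisible(list(M = M, truth = truth, wif = paths[1L], truth_file = paths[2L],
                 provenance = paths[3L]))
}
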