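#' Genetic-algorithm configuration
#'
#' Defaults follow the setting selected by a grid search over population
#' size, crossover and mutation rates on long-read instances: |P| = 100,
#' c_r = 0.9, m_r = 0.05, tournament size 0.1 |P| (floored at 2),
#' T = 100 iterations, stall limit ceiling(0.25 T), and a burst mutation
#' that fires after 2 non-improving iterations.
#'
#' @param population_size number of individuals |P|.
#' @param crossover_rate probability c_r that a parent pair recombines.
#' @param mutation_rate per-bit flip probability m_r.
#' @param tournament_size tournament size; default `ceiling(0.1 * |P|)`,
#'   never below 2.
#' @param max_iterations iteration budget T.
#' @param stall_limit stop after this many non-improving iterations;
#'   default `ceiling(0.25 * max_iterations)`.
#' @param burst_mutation_stall non-improving iterations before the burst
#'   (consecutive-run) mutation is applied in addition to the classic one.
#' @param seed integer seed for this GA run (optional; callers that manage
#'   their own RNG streams may leave it `NULL`).
#' @param weighted use phred weights in haplotype inference.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, crossover_rate = 0.9,
                      mutation_rate = 0.05, tournament_size = NULL,
                      max_iterations = 100L, stall_limit = NULL,
                      burst_mutation_stall = 2L, seed = NULL,
                      weighted = TRUE) {
  if (is.null(tournament_size))
    tournament_size <- max(2L, as.integer(ceiling(0.1 * population_size)))
  if (is.null(stall_limit))
    stall_limit <- as.integer(ceiling(0.25 * max_iterations))
  stopifnot(population_size >= 2L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            tournament_size >= 2L, tournament_size <= population_size,
            max_iterations >= 1L, stall_limit >= 1L,
            burst_mutation_stall >= 1L)
  structure(list(population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 max_iterations = as.integer(max_iterations),
                 stall_limit = as.integer(stall_limit),
                 burst_mutation_stall = as.integer(burst_mutation_stall),
                 seed = seed, weighted = isTRUE(weighted)),
            class = "ga_config")
}

#' Decode an individual into a read bipartition
#'
#' Bit i = 0 places read i in part 1 (M1), bit 1 in part 2 (M2); the map
#' is a bijection for a fixed read order.
#'
#' @param bits binary vector.
#' @return integer vector over \{1, 2\}.
#' @export
decode_individual <- function(bits) {
  if (!all(bits %in% c(0L, 1L))) stop("individual bits must be 0/1")
  as.integer(bits) + 1L
}

#' Fitness of an individual on a sub-matrix
#'
#' Decodes the bipartition, infers the haplotype pair by (weighted)
#' majority, and returns the wMEC correction count.
#'
#' @param bits binary vector, one bit per read of `M`.
#' @param M a [fragment_matrix()].
#' @param weighted use phred weights for inference.
#' @return non-negative integer fitness.
#' @export
evaluate_individual <- function(bits, M, weighted = TRUE) {
  p <- decode_individual(bits)
  h <- infer_haplotypes(M, p, weighted = weighted)
  wmec_cost(M, p, h$h1, h$h2)
}

#' Tournament selection
#'
#' Samples `k` distinct individuals uniformly and returns the index of the
#' fittest (minimum wMEC cost); ties go to the first sampled.
#'
#' @param fitness vector of evaluated fitnesses.
#' @param k tournament size, `2 <= k <= length(fitness)`.
#' @return the selected index.
#' @export
tournament_select <- function(fitness, k) {
  np <- length(fitness)
  if (np == 0L) stop("empty population")
  if (k > np) stop("tournament larger than population")
  idx <- sample.int(np, k)
  idx[which.min(fitness[idx])]
}

#' Single-point crossover
#'
#' With probability `c_r` a cut is drawn uniformly from the len-1 internal
#' boundaries and the tails are exchanged; otherwise (and for length-1
#' parents, where no cut exists) the parents are copied unchanged.
#'
#' @param a,b equal-length binary vectors.
#' @param c_r crossover probability.
#' @param cut optional fixed cut in `1:(len-1)` (tail starts at `cut+1`);
#'   mainly for testing.
#' @return list of two offspring.
#' @export
single_point_crossover <- function(a, b, c_r = 0.9, cut = NULL) {
  len <- length(a)
  if (length(b) != len) stop("parent length mismatch")
  if (len < 2L || (is.null(cut) && stats::runif(1) >= c_r))
    return(list(a, b))
  if (is.null(cut)) cut <- sample.int(len - 1L, 1L)
  tail <- (cut + 1L):len
  ca <- a; cb <- b
  ca[tail] <- b[tail]
  cb[tail] <- a[tail]
  list(ca, cb)
}

#' Classic bit-flip mutation
#'
#' Each bit is flipped independently with probability `m_r`.
#'
#' @param bits binary vector.
#' @param m_r per-bit flip probability.
#' @return mutated vector.
#' @export
bitflip_mutation <- function(bits, m_r = 0.05) {
  flip <- stats::runif(length(bits)) < m_r
  bits[flip] <- 1L - bits[flip]
  bits
}

#' Burst mutation over a circular run
#'
#' The individual is treated as a circular array: a start position and a
#' run length (both uniform, run >= 1) select one circular interval whose
#' bits are each flipped with probability `m_r`.  Applied while the best
#' fitness has stalled, to re-inject diversity.
#'
#' @param bits binary vector.
#' @param m_r per-bit flip probability inside the run.
#' @return mutated vector; attribute `run` records the flipped interval's
#'   positions (for property testing).
#' @export
burst_mutation <- function(bits, m_r = 0.05) {
  len <- length(bits)
  start <- sample.int(len, 1L)
  run_len <- sample.int(len, 1L)
  run <- ((start - 1L + seq_len(run_len) - 1L) %% len) + 1L
  flip <- run[stats::runif(run_len) < m_r]
  bits[flip] <- 1L - bits[flip]
  attr(bits, "run") <- run
  bits
}

#' Run the genetic algorithm on one sub-matrix
#'
#' Generational GA with elitism: the best individual is copied unchanged
#' into the next population; the remaining slots are filled by tournament
#' selection, single-point crossover and bit-flip mutation (plus the burst
#' mutation while stalled).  Stops at a zero-error solution, after
#' `max_iterations`, or after `stall_limit` non-improving iterations.
#' The generational loop runs in compiled code, drawing all randomness
#' from R's RNG stream; the exported operator functions
#' ([tournament_select()], [single_point_crossover()],
#' [bitflip_mutation()], [burst_mutation()]) are the reference
#' definitions it mirrors.
#'
#' @param M a [fragment_matrix()] (the sub-problem).
#' @param config a [ga_config()]; if `config$seed` is set the R RNG is
#'   seeded before the run.
#' @return list with `partition` (decoded best-ever individual), `h1`,
#'   `h2` (inferred on `M`), `cost`, and `stats` (class `ga_stats`):
#'   `best_fitness_per_iteration`, `iterations_run`, `termination_reason`.
#' @export
run_ga <- function(M, config = ga_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- nrow(M$entries)
  np <- config$population_size

  finish <- function(best_bits, curve, reason) {
    partition <- decode_individual(best_bits)
    h <- infer_haplotypes(M, partition, weighted = config$weighted)
    list(partition = partition, h1 = h$h1, h2 = h$h2,
         cost = curve[length(curve)],
         stats = structure(list(best_fitness_per_iteration = curve,
                                iterations_run = length(curve),
                                termination_reason = reason),
                           class = "ga_stats"))
  }

  if (m == 1L)
    return(finish(0L, 0L, "zero_error"))

  core <- ga_core(M$entries, M$weights, np, config$crossover_rate,
                  config$mutation_rate, config$tournament_size,
                  config$max_iterations, config$stall_limit,
                  config$burst_mutation_stall, config$weighted)
  finish(core$best_bits, core$curve, core$termination_reason)
}
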