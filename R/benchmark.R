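#' Simulate one instance and assemble it
#'
#' Convenience wrapper used by the benchmark driver and the acceptance
#' report: plants a truth, samples reads with the given profile, runs the
#' assembler, and scores the haplotype error rate against the planted
#' truth.  The GA master seed is derived from the instance seed, so the
#' whole run is reproducible from `seed` alone.
#'
#' @param profile `"roche454"` or `"pacbio"`.
#' @param n_snps,f_snps,cov simulation parameters (see [sim_config()]).
#' @param seed instance seed.
#' @param config a [ga_config()] (its `seed` field is overwritten).
#' @param workers worker-pool size for [assemble()].
#' @return list: `he` (pooled HE, percent), `masked`, `total_cost`,
#'   `n_blocks`, plus the full `result` and `truth`.
#' @export
run_instance <- function(profile, n_snps, f_snps, cov, seed,
                         config = ga_config(), workers = 1L) {
  scfg <- sim_config(n_snps = n_snps, f_snps = f_snps, cov = cov,
                     profile = profile, seed = seed)
  set.seed(scfg$seed)
  truth <- generate_truth(scfg)
  M <- simulate_reads(truth, scfg)
  config$seed <- derive_seed(seed, 7919L)
  res <- assemble(M, config, workers = workers)
  he <- haplotype_error_rate(res, truth)
  list(he = he$pooled, masked = he$masked, total_cost = res$total_cost,
       n_blocks = length(res$blocks), result = res, truth = truth)
}

#' Mean haplotype error rate over a grid of simulated conditions
#'
#' Runs `n_reps` independent instances for every combination of the
#' supplied `n_snps` and `f_snps` values and returns the per-instance HE
#' values, one row per instance.  Instance seeds are derived from
#' `master_seed` and the cell coordinates.
#'
#' @param profile `"roche454"` or `"pacbio"`.
#' @param cov coverage.
#' @param n_snps_values,f_snps_values vectors defining the grid.
#' @param n_reps instances per cell.
#' @param master_seed master seed; every instance seed derives from it.
#' @param config a [ga_config()].
#' @param workers worker-pool size.
#' @return data.frame with columns `profile`, `cov`, `n_snps`, `f_snps`,
#'   `rep`, `seed`, `he`, `masked`, `cost`.
#' @export
he_benchmark <- function(profile, cov, n_snps_values, f_snps_values,
                         n_reps = 5L, master_seed = 1L,
                         config = ga_config(), workers = 1L) {
  grid <- expand.grid(n_snps = n_snps_values, f_snps = f_snps_values,
                      rep = seq_len(n_reps))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    seed <- derive_seed(master_seed, match(g$n_snps, n_snps_values),
                        match(g$f_snps, f_snps_values), g$rep)
    r <- run_instance(profile, g$n_snps, g$f_snps, cov, seed,
                      config = config, workers = workers)
    data.frame(profile = profile, cov = cov, n_snps = g$n_snps,
               f_snps = g$f_snps, rep = g$rep, seed = seed,
               he = r$he, masked = r$masked, cost = r$total_cost)
  })
  do.call(rbind, rows)
}
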