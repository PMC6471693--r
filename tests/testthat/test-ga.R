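test_that("individuals decode to bipartitions bijectively", {
  expect_identical(decode_individual(c(0L, 0L, 0L)), c(1L, 1L, 1L))
  expect_identical(decode_individual(c(1L, 1L)), c(2L, 2L))
  expect_identical(decode_individual(c(0L, 1L, 0L, 1L)), c(1L, 2L, 1L, 2L))
  expect_error(decode_individual(c(0L, 2L)), "bits")
})

test_that("GA config applies the documented defaults and bounds", {
  cfg <- ga_config()
  expect_identical(cfg$population_size, 100L)
  expect_equal(cfg$crossover_rate, 0.9)
  expect_equal(cfg$mutation_rate, 0.05)
  expect_identical(cfg$tournament_size, 10L)     # ceiling(0.1 * 100)
  expect_identical(cfg$max_iterations, 100L)
  expect_identical(cfg$stall_limit, 25L)         # ceiling(0.25 * 100)
  expect_identical(cfg$burst_mutation_stall, 2L)
  expect_identical(ga_config(population_size = 10L)$tournament_size, 2L)
  expect_error(ga_config(crossover_rate = 1.5))
  expect_error(ga_config(tournament_size = 300L))
})

test_that("individual fitness equals the oracle recount", {
  set.seed(5)
  for (rep in 1:15) {
    inst <- random_instance(m = 8, n = 6, error_rate = 0.2)
    bits <- sample(c(0L, 1L), 8, replace = TRUE)
    f <- evaluate_individual(bits, inst$M)
    expect_identical(as.integer(f), as.integer(oracle_cost(inst$M, bits + 1L)))
    # complement symmetry: swapping all labels never changes fitness
    expect_identical(evaluate_individual(1L - bits, inst$M), f)
  }
  # the planted bipartition of an error-free instance has fitness zero
  inst0 <- random_instance(m = 8, n = 6, error_rate = 0)
  expect_identical(evaluate_individual(inst0$partition - 1L, inst0$M), 0L)
})

test_that("tournament selection prefers fitter individuals", {
  set.seed(9)
  fitness <- c(5, 1, 3, 4, 2)
  # a tournament over the whole population always returns the best
  for (rep in 1:20)
    expect_identical(tournament_select(fitness, 5L), 2L)
  expect_error(tournament_select(numeric(0), 1L), "empty")
  expect_error(tournament_select(fitness, 6L), "larger")
  # selection pressure: with k = 2 the best is selected more often than
  # the worst over many tournaments
  picks <- replicate(10000, tournament_select(c(1, 2, 3), 2L))
  expect_gt(sum(picks == 1L), sum(picks == 3L))
})

test_that("single-point crossover exchanges tails", {
  expect_identical(
    single_point_crossover(rep(0L, 4), rep(1L, 4), c_r = 1, cut = 2L),
    list(c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L)))
  set.seed(2)
  a <- sample(c(0L, 1L), 6, replace = TRUE)
  b <- sample(c(0L, 1L), 6, replace = TRUE)
  expect_identical(single_point_crossover(a, b, c_r = 0), list(a, b))
  # offspring take every position from one of the two parents
  for (rep in 1:30) {
    kids <- single_point_crossover(a, b, c_r = 1)
    for (k in kids)
      expect_true(all(k == a | k == b))
    # positionwise multiset of bits is preserved
    expect_identical(kids[[1L]] + kids[[2L]], a + b)
  }
  # length-1 parents cannot be cut
  expect_identical(single_point_crossover(0L, 1L, c_r = 1), list(0L, 1L))
})

test_that("bit-flip mutation has the stated marginal behaviour", {
  bits <- c(0L, 1L, 1L, 0L, 1L)
  expect_identical(bitflip_mutation(bits, 0), bits)
  expect_identical(bitflip_mutation(bits, 1), 1L - bits)
  set.seed(4)
  len <- 50L
  flips <- replicate(400, sum(bitflip_mutation(rep(0L, len), 0.1)))
  # Monte-Carlo mean within 3 standard errors of m_r * len
  se <- sqrt(len * 0.1 * 0.9 / 400)
  expect_lt(abs(mean(flips) - 0.1 * len), 3 * se)
})

test_that("burst mutation flips inside one circular run", {
  set.seed(8)
  for (rep in 1:50) {
    len <- sample(3:12, 1)
    bits <- sample(c(0L, 1L), len, replace = TRUE)
    out <- burst_mutation(bits, m_r = 1)
    run <- attr(out, "run")
    expect_gte(length(run), 1L)
    # the run is one circular interval: consecutive positions differ by
    # 1 modulo len
    if (length(run) > 1L)
      expect_true(all((diff(run) %% len) %in% c(1L, 1L - len)))
    # with m_r = 1 exactly the run is flipped
    changed <- which(as.integer(out) != bits)
    expect_setequal(changed, unique(run))
  }
  # m_r = 0 leaves the individual untouched
  bits <- c(0L, 1L, 0L)
  expect_identical(as.integer(burst_mutation(bits, 0)), bits)
})

test_that("run_ga handles degenerate and conflict-free inputs", {
  M1 <- fm(list(c(0L, 1L, 0L)))
  res <- run_ga(M1, ga_config(seed = 1L))
  expect_identical(res$stats$termination_reason, "zero_error")
  expect_identical(res$cost, 0L)

  set.seed(10)
  inst <- random_instance(m = 10, n = 8, error_rate = 0)
  res0 <- run_ga(inst$M, ga_config(seed = 2L))
  expect_identical(res0$stats$termination_reason, "zero_error")
  expect_identical(res0$cost, 0L)
})

test_that("run_ga attains the exhaustive optimum on small noisy instances", {
  set.seed(21)
  hits <- 0L
  for (rep in 1:10) {
    inst <- random_instance(m = 10, n = sample(5:8, 1), error_rate = 0.15)
    opt <- oracle_optimum(inst$M)
    res <- run_ga(inst$M, ga_config(seed = rep))
    expect_gte(res$cost, opt)
    if (res$cost == opt) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("run_ga is deterministic and its best-fitness curve monotone", {
  set.seed(33)
  inst <- random_instance(m = 12, n = 8, error_rate = 0.2)
  a <- run_ga(inst$M, ga_config(seed = 99L))
  b <- run_ga(inst$M, ga_config(seed = 99L))
  expect_identical(a$partition, b$partition)
  expect_identical(a$stats$best_fitness_per_iteration,
                   b$stats$best_fitness_per_iteration)
  expect_true(all(diff(a$stats$best_fitness_per_iteration) <= 0))
  expect_true(a$stats$termination_reason %in%
                c("zero_error", "max_iterations", "stalled"))
  expect_identical(a$stats$iterations_run,
                   length(a$stats$best_fitness_per_iteration))
})
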