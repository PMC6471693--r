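# Shared fixture builders and the independent brute-force wMEC oracle.
# Everything here is deliberately written in plain loops, independent of
# the package's vectorized / compiled code paths.

# a fragment matrix from a plain list of rows (NA = not covered)
fm <- function(rows, weights = NULL, positions = NULL) {
  e <- do.call(rbind, rows)
  fragment_matrix(e, weights, positions)
}

# random ternary vector over {0, 1, NA}
random_ternary <- function(n, p_missing = 0.3) {
  v <- sample(c(0L, 1L), n, replace = TRUE)
  v[runif(n) < p_missing] <- NA_integer_
  v
}

# a small random instance: planted haplotype pair, reads covering random
# contiguous windows, optional allele flips, integer phred-like weights
random_instance <- function(m = 8, n = 6, error_rate = 0.1,
                            max_weight = 20L) {
  h1 <- sample(c(0L, 1L), n, replace = TRUE)
  h2 <- 1L - h1
  entries <- matrix(NA_integer_, m, n)
  weights <- matrix(0, m, n)
  src <- integer(m)
  for (i in seq_len(m)) {
    a <- sample.int(n, 1L)
    b <- min(n, a + sample.int(max(1L, n %/% 2L), 1L))
    src[i] <- sample(1:2, 1L)
    hap <- if (src[i] == 1L) h1 else h2
    vals <- hap[a:b]
    err <- runif(b - a + 1L) < error_rate
    vals[err] <- 1L - vals[err]
    entries[i, a:b] <- vals
    weights[i, a:b] <- sample.int(max_weight, b - a + 1L, replace = TRUE)
  }
  # guard: every column covered (resample columns nobody covers as unit reads)
  uncovered <- which(colSums(!is.na(entries)) == 0L)
  for (j in uncovered) {
    i <- sample.int(m, 1L)
    entries[i, j] <- h1[j]
    weights[i, j] <- 1
  }
  M <- fragment_matrix(entries, weights)
  list(M = M, h1 = h1, h2 = h2, partition = src)
}

# independent recount of the wMEC cost of a fixed partition: nested loops,
# explicit majority per column per part
oracle_cost <- function(M, partition, weighted = TRUE) {
  total <- 0L
  for (k in 1:2) {
    rows <- which(partition == k)
    for (j in seq_len(ncol(M$entries))) {
      vals <- M$entries[rows, j]
      w <- M$weights[rows, j]
      def <- which(!is.na(vals))
      if (length(def) == 0L) next
      ww <- if (weighted) w[def] else rep(1, length(def))
      n1 <- sum(ww[vals[def] == 1L])
      n0 <- sum(ww[vals[def] == 0L])
      allele <- if (n1 >= n0) 1L else 0L
      total <- total + sum(vals[def] != allele)
    }
  }
  total
}

# exhaustive enumeration of all label-distinct bipartitions (read 1 fixed
# in part 1); returns the optimal cost
oracle_optimum <- function(M, weighted = TRUE) {
  m <- nrow(M$entries)
  best <- Inf
  for (code in 0:(2^(m - 1L) - 1L)) {
    bits <- c(0L, as.integer(intToBits(code))[seq_len(m - 1L)])
    cost <- oracle_cost(M, bits + 1L, weighted)
    if (cost < best) best <- cost
  }
  best
}
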