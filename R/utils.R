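#' @useDynLib hapga, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Derive a deterministic child seed
#'
#' A small multiplicative hash of a master seed and any number of integer
#' coordinates (block index, sub-problem index, replicate, ...), kept
#' inside the 32-bit signed range.  The assembler derives one RNG stream
#' per sub-problem this way, which is what makes results independent of
#' worker count and scheduling order.
#'
#' @param master integer master seed.
#' @param ... integer coordinates.
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, ...) {
  x <- as.double(master) %% 2147483647
  for (k in c(...)) x <- (x * 48271 + as.double(k) * 8191 + 1) %% 2147483647
  as.integer(x) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
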