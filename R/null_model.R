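#' Monte Carlo random-segregation null and its analytic oracle
#'
#' Under the random null each of the two single-chromatid homologs of a
#' pair is tossed independently to the PB2 or the zygote with probability
#' `p_to_zygote`; the pair segregates properly when they land on opposite
#' sides, which happens with probability `2 p (1 - p)` — 50% at the fair
#' coin. The number of properly segregated pairs per embryo is therefore
#' Binomial(20, 0.5) with mean 10, the expectation against which observed
#' cohorts are compared.
#'
#' @name null_model_stats
NULL

#' Null-model configuration
#'
#' @param n_embryos Embryos per replicate (default 63, the hybrid cohort
#'   size).
#' @param n_pairs Homolog pairs (default 20).
#' @param p_to_zygote Per-chromatid probability of landing in the zygote
#'   (default 0.5).
#' @param n_reps Number of cohort replicates (default 1).
#' @param seed Optional RNG seed.
#' @return A `null_config` list.
#' @export
null_config <- function(n_embryos = 63L, n_pairs = 20L, p_to_zygote = 0.5,
                        n_reps = 1L, seed = NULL) {
  if (p_to_zygote < 0 || p_to_zygote > 1) stop("p_to_zygote must be in [0, 1]")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  structure(list(n_embryos = as.integer(n_embryos),
                 n_pairs = as.integer(n_pairs),
                 p_to_zygote = p_to_zygote, n_reps = as.integer(n_reps),
                 seed = seed),
            class = "null_config")
}

#' Monte Carlo simulation of random segregation
#'
#' Literal coin-flip simulation: per pair, two independent Bernoulli
#' (`p_to_zygote`) draws decide each chromatid's destination; the pair
#' counts as proper iff the draws differ. Bit-reproducible for a fixed
#' seed.
#'
#' @param config A [null_config()].
#' @return Integer matrix `n_reps` x `n_embryos` of properly segregated
#'   pair counts (0..`n_pairs`).
#' @export
simulate_random_null <- function(config = null_config()) {
  stopifnot(inherits(config, "null_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_reps * config$n_embryos * config$n_pairs
  c1 <- stats::runif(n) < config$p_to_zygote
  c2 <- stats::runif(n) < config$p_to_zygote
  proper <- c1 != c2
  counts <- colSums(matrix(proper, nrow = config$n_pairs))
  matrix(as.integer(counts), nrow = config$n_reps, byrow = TRUE)
}

#' Per-pair proper probability from the per-chromatid probability
#'
#' @param p_to_zygote Per-chromatid probability.
#' @return `2 p (1 - p)`.
#' @export
proper_probability <- function(p_to_zygote = 0.5) {
  if (any(p_to_zygote < 0 | p_to_zygote > 1)) {
    stop("p_to_zygote must be in [0, 1]")
  }
  2 * p_to_zygote * (1 - p_to_zygote)
}

#' Exhaustive enumeration of the four pole assignments of one pair
#'
#' The two chromatids of a pair can land in `2 x 2 = 4` ways; the table
#' lists each with its probability and whether it is a proper
#' segregation. Summing the proper rows at `p = 0.5` gives the 50%
#' reference chance.
#'
#' @param p_to_zygote Per-chromatid probability.
#' @return Data.frame `chromatid_a`, `chromatid_b`, `probability`,
#'   `proper`.
#' @export
enumerate_pair_assignments <- function(p_to_zygote = 0.5) {
  dest <- c("ZYGOTE", "PB2")
  pr <- c(p_to_zygote, 1 - p_to_zygote)
  grid <- expand.grid(chromatid_a = dest, chromatid_b = dest,
                      stringsAsFactors = FALSE)
  grid$probability <- pr[match(grid$chromatid_a, dest)] *
    pr[match(grid$chromatid_b, dest)]
  grid$proper <- grid$chromatid_a != grid$chromatid_b
  grid
}

#' Analytic pmf of proper pair counts
#'
#' Exact Binomial(`n_pairs`, `p_proper`) probabilities over 0..`n_pairs`,
#' the closed-form oracle for [simulate_random_null()].
#'
#' @param n_pairs Homolog pairs (default 20).
#' @param p_proper Per-pair proper probability; defaults to
#'   [proper_probability()] of a fair coin (0.5).
#' @return Named numeric vector of probabilities for counts 0..`n_pairs`.
#' @export
binomial_proper_pmf <- function(n_pairs = 20L, p_proper = proper_probability()) {
  if (p_proper < 0 || p_proper > 1) stop("p_proper must be in [0, 1]")
  stats::setNames(stats::dbinom(0:n_pairs, n_pairs, p_proper),
                  as.character(0:n_pairs))
}

#' Total-variation distance between an empirical and an analytic pmf
#'
#' @param counts Integer sample (e.g. flattened null draws).
#' @param pmf Named analytic pmf over the support, as from
#'   [binomial_proper_pmf()].
#' @return Total-variation distance in \[0, 1\].
#' @export
total_variation <- function(counts, pmf) {
  emp <- table(factor(counts, levels = names(pmf))) / length(counts)
  sum(abs(as.numeric(emp) - as.numeric(pmf))) / 2
}
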