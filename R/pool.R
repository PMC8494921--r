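#' Generate a variant payoff pool
#'
#' Each of the `pool_size` possible variants gets an integer payoff:
#' a draw `x` from an exponential distribution with rate `payoff_rate` is
#' squared, doubled, rounded (half away from zero) and incremented by 1.
#' The exponential shape gives a few variants with very high payoffs and a
#' majority with low ones; the `+ 1` guarantees a minimum payoff of 1, so
#' roulette weights are always positive. At the default rate 1 the largest
#' payoff in a 100-variant pool is typically around 50. A fresh pool is
#' generated for every simulation run.
#'
#' @param pool_size Number of variants (default 100).
#' @param payoff_rate Exponential rate `lambda` (default 1).
#' @return Integer vector of payoffs; variant id `v` (0-based) has payoff
#'   `pool[v + 1]`.
#' @export
#' @examples
#' set.seed(1)
#' pool <- generate_payoff_pool()
#' min(pool)  # always >= 1
generate_payoff_pool <- function(pool_size = 100L, payoff_rate = 1) {
  if (!is.numeric(pool_size) || length(pool_size) != 1 || pool_size < 1)
    stop("pool_size must be a positive integer")
  if (!is.numeric(payoff_rate) || length(payoff_rate) != 1 || payoff_rate <= 0)
    stop("payoff_rate must be positive")
  x <- rexp(as.integer(pool_size), rate = payoff_rate)
  as.integer(round_half_away(2 * x^2) + 1)
}

#' Look up the payoff of a variant id
#'
#' @param pool Integer payoff vector from [generate_payoff_pool()].
#' @param id 0-based variant id(s).
#' @return Integer payoff(s).
#' @export
variant_payoff <- function(pool, id) {
  if (any(id < 0 | id >= length(pool)))
    stop("variant id out of pool range")
  pool[id + 1L]
}

#' Initialise a population state
#'
#' Every agent is independently assigned a uniform-random variant id from
#' the pool, sampled with replacement (duplicates allowed).
#'
#' @param config A [simulation_config()].
#' @param pool Payoff pool; defaults to a fresh [generate_payoff_pool()]
#'   under the config's pool parameters.
#' @return A `cultsel_state`: list with `variants` (0-based ids, one per
#'   agent) and `pool`.
#' @export
initialize_population <- function(config,
                                  pool = generate_payoff_pool(config$pool_size,
                                                              config$payoff_rate)) {
  n <- config$population_size
  variants <- as.integer(floor(runif(n) * length(pool)))
  variants[variants >= length(pool)] <- length(pool) - 1L
  structure(list(variants = variants, pool = pool), class = "cultsel_state")
}

#' @export
print.cultsel_state <- function(x, ...) {
  cat(sprintf("<cultsel_state> %d agents, %d-variant pool\n",
              length(x$variants), length(x$pool)))
  cat("  variants:", paste(utils::head(x$variants, 20), collapse = " "),
      if (length(x$variants) > 20) "..." else "", "\n")
  invisible(x)
}
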