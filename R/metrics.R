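#' Gini-Simpson diversity index
#'
#' `1 - sum((n_v / N)^2)` over variant counts `n_v`: the probability that
#' two randomly chosen agents hold different variants. 0 when all agents
#' share one variant; the maximum `1 - 1/N` is attained exactly when all
#' `N` agents hold distinct variants (0.9 for N = 10, 0.95 for 20, 0.99
#' for 100, 0.995 for 200). The plain (uncorrected) form is used, not the
#' unbiased finite-sample estimator.
#'
#' @param variants Vector of variant ids held by the agents.
#' @return Diversity score in `[0, 1 - 1/N]`.
#' @export
#' @examples
#' gini_simpson(rep(3, 10))      # fixation: 0
#' gini_simpson(0:9)             # all distinct among 10: 0.9
gini_simpson <- function(variants) {
  if (length(variants) == 0) stop("variants must be non-empty")
  counts <- tabulate(match(variants, unique(variants)))
  1 - sum((counts / length(variants))^2)
}

#' Mean variant payoff of a population
#'
#' Arithmetic mean of the payoffs of the variants the agents currently
#' hold; its increase over time is the model's measure of population-level
#' adaptation.
#'
#' @param variants 0-based variant ids, one per agent.
#' @param pool Payoff pool.
#' @return Mean payoff (lies within the pool's payoff range).
#' @export
mean_payoff <- function(variants, pool) {
  if (length(variants) == 0) stop("variants must be non-empty")
  mean(variant_payoff(pool, variants))
}

# Per-step metrics for an (n_steps + 1) x N matrix of variant ids.
trajectory_metrics <- function(states, pool) {
  tibble::tibble(
    time_step = seq_len(nrow(states)) - 1L,
    diversity = apply(states, 1, gini_simpson),
    mean_payoff = apply(states, 1, mean_payoff, pool = pool)
  )
}
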