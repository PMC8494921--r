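#' Simulation configuration
#'
#' Bundles and validates all parameters of a single simulation run.
#'
#' @param payoff_bias Probability `b` in `[0, 1]` that an agent's update is
#'   critical, i.e. decided by payoff-proportional roulette over its own,
#'   a model's and an innovated variant. `b = 0` is fully uncritical
#'   (drift under the default strategy), `b = 1` fully critical.
#' @param learner_type Uncritical default strategy: `"copier"` (adopt a
#'   model's variant), `"innovator"` (draw a fresh variant from the pool)
#'   or `"maintainer"` (keep the current variant).
#' @param population_size Number of agents `N` (at least 2, so every agent
#'   has a possible model).
#' @param error_rate Probability `e` in `[0, 1]` that the adopted variant
#'   is replaced by a uniform-random pool variant (production error).
#'   Default 0.02.
#' @param pool_size Number of possible variants (default 100).
#' @param structure_sigma Standard deviation of the Gaussian offset used
#'   for model selection on a circular line of agents, or `NULL` (default)
#'   for an unstructured population where every other agent is an equally
#'   likely model.
#' @param n_steps Number of time steps (default 200).
#' @param payoff_rate Rate `lambda` of the exponential distribution behind
#'   variant payoffs (default 1).
#' @param seed Integer seed making the run exactly reproducible, or `NULL`
#'   to continue from the current RNG state.
#' @param shuffle_order If `TRUE`, the sequential update order is
#'   re-randomised at every time step; the default `FALSE` uses fixed
#'   index order `0 .. N-1`.
#' @return An object of class `cultsel_config`.
#' @export
#' @examples
#' simulation_config(payoff_bias = 0.2, learner_type = "maintainer",
#'                   population_size = 10, seed = 1)
simulation_config <- function(payoff_bias,
                              learner_type = c("copier", "innovator", "maintainer"),
                              population_size,
                              error_rate = 0.02,
                              pool_size = 100L,
                              structure_sigma = NULL,
                              n_steps = 200L,
                              payoff_rate = 1,
                              seed = NULL,
                              shuffle_order = FALSE) {
  learner_type <- match.arg(learner_type)
  stopifnot(
    "payoff_bias must be a probability in [0, 1]" =
      is.numeric(payoff_bias) && length(payoff_bias) == 1 &&
      payoff_bias >= 0 && payoff_bias <= 1,
    "error_rate must be a probability in [0, 1]" =
      is.numeric(error_rate) && length(error_rate) == 1 &&
      error_rate >= 0 && error_rate <= 1,
    "population_size must be an integer >= 2" =
      is.numeric(population_size) && length(population_size) == 1 &&
      population_size >= 2,
    "pool_size must be a positive integer" =
      is.numeric(pool_size) && length(pool_size) == 1 && pool_size >= 1,
    "n_steps must be a non-negative integer" =
      is.numeric(n_steps) && length(n_steps) == 1 && n_steps >= 0,
    "payoff_rate must be positive" =
      is.numeric(payoff_rate) && length(payoff_rate) == 1 && payoff_rate > 0
  )
  if (!is.null(structure_sigma)) {
    stopifnot("structure_sigma must be positive" =
                is.numeric(structure_sigma) && length(structure_sigma) == 1 &&
                structure_sigma > 0)
  }
  structure(
    list(payoff_bias = payoff_bias,
         learner_type = learner_type,
         population_size = as.integer(population_size),
         error_rate = error_rate,
         pool_size = as.integer(pool_size),
         structure_sigma = structure_sigma,
         n_steps = as.integer(n_steps),
         payoff_rate = payoff_rate,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         shuffle_order = isTRUE(shuffle_order)),
    class = "cultsel_config"
  )
}

#' @export
print.cultsel_config <- function(x, ...) {
  cat("<cultsel_config>\n")
  cat(sprintf("  payoff bias b = %g, learner type = %s, error rate e = %g\n",
              x$payoff_bias, x$learner_type, x$error_rate))
  cat(sprintf("  N = %d agents, %s, pool of %d variants (lambda = %g)\n",
              x$population_size,
              if (is.null(x$structure_sigma)) "unstructured"
              else sprintf("ring with Gaussian sigma = %g", x$structure_sigma),
              x$pool_size, x$payoff_rate))
  cat(sprintf("  %d time steps, seed = %s, update order = %s\n",
              x$n_steps,
              if (is.null(x$seed)) "none" else x$seed,
              if (x$shuffle_order) "reshuffled each step" else "fixed 0..N-1"))
  invisible(x)
}

#' Read a simulation configuration from a YAML/JSON file
#'
#' The file is a flat key/value document whose keys match the arguments of
#' [simulation_config()]. Keys supplied in `overrides` take precedence, so
#' command-line flags can override file values.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) config file.
#' @param overrides Named list of values overriding the file's.
#' @return A `cultsel_config`.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, overrides)
  do.call(simulation_config, vals)
}
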