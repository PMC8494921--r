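#' Build the model-selection operation for a configuration
#'
#' Returns a function of a 0-based agent index yielding a model index:
#' uniform over the other agents for unstructured populations, Gaussian
#' offsets on a ring when `structure_sigma` is set.
#'
#' @param config A [simulation_config()].
#' @return Function `(agent_index) -> model index`.
#' @export
make_model_selector <- function(config) {
  if (is.null(config$structure_sigma)) {
    n <- config$population_size
    function(agent_index) select_model_unstructured(agent_index, n)
  } else {
    topo <- ring_topology(config$population_size, config$structure_sigma)
    function(agent_index) select_model_structured(agent_index, topo)
  }
}

#' Update one agent (single adoption decision)
#'
#' With probability `b` the agent is critical: a model and an innovated
#' variant are drawn, and the adopted variant is chosen by
#' [critical_choice()] over (own, model's, innovated) with
#' payoff-proportional probabilities. Otherwise the uncritical default
#' applies: a copier draws only a model and adopts its variant, an
#' innovator draws only an innovation, a maintainer keeps its own variant
#' and draws nothing. Production error is then applied once to whichever
#' variant was chosen. Candidate draws are lazy -- only the branch taken
#' consumes random numbers -- which is observationally equivalent to
#' drawing everything up front but keeps the random stream interpretable.
#'
#' @param agent_index 0-based index of the updating agent.
#' @param state A `cultsel_state` (current holdings of all agents).
#' @param config A [simulation_config()].
#' @param model_selector Function `(agent_index) -> model index`, e.g.
#'   from [make_model_selector()].
#' @return The adopted 0-based variant id. The caller
#'   ([run_time_step()]) writes it into the state before the next agent
#'   updates.
#' @export
update_agent <- function(agent_index, state, config, model_selector) {
  pool <- state$pool
  own <- state$variants[agent_index + 1L]
  if (runif(1L) < config$payoff_bias) {
    m <- model_selector(agent_index)
    innov <- innovate_variant(pool)
    cand <- candidate_set(own, state$variants[m + 1L], innov, pool)
    chosen <- critical_choice(cand)
  } else {
    chosen <- switch(config$learner_type,
                     copier = state$variants[model_selector(agent_index) + 1L],
                     innovator = innovate_variant(pool),
                     maintainer = own)
  }
  apply_production_error(chosen, config$error_rate, pool)
}

#' Run one sequential time step
#'
#' Agents update one at a time (fixed index order `0 .. N-1`, or a fresh
#' random permutation if `config$shuffle_order`); each update sees the
#' current, possibly already-updated holdings of all other agents, so a
#' later agent can copy a variant an earlier agent adopted within the
#' same step. The same model may serve multiple agents.
#'
#' @inheritParams update_agent
#' @param model_selector Defaults to [make_model_selector()] on `config`.
#' @return The updated `cultsel_state`.
#' @export
run_time_step <- function(state, config,
                          model_selector = make_model_selector(config)) {
  n <- length(state$variants)
  ord <- 0:(n - 1L)
  if (config$shuffle_order) {
    # Fisher-Yates with the shared uniform-index primitive
    for (i in seq(n, 2L)) {
      j <- draw_index(i) + 1L
      tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
    }
  }
  for (i in ord) {
    state$variants[i + 1L] <- update_agent(i, state, config, model_selector)
  }
  state
}

#' Run one full simulation
#'
#' Generates a fresh payoff pool, initialises the population with
#' uniform-random variants, then runs `n_steps` sequential time steps,
#' recording Gini-Simpson diversity and mean variant payoff after every
#' step plus a `t = 0` baseline. With a seed in the config the run is
#' exactly reproducible. The default engine is compiled; `engine = "r"`
#' runs the pure-R reference implementation
#' ([run_time_step()]/[update_agent()]), which consumes the identical
#' random stream and produces bit-identical trajectories.
#'
#' @param config A [simulation_config()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @return A `cultsel_trajectory`: tibble with columns `time_step`,
#'   `diversity`, `mean_payoff`, carrying the config, the payoff pool and
#'   the final population state as attributes.
#' @export
#' @examples
#' cfg <- simulation_config(payoff_bias = 0.2, learner_type = "maintainer",
#'                          population_size = 10, n_steps = 20, seed = 1)
#' run_simulation(cfg)
run_simulation <- function(config, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!is.null(config$seed)) set.seed(config$seed)
  pool <- generate_payoff_pool(config$pool_size, config$payoff_rate)
  state <- initialize_population(config, pool)
  sigma <- if (is.null(config$structure_sigma)) -1 else config$structure_sigma
  if (engine == "cpp") {
    learner <- match(config$learner_type,
                     c("copier", "innovator", "maintainer")) - 1L
    states <- sim_engine_cpp(pool, state$variants, config$payoff_bias,
                             learner, config$error_rate, sigma,
                             config$n_steps, config$shuffle_order)
    final <- structure(list(variants = states[nrow(states), ], pool = pool),
                       class = "cultsel_state")
  } else {
    selector <- make_model_selector(config)
    states <- matrix(NA_integer_, nrow = config$n_steps + 1L,
                     ncol = config$population_size)
    states[1L, ] <- state$variants
    if (config$n_steps > 0) {
      for (t in seq_len(config$n_steps)) {
        state <- run_time_step(state, config, selector)
        states[t + 1L, ] <- state$variants
      }
    }
    final <- state
  }
  traj <- trajectory_metrics(states, pool)
  attr(traj, "config") <- config
  attr(traj, "pool") <- pool
  attr(traj, "final_state") <- final
  attr(traj, "states") <- states
  class(traj) <- c("cultsel_trajectory", class(traj))
  traj
}
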