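#' Innovate a variant
#'
#' Draws uniform-random variant id(s) from the full pool of possible
#' variants. An innovated variant may coincide with the agent's current or
#' model's variant; the pool represents all possible variants and no
#' exclusion is applied.
#'
#' @param pool Payoff pool.
#' @param n Number of independent draws (default 1).
#' @return Integer 0-based variant id(s).
#' @export
innovate_variant <- function(pool, n = 1L) {
  if (length(pool) < 1) stop("pool must be non-empty")
  id <- as.integer(floor(runif(n) * length(pool)))
  id[id >= length(pool)] <- length(pool) - 1L
  id
}

#' Assemble the three candidate variants of an update
#'
#' The critical branch of an agent update chooses among three candidates:
#' the agent's own variant (payoff `p_s`), the model's variant (`p_m`) and
#' a freshly innovated variant (`p_n`). Duplicate ids are kept in separate
#' slots; their selection masses add. The `payoff` column is the hook
#' point for payoff modifiers (e.g. evaluation or learning costs): a
#' transformed candidate set can be passed straight to
#' [critical_choice()].
#'
#' @param own,model,innovated 0-based variant ids.
#' @param pool Payoff pool used to look up each candidate's payoff.
#' @return A `cultsel_candidates` tibble with columns `slot`, `id`,
#'   `payoff`.
#' @export
candidate_set <- function(own, model, innovated, pool) {
  ids <- c(own, model, innovated)
  out <- tibble::tibble(
    slot = c("own", "model", "innovated"),
    id = as.integer(ids),
    payoff = as.numeric(variant_payoff(pool, ids))
  )
  if (any(out$payoff < 1)) stop("candidate payoffs must be >= 1")
  class(out) <- c("cultsel_candidates", class(out))
  out
}

#' Critical (payoff-biased) choice among candidates
#'
#' Roulette-wheel selection: each candidate slot is chosen with
#' probability equal to its payoff divided by the summed payoffs
#' `p_s + p_m + p_n`. With payoffs (10, 6, 4) the first slot wins with
#' probability 10/(10 + 6 + 4) = 0.5. Duplicate variant ids occupy
#' separate slots, so their masses add.
#'
#' @param candidates A [candidate_set()] (any data frame with `id` and
#'   `payoff` columns works).
#' @param n Number of independent draws (default 1).
#' @return Integer variant id(s), one per draw.
#' @export
critical_choice <- function(candidates, n = 1L) {
  p <- as.numeric(candidates$payoff)
  if (any(p <= 0)) stop("candidate payoffs must be positive")
  cum <- cumsum(p)
  u <- runif(n) * cum[length(cum)]
  slot <- findInterval(u, cum) + 1L  # u < cum[slot], strict as in engine
  candidates$id[slot]
}

#' Uncritical (default-strategy) choice
#'
#' The learner type dictates the choice outright, never inspecting
#' payoffs: a maintainer keeps its own variant, a copier adopts the
#' model's, an innovator adopts the innovated one.
#'
#' @param learner_type `"copier"`, `"innovator"` or `"maintainer"`.
#' @param candidates A [candidate_set()].
#' @return Integer variant id.
#' @export
uncritical_choice <- function(learner_type, candidates) {
  slot <- switch(learner_type,
                 copier = "model",
                 innovator = "innovated",
                 maintainer = "own",
                 stop("unknown learner type: ", learner_type))
  candidates$id[candidates$slot == slot]
}

#' Apply production error to a chosen variant
#'
#' With probability `1 - error_rate` the chosen variant is returned
#' unchanged; with probability `error_rate` it is replaced by a
#' uniform-random id from the full pool, which may equal the variant the
#' agent was trying to produce.
#'
#' @param chosen Integer 0-based variant id(s).
#' @param error_rate Probability in `[0, 1]`.
#' @param pool Payoff pool.
#' @return Integer variant id(s), same length as `chosen`.
#' @export
apply_production_error <- function(chosen, error_rate, pool) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  chosen <- as.integer(chosen)
  err <- runif(length(chosen)) < error_rate
  if (any(err)) chosen[err] <- innovate_variant(pool, sum(err))
  chosen
}
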