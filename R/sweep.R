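#' Build a parameter-sweep grid
#'
#' Cartesian product of payoff-bias levels, learner types, and either
#' population sizes (`kind = "size"`, unstructured populations) or
#' Gaussian neighbourhood sigmas at a fixed population size
#' (`kind = "structure"`). The defaults are the standard study grid:
#' b in \{0, 0.2, ..., 1\} x \{copier, innovator, maintainer\} x sizes
#' \{10, 20, 100, 200\} (or sigmas \{1, 3, 5, 7\} at N = 200), i.e. 72
#' cells, each run for 200 steps at error rate 0.02 with a 100-variant
#' pool.
#'
#' @param kind `"size"` (unstructured, varying N) or `"structure"`
#'   (ring-structured, varying sigma at fixed N).
#' @param payoff_bias_levels Numeric vector of payoff-bias levels.
#' @param learner_types Character vector of learner types.
#' @param population_sizes Population sizes for the size sweep.
#' @param sigmas Gaussian sigmas for the structure sweep.
#' @param structured_population_size Fixed N for the structure sweep.
#' @param n_replicates Replicates per cell (the full study uses 10,000;
#'   desk-scale checks use 200-1000).
#' @param n_steps,error_rate,pool_size,payoff_rate As in
#'   [simulation_config()].
#' @param base_seed Integer; per-replicate seeds are derived from it with
#'   [derive_seed()], so any cell or replicate can be reproduced in
#'   isolation.
#' @return A `cultsel_sweep_grid` with a `cells` tibble (one row per
#'   parameter combination).
#' @export
#' @examples
#' build_sweep("size")$n_cells  # 72
build_sweep <- function(kind = c("size", "structure"),
                        payoff_bias_levels = seq(0, 1, by = 0.2),
                        learner_types = c("copier", "innovator", "maintainer"),
                        population_sizes = c(10L, 20L, 100L, 200L),
                        sigmas = c(1, 3, 5, 7),
                        structured_population_size = 200L,
                        n_replicates = 10000L,
                        n_steps = 200L,
                        error_rate = 0.02,
                        pool_size = 100L,
                        payoff_rate = 1,
                        base_seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(
    "payoff_bias_levels must be non-empty" = length(payoff_bias_levels) > 0,
    "learner_types must be non-empty" = length(learner_types) > 0,
    all(payoff_bias_levels >= 0 & payoff_bias_levels <= 1),
    all(learner_types %in% c("copier", "innovator", "maintainer")),
    n_replicates >= 1
  )
  if (kind == "size") {
    stopifnot("population_sizes must be non-empty" = length(population_sizes) > 0)
    cells <- expand.grid(payoff_bias = payoff_bias_levels,
                         learner_type = learner_types,
                         population_size = as.integer(population_sizes),
                         stringsAsFactors = FALSE)
    cells$sigma <- NA_real_
  } else {
    stopifnot("sigmas must be non-empty" = length(sigmas) > 0)
    cells <- expand.grid(payoff_bias = payoff_bias_levels,
                         learner_type = learner_types,
                         sigma = sigmas,
                         stringsAsFactors = FALSE)
    cells$population_size <- as.integer(structured_population_size)
  }
  cells <- tibble::as_tibble(cells[, c("payoff_bias", "learner_type",
                                       "population_size", "sigma")])
  cells$cell <- seq_len(nrow(cells))
  structure(
    list(kind = kind, cells = cells, n_cells = nrow(cells),
         n_replicates = as.integer(n_replicates),
         n_steps = as.integer(n_steps), error_rate = error_rate,
         pool_size = as.integer(pool_size), payoff_rate = payoff_rate,
         base_seed = as.integer(base_seed)),
    class = "cultsel_sweep_grid"
  )
}

#' @export
print.cultsel_sweep_grid <- function(x, ...) {
  cat(sprintf("<cultsel_sweep_grid> %s sweep: %d cells x %d replicates, %d steps\n",
              x$kind, x$n_cells, x$n_replicates, x$n_steps))
  invisible(x)
}

# Config for one cell of a grid (replicate seed supplied separately).
cell_config <- function(grid, cell_row, seed) {
  simulation_config(
    payoff_bias = cell_row$payoff_bias,
    learner_type = cell_row$learner_type,
    population_size = cell_row$population_size,
    error_rate = grid$error_rate,
    pool_size = grid$pool_size,
    structure_sigma = if (is.na(cell_row$sigma)) NULL else cell_row$sigma,
    n_steps = grid$n_steps,
    payoff_rate = grid$payoff_rate,
    seed = seed
  )
}

#' Run a parameter sweep
#'
#' Runs `n_replicates` independent simulations per grid cell with seeds
#' derived deterministically from `(base_seed, cell, replicate)`, and
#' aggregates per-time-step means and standard errors of diversity and
#' mean payoff across replicates. Cells are independent, so the result
#' does not depend on execution order, and rerunning any single cell with
#' its recorded seeds reproduces its aggregate exactly.
#'
#' @param grid A [build_sweep()] grid.
#' @param cells Optional integer vector restricting the run to a subset
#'   of cell indices (seeds are unchanged, so subsets reproduce the full
#'   sweep's values).
#' @param verbose Print per-cell progress with seeds.
#' @return A `cultsel_sweep_result`: list with `summary` (tidy tibble,
#'   one row per cell x time step) and `finals` (per-replicate final
#'   diversity and payoff, for confidence-interval and distributional
#'   checks), plus the grid.
#' @export
run_sweep <- function(grid, cells = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "cultsel_sweep_grid"))
  idx <- if (is.null(cells)) grid$cells$cell else as.integer(cells)
  n_rep <- grid$n_replicates
  n_row <- grid$n_steps + 1L
  summaries <- vector("list", length(idx))
  finals <- vector("list", length(idx))
  for (ci in seq_along(idx)) {
    cell <- idx[ci]
    row <- grid$cells[grid$cells$cell == cell, ]
    if (nrow(row) != 1) stop("unknown cell index: ", cell)
    if (verbose) {
      message(sprintf("cell %d/%d: b=%g t=%s N=%d sigma=%s (first seed %d)",
                      cell, grid$n_cells, row$payoff_bias, row$learner_type,
                      row$population_size,
                      ifelse(is.na(row$sigma), "-", row$sigma),
                      derive_seed(grid$base_seed, cell, 1L)))
    }
    div_sum <- numeric(n_row); div_sq <- numeric(n_row)
    pay_sum <- numeric(n_row); pay_sq <- numeric(n_row)
    fin_div <- numeric(n_rep); fin_pay <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      cfg <- cell_config(grid, row, derive_seed(grid$base_seed, cell, r))
      traj <- run_simulation(cfg)
      div_sum <- div_sum + traj$diversity
      div_sq <- div_sq + traj$diversity^2
      pay_sum <- pay_sum + traj$mean_payoff
      pay_sq <- pay_sq + traj$mean_payoff^2
      fin_div[r] <- traj$diversity[n_row]
      fin_pay[r] <- traj$mean_payoff[n_row]
    }
    se <- function(s, sq) {
      if (n_rep < 2) return(rep(NA_real_, n_row))
      var_hat <- pmax(0, (sq - s^2 / n_rep) / (n_rep - 1))
      sqrt(var_hat / n_rep)
    }
    summaries[[ci]] <- tibble::tibble(
      sweep_kind = grid$kind,
      payoff_bias = row$payoff_bias,
      learner_type = row$learner_type,
      population_size = row$population_size,
      sigma = row$sigma,
      time_step = 0:grid$n_steps,
      mean_diversity = div_sum / n_rep,
      se_diversity = se(div_sum, div_sq),
      mean_payoff = pay_sum / n_rep,
      se_payoff = se(pay_sum, pay_sq),
      n_replicates = n_rep
    )
    finals[[ci]] <- tibble::tibble(
      payoff_bias = row$payoff_bias,
      learner_type = row$learner_type,
      population_size = row$population_size,
      sigma = row$sigma,
      replicate = seq_len(n_rep),
      final_diversity = fin_div,
      final_payoff = fin_pay
    )
  }
  structure(
    list(summary = do.call(rbind, summaries),
         finals = do.call(rbind, finals),
         grid = grid),
    class = "cultsel_sweep_result"
  )
}

#' @export
print.cultsel_sweep_result <- function(x, ...) {
  cat(sprintf("<cultsel_sweep_result> %s sweep, %d cells x %d replicates\n",
              x$grid$kind, length(unique(paste(x$summary$payoff_bias,
                                               x$summary$learner_type,
                                               x$summary$population_size,
                                               x$summary$sigma))),
              x$grid$n_replicates))
  print(x$summary)
  invisible(x)
}
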