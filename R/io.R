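#' Write sweep results to disk
#'
#' Writes the tidy per-step summary as `<path>.csv` (columns:
#' `sweep_kind, payoff_bias, learner_type, population_size, sigma,
#' time_step, mean_diversity, se_diversity, mean_payoff, se_payoff,
#' n_replicates`) and a JSON sidecar `<path>.json` holding the full grid
#' configuration, base seed and package version, so the sweep can be
#' replayed exactly. Numbers are written in shortest round-trip form:
#' re-reading the CSV reproduces the in-memory aggregates bit for bit.
#'
#' @param result A [run_sweep()] result.
#' @param path Output path prefix (without extension).
#' @return Invisibly, the two file paths written.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "cultsel_sweep_result"))
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  readr::write_csv(result$summary, csv)
  grid <- result$grid
  meta <- list(
    kind = grid$kind,
    cells = as.data.frame(grid$cells),
    n_replicates = grid$n_replicates,
    n_steps = grid$n_steps,
    error_rate = grid$error_rate,
    pool_size = grid$pool_size,
    payoff_rate = grid$payoff_rate,
    base_seed = grid$base_seed,
    package_version = as.character(utils::packageVersion("cultsel"))
  )
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' Read a sweep summary back from disk
#'
#' @param path Path prefix used in [write_results()].
#' @return The summary tibble (with the JSON metadata attached as the
#'   `meta` attribute when the sidecar is present).
#' @export
read_results <- function(path) {
  csv <- paste0(path, ".csv")
  out <- readr::read_csv(
    csv,
    col_types = readr::cols(
      sweep_kind = readr::col_character(),
      learner_type = readr::col_character(),
      population_size = readr::col_integer(),
      time_step = readr::col_integer(),
      n_replicates = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  json <- paste0(path, ".json")
  if (file.exists(json)) attr(out, "meta") <- jsonlite::read_json(json)
  out
}

#' Replay a sweep from its JSON sidecar
#'
#' Rebuilds the grid recorded in a sidecar written by [write_results()]
#' and reruns it; with the recorded base seed the replay is bit-identical
#' to the original.
#'
#' @param json_path Path to the `.json` sidecar.
#' @return A `cultsel_sweep_result`.
#' @export
replay_sweep <- function(json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  cells <- meta$cells
  cells$payoff_bias <- as.numeric(cells$payoff_bias)
  cells$population_size <- as.integer(cells$population_size)
  # an unstructured sweep's sigma column is all-NA and may drop out of JSON
  cells$sigma <- if (is.null(cells$sigma)) NA_real_ else as.numeric(cells$sigma)
  if (meta$kind == "size") {
    grid <- build_sweep(
      "size",
      payoff_bias_levels = unique(cells$payoff_bias),
      learner_types = unique(cells$learner_type),
      population_sizes = unique(cells$population_size),
      n_replicates = meta$n_replicates, n_steps = meta$n_steps,
      error_rate = meta$error_rate, pool_size = meta$pool_size,
      payoff_rate = meta$payoff_rate, base_seed = meta$base_seed
    )
  } else {
    grid <- build_sweep(
      "structure",
      payoff_bias_levels = unique(cells$payoff_bias),
      learner_types = unique(cells$learner_type),
      sigmas = unique(cells$sigma),
      structured_population_size = unique(cells$population_size),
      n_replicates = meta$n_replicates, n_steps = meta$n_steps,
      error_rate = meta$error_rate, pool_size = meta$pool_size,
      payoff_rate = meta$payoff_rate, base_seed = meta$base_seed
    )
  }
  run_sweep(grid)
}
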