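make_state <- function(variants, pool) {
  structure(list(variants = as.integer(variants), pool = as.integer(pool)),
            class = "cultsel_state")
}

test_that("sequential updating lets later agents copy already-updated ones", {
  # two uncritical copiers, no error: agent 0 copies agent 1's initial
  # variant, then agent 1 copies agent 0's new variant, so both end the
  # step holding agent 1's initial variant
  cfg <- simulation_config(payoff_bias = 0, learner_type = "copier",
                           population_size = 2, error_rate = 0, pool_size = 10)
  st <- make_state(c(3, 7), rep(1, 10))
  set.seed(1)
  out <- run_time_step(st, cfg)
  expect_identical(out$variants, c(7L, 7L))
})

test_that("uncritical maintainers with no error are a fixed point", {
  cfg <- simulation_config(payoff_bias = 0, learner_type = "maintainer",
                           population_size = 8, error_rate = 0, pool_size = 20,
                           n_steps = 50, seed = 5)
  traj <- run_simulation(cfg)
  expect_equal(length(unique(traj$diversity)), 1)
  expect_equal(length(unique(traj$mean_payoff)), 1)
  states <- attr(traj, "states")
  expect_true(all(states == rep(states[1, ], each = nrow(states))))
})

test_that("a time step conserves population size and pool closure", {
  cfg <- simulation_config(payoff_bias = 0.5, learner_type = "innovator",
                           population_size = 15, pool_size = 25, n_steps = 40,
                           seed = 6)
  traj <- run_simulation(cfg)
  states <- attr(traj, "states")
  expect_equal(dim(states), c(41, 15))
  expect_true(all(states >= 0 & states < 25))
  expect_identical(attr(traj, "pool"), attr(traj, "final_state")$pool)
})

test_that("zero steps yield only the initial record", {
  cfg <- simulation_config(payoff_bias = 1, learner_type = "copier",
                           population_size = 5, n_steps = 0, seed = 7)
  traj <- run_simulation(cfg)
  expect_equal(nrow(traj), 1)
  expect_equal(traj$time_step, 0)
})

test_that("identical seed and config give bit-identical trajectories", {
  cfg <- simulation_config(payoff_bias = 0.4, learner_type = "maintainer",
                           population_size = 20, n_steps = 60, seed = 123)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(attr(a, "states"), attr(b, "states"))
  expect_identical(a$diversity, b$diversity)
  expect_identical(a$mean_payoff, b$mean_payoff)
})

test_that("compiled and reference engines consume the same random stream", {
  for (lt in c("copier", "innovator", "maintainer")) {
    for (sg in list(NULL, 2)) {
      cfg <- simulation_config(payoff_bias = 0.4, learner_type = lt,
                               population_size = 12, structure_sigma = sg,
                               n_steps = 25, seed = 99)
      expect_identical(attr(run_simulation(cfg, engine = "cpp"), "states"),
                       attr(run_simulation(cfg, engine = "r"), "states"))
    }
  }
  # and with re-randomised update order
  cfg <- simulation_config(payoff_bias = 0.3, learner_type = "copier",
                           population_size = 9, n_steps = 25, seed = 42,
                           shuffle_order = TRUE)
  expect_identical(attr(run_simulation(cfg, engine = "cpp"), "states"),
                   attr(run_simulation(cfg, engine = "r"), "states"))
})

test_that("the critical branch fires at rate b", {
  # maintainers only consult a model when critical, so counting selector
  # calls counts critical updates
  cfg <- simulation_config(payoff_bias = 0.2, learner_type = "maintainer",
                           population_size = 10, n_steps = 100, pool_size = 20)
  calls <- new.env()
  calls$n <- 0L
  counting_selector <- function(agent_index) {
    calls$n <- calls$n + 1L
    select_model_unstructured(agent_index, 10)
  }
  set.seed(8)
  pool <- generate_payoff_pool(20)
  st <- initialize_population(cfg, pool)
  for (t in 1:100) st <- run_time_step(st, cfg, counting_selector)
  expect_freq(calls$n, 1000, 0.2, k = 4)
})

test_that("at full payoff bias learner type is irrelevant", {
  trajs <- lapply(c("copier", "innovator", "maintainer"), function(lt) {
    cfg <- simulation_config(payoff_bias = 1, learner_type = lt,
                             population_size = 10, n_steps = 50, seed = 11)
    attr(run_simulation(cfg), "states")
  })
  expect_identical(trajs[[1]], trajs[[2]])
  expect_identical(trajs[[1]], trajs[[3]])
})

test_that("pure innovators hold pool-mean payoff in expectation", {
  # every update resamples uniformly from the pool, so at any step the
  # population's expected mean payoff equals the pool's mean payoff
  set.seed(9)
  n_rep <- 300
  diffs <- vapply(seq_len(n_rep), function(r) {
    cfg <- simulation_config(payoff_bias = 0, learner_type = "innovator",
                             population_size = 20, error_rate = 0,
                             n_steps = 10, seed = 5000 + r)
    traj <- run_simulation(cfg)
    traj$mean_payoff[nrow(traj)] - mean(attr(traj, "pool"))
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(n_rep))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simulation_config(payoff_bias = 1.2, learner_type = "copier",
                                 population_size = 10), "payoff_bias")
  expect_error(simulation_config(payoff_bias = 0.5, learner_type = "copier",
                                 population_size = 1), "population_size")
  expect_error(simulation_config(payoff_bias = 0.5, learner_type = "copier",
                                 population_size = 10, error_rate = -0.1),
               "error_rate")
  expect_error(simulation_config(payoff_bias = 0.5, learner_type = "copier",
                                 population_size = 10, structure_sigma = 0),
               "structure_sigma")
  expect_error(simulation_config(payoff_bias = 0.5, learner_type = "zealot",
                                 population_size = 10))
})

test_that("configs round-trip through YAML files with flag overrides", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("payoff_bias: 0.4", "learner_type: maintainer",
               "population_size: 50", "n_steps: 20", "seed: 3"), f)
  cfg <- read_config(f)
  expect_equal(cfg$payoff_bias, 0.4)
  expect_equal(cfg$population_size, 50L)
  cfg2 <- read_config(f, overrides = list(payoff_bias = 0.8))
  expect_equal(cfg2$payoff_bias, 0.8)
  expect_equal(cfg2$learner_type, "maintainer")
})
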