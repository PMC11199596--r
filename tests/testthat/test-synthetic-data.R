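# The synthetic-data generator: design shapes, determinism, degenerate
# noise, moment convergence, and the analytic expected LLOQ.

test_that("curve design emits the closed-form row count", {
  cfg <- small_config(designs = "curve", matrices = "tissue",
                      dropout_threshold = 0, interference_rate = 0)
  sim <- simulate_panel(cfg, seed = 1)
  # peptides x 2 labels x transitions x (8 levels x 3 reps + 3 blanks)
  expect_equal(nrow(sim$records), 6L * 2L * 3L * (8L * 3L + 3L))
  cfg2 <- simulation_config(designs = "curve", matrices = "tissue",
                            dropout_threshold = 0, interference_rate = 0)
  sim2 <- simulate_panel(cfg2, seed = 1)
  expect_equal(nrow(sim2$records), 43L * 2L * 3L * (8L * 3L + 3L))
})

test_that("the generator is deterministic under seed", {
  cfg <- small_config()
  a <- simulate_panel(cfg, seed = 123)
  b <- simulate_panel(cfg, seed = 123)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$peptides, b$truth$peptides)
  c <- simulate_panel(cfg, seed = 124)
  expect_false(identical(a$records$area, c$records$area))
})

test_that("zero-variance simulation produces identical replicates", {
  sim <- simulate_panel(noiseless_config(designs = c("curve",
                                                     "repeatability"),
                                         matrices = "tissue",
                                         panel_size = 4L), seed = 2)
  m <- summarize_measurements(sim$records[sim$records$design ==
                                            "repeatability", ])
  spread <- tapply(m$par, paste(m$peptide_id, m$spike_level),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("within-day CV of simulated ratios converges to the configured
           multiplicative CV", {
  cfg <- simulation_config(panel_size = 1L, designs = "repeatability",
                           matrices = "tissue", repeat_days = 1L,
                           repeat_reps = 1000L,
                           repeat_levels = c(medium = 200),
                           noise_floor = c(tissue = 0, plasma = 0, cell = 0),
                           interference_rate = 0, sigma_transition = 0)
  sim <- simulate_panel(cfg, seed = 3)
  m <- summarize_measurements(sim$records)
  cv_target <- 100 * sqrt(exp((log(2) * cfg$sigma_intra)^2) - 1)
  cv_obs <- 100 * sd(m$par) / mean(m$par)
  expect_lt(abs(cv_obs - cv_target) / cv_target, 0.10)
})

test_that("expected LLOQ follows the predicted-CV crossing rule", {
  cfg <- simulation_config(panel_size = 1L,
                           noise_floor = c(tissue = 0, plasma = 0,
                                           cell = 0))
  sim <- simulate_panel(cfg, seed = 4)
  pep <- sim$truth$peptides$peptide_id[1]
  # no additive noise and ~6% multiplicative CV: lowest designed level
  expect_equal(expected_lloq(sim$truth, pep, "tissue"), 0.205)

  # construct a noise floor so the additive CV alone is ~25% at 0.512 and
  # ~12.5% at 1.28 for this peptide: crossing lands on 1.28
  rf <- sim$truth$peptides$response_factor[1]
  nf <- 0.25 * rf * 0.512 / sqrt(cfg$n_transitions)
  sim$truth$config$noise_floor["tissue"] <- nf
  expect_equal(expected_lloq(sim$truth, pep, "tissue"), 1.28)
})

test_that("interference marks transitions that the screen then removes", {
  cfg <- small_config(designs = "endogenous", matrices = "tissue",
                      interference_rate = 0.4)
  sim <- simulate_panel(cfg, seed = 6)
  m <- summarize_measurements(sim$records)
  frag <- sim$truth$fragments
  n_interfered <- tapply(frag$interfered, frag$peptide_id, sum)
  for (p in names(n_interfered)) {
    rows <- m[m$peptide_id == p & m$n_used + m$n_excluded == 3, ]
    if (nrow(rows) == 0) next
    expect_true(all(rows$n_excluded >= n_interfered[[p]]))
  }
  # clean-data control: nothing excluded
  clean <- simulate_panel(small_config(designs = "endogenous",
                                       matrices = "tissue",
                                       interference_rate = 0,
                                       noise_floor = c(tissue = 0,
                                                       plasma = 0,
                                                       cell = 0)),
                          seed = 6)
  mc <- summarize_measurements(clean$records)
  expect_true(all(mc$n_excluded == 0))
})

test_that("impossible designs are rejected", {
  expect_error(simulation_config(curve_reps = 0L), "replicates|not TRUE")
  expect_error(simulation_config(sigma_intra = -1), "not TRUE")
  expect_error(simulation_config(n_transitions = 1L), "not TRUE")
})
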