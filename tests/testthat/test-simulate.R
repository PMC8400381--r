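# Short simulations are enough for unit checks; the acceptance suite runs
# the documented defaults (2000 steps, 50 runs, burn-in 500).
SIM <- list(steps = 600L, runs = 20L, burn_in = 200L)

test_that("run_stochastic is reproducible and validates inputs", {
  m <- ra_model()
  a <- run_stochastic(m, doses = c(TNF = 0.5), steps = SIM$steps,
                      runs = SIM$runs, burn_in = SIM$burn_in, seed = 11)
  b <- run_stochastic(m, doses = c(TNF = 0.5), steps = SIM$steps,
                      runs = SIM$runs, burn_in = SIM$burn_in, seed = 11)
  expect_identical(a$activity, b$activity)
  expect_identical(a$stderr, b$stderr)

  expect_error(run_stochastic(m, doses = c(TNF = 1.5)), "\\[0, 1\\]")
  expect_error(run_stochastic(m, doses = c(NOPE = 1)), "unknown")
  expect_error(run_stochastic(m, steps = 100, burn_in = 100), "burn_in")
  expect_error(run_stochastic(m, doses = c(MAPK14 = 1),
                              perturbation = c(MAPK14 = 0L)),
               "dosed and clamped")
})

test_that("all-zero dosing keeps every variable off", {
  m <- ra_model()
  est <- run_stochastic(m, doses = c(TNF = 0, IL6 = 0, TGFB1 = 0),
                        steps = SIM$steps, runs = 5,
                        burn_in = SIM$burn_in, seed = 1)
  expect_true(all(est$activity == 0))
})

test_that("Boolean doses converge to the matching fixed point", {
  m <- ra_model()
  # unique fixed point under TNF=1, IL6=1, TGFB1=1
  clamped <- apply_perturbation(m, c(TNF = 1L, IL6 = 1L, TGFB1 = 1L))
  fp <- stable_states(clamped)
  expect_equal(nrow(fp), 1)
  est <- run_stochastic(m, doses = c(TNF = 1, IL6 = 1, TGFB1 = 1),
                        steps = 2000, runs = 10, burn_in = 500, seed = 2)
  expect_true(all(abs(est$activity - as.numeric(fp[1, names(est$activity)]))
                  <= 0.02))

  # and under all inputs 0, the all-zero fixed point absorbs
  clamped0 <- apply_perturbation(m, c(TNF = 0L, IL6 = 0L, TGFB1 = 0L))
  fp0 <- stable_states(clamped0)
  expect_equal(nrow(fp0), 1)
  expect_true(all(fp0 == 0))
})

test_that("dose_response endpoints match run_stochastic and validate", {
  m <- ra_model()
  dr <- dose_response(m, "TGFB1", grid = c(0, 1),
                      base = c(TNF = 0, IL6 = 0),
                      steps = SIM$steps, runs = SIM$runs,
                      burn_in = SIM$burn_in, seed = 5)
  lo <- run_stochastic(m, doses = c(TNF = 0, IL6 = 0, TGFB1 = 0),
                       steps = SIM$steps, runs = SIM$runs,
                       burn_in = SIM$burn_in, seed = 5)
  hi <- run_stochastic(m, doses = c(TNF = 0, IL6 = 0, TGFB1 = 1),
                       steps = SIM$steps, runs = SIM$runs,
                       burn_in = SIM$burn_in, seed = 6)
  expect_identical(dr$estimates[[1]]$activity, lo$activity)
  expect_identical(dr$estimates[[2]]$activity, hi$activity)

  df <- as.data.frame(dr)
  expect_equal(nrow(df), 2 * length(m$variables))

  expect_error(dose_response(m, "MAPK14", grid = c(0, 1),
                             perturbation = c(MAPK14 = 0L)), "clamped")
  expect_error(dose_response(m, "TNF", grid = c(1, 0)), "ascending")
})

test_that("sensitivity_grid is consistent with dose_response", {
  m <- ra_model()
  grid <- c(0, 1)
  sens <- sensitivity_grid(m, "IL6", "TGFB1", grid = grid,
                           clamped = c(TNF = 0L),
                           steps = SIM$steps, runs = SIM$runs,
                           burn_in = SIM$burn_in, seed = 9)
  jun <- sensitivity_matrix(sens, "JUN")
  expect_equal(dim(jun), c(2, 2))
  expect_equal(jun[1, 1], 0)  # both inputs off, TNF clamped: all off

  # cell (1.0, 0.0) equals the matching single-input run
  single <- run_stochastic(m, doses = c(IL6 = 1, TGFB1 = 0),
                           perturbation = c(TNF = 0L),
                           steps = SIM$steps, runs = SIM$runs,
                           burn_in = SIM$burn_in,
                           seed = 9 + 1 * length(grid) + 0)
  expect_identical(sens$estimates[[2]][[1]]$activity, single$activity)

  expect_error(sensitivity_grid(m, "IL6", "IL6", grid = grid), "differ")
  expect_error(sensitivity_grid(m, "IL6", "TNF", grid = grid,
                                clamped = c(TNF = 0L)), "clamped")
})
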