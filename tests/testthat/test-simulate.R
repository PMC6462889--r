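test_that("noise-free simulation is deterministic and reaches the closed-form plateau", {
  m <- n1_model(
    n1_design(1, 1, 10, sampling_times = seq(1, 10, 0.5), dt = 0.01),
    treatment_profile(5, 0.01, 0.01),
    outcome_model(3, sensitivity = 50))
  tr1 <- simulate(m, seed = 1)
  tr2 <- simulate(m, seed = 2)
  expect_identical(tr1$state, tr2$state)        # no stochastic component
  obs <- observations(tr1)
  expect_equal(obs$value, rep(8, nrow(obs)), tolerance = 1e-3)
  # with all noise off and numeric outcome, observations equal the state
  idx <- round(obs$time / 0.01) + 1
  expect_identical(obs$value, tr1$state[idx])
})

test_that("traces are reproducible from their seed and differ across seeds", {
  m <- hypertension_study()
  a <- simulate(m, seed = 77)
  b <- simulate(m, seed = 77)
  expect_identical(a$state, b$state)
  expect_identical(a$observations, b$observations)
  c <- simulate(m, seed = 78)
  expect_false(identical(a$observations$value, c$observations$value))
})

test_that("noise sub-streams are independent: toggling one source leaves others unchanged", {
  m <- hypertension_study()
  m0 <- m; m0$outcome$sigma_o <- 0
  with_obs <- simulate(m, seed = 11)
  without_obs <- simulate(m0, seed = 11)
  expect_identical(with_obs$baseline, without_obs$baseline)
  expect_identical(with_obs$state, without_obs$state)
  expect_false(identical(with_obs$observations$value,
                         without_obs$observations$value))
})

test_that("latent effects approach their asymptotes monotonically and superpose", {
  m <- n1_model(
    n1_design(2, 2, 30, block_orders = list(c(1, 2), c(1, 2)), dt = 0.1),
    list(treatment_profile(-40, 6, 3), treatment_profile(-30, 2, 10)),
    outcome_model(160, 0.5))
  tr <- simulate(m, seed = 3)
  X <- tr$effects
  i_per1 <- which(tr$times >= 0 & tr$times < 30)
  # wash-in: treatment 1 decays toward -40, monotone, never beyond
  expect_true(all(diff(X[i_per1, 1]) <= 0))
  expect_true(all(X[, 1] > -40))
  # wash-out in period 2: decays back toward 0, monotone
  i_per2 <- which(tr$times >= 30 & tr$times < 60)
  expect_true(all(diff(X[i_per2, 1]) >= 0))
  # target superposes baseline and both treatment effects (carryover overlaps)
  expect_equal(tr$target, tr$baseline + X[, 1] + X[, 2])
  expect_true(any(X[i_per2, 1] < -1 & X[i_per2, 2] < -1))
})

test_that("full trajectory of the exact stepper matches fine-step Euler integration", {
  # one wash-in period then one wash-out period
  m <- n1_model(
    n1_design(1, 2, 3, block_orders = list(c(2, 1)), dt = 0.1),
    list(treatment_profile(0, 1, 1), treatment_profile(-40, 6, 3)),
    outcome_model(0, 10))
  tr <- simulate(m, seed = 1)
  at <- function(t) tr$effects[round(t / 0.1) + 1, 2]
  expect_equal(at(3), euler_effect(0, -40, 6, 3, TRUE, 3), tolerance = 5e-3)
  x_end <- euler_effect(euler_effect(0, -40, 6, 3, TRUE, 3), -40, 6, 3,
                        FALSE, 3)
  expect_equal(at(6), x_end, tolerance = 5e-3)
})

test_that("the blood-pressure study yields 120 daily observations ordered by efficacy", {
  m <- hypertension_study(block_orders = list(c(1, 2), c(1, 2)))
  tr <- simulate(m, seed = 12)
  obs <- observations(tr)
  expect_equal(nrow(obs), 120L)
  expect_equal(sort(unique(obs$treatment)), c(1L, 2L))
  # treatment 1 lowers blood pressure 10 points more in the long run
  expect_lt(mean(obs$value[obs$treatment == 1]),
            mean(obs$value[obs$treatment == 2]))
})

test_that("model assembly validates treatment count and profile types", {
  d <- n1_design(1, 2, 10)
  o <- outcome_model(0, 1)
  expect_error(n1_model(d, list(), o), "at least one")
  expect_error(n1_model(d, list(treatment_profile(1, 1, 1)), o),
               "2 treatments but 1")
  expect_error(n1_model(d, list(treatment_profile(1, 1, 1), "x"), o),
               "treatment_profile")
  expect_error(treatment_profile(1, -1, 1), "wash_in_tau")
  expect_error(treatment_profile(1, 1, 0), "wash_out_gamma")
  expect_error(outcome_model(0, 0), "sensitivity")
  expect_error(outcome_model(0, 1, sigma_p = -1), "sigma_p")
  expect_error(outcome_model(0, 1, outcome_type = "score"), "outcome_max")
})

test_that("tidy data frame export carries the latent columns and observations", {
  m <- instant_model(0, 4, n_blocks = 1, period_length = 3, sigma_o = 0)
  tr <- simulate(m, seed = 6)
  df <- as.data.frame(tr)
  expect_named(df, c("time_day", "block", "treatment", "X_total",
                     "baseline", "Z_true", "Y_observed"))
  expect_equal(sum(!is.na(df$Y_observed)), nrow(observations(tr)))
  df2 <- as.data.frame(tr, latent = FALSE)
  expect_false(any(c("X_total", "Z_true") %in% names(df2)))
})
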