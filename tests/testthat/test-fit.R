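test_that("noise-free instantaneous data are interpolated exactly", {
  m <- instant_model(0, 10, n_blocks = 2, period_length = 6)
  # the fit is exact by construction, so lm warns about a perfect fit
  fit <- suppressWarnings(n1_fit(observations(simulate(m, seed = 1))))
  expect_equal(fit$contrasts$estimate, 10, tolerance = 1e-6)
  expect_lt(fit$contrasts$p_value, 1e-12)
  expect_true(fit$significant)
})

test_that("coefficients equal the normal-equations oracle to 1e-10", {
  # hand-built 12-row table: 2 treatments x 2 blocks, deterministic values
  d <- data.frame(
    block = rep(1:2, each = 6),
    treatment = rep(c(1, 1, 1, 2, 2, 2), 2),
    value = c(3.1, 2.7, 3.4, 9.2, 8.8, 9.9, 4.0, 3.6, 4.4, 10.8, 10.1, 11.0))
  fit <- n1_fit(d)

  X <- cbind(1, as.numeric(d$treatment == 2), as.numeric(d$block == 2))
  beta <- ols_oracle(X, d$value)
  expect_equal(fit$contrasts$estimate, beta[2], tolerance = 1e-10)
  expect_equal(unname(coef(fit$lm)), as.numeric(beta), tolerance = 1e-10)

  # classical standard error from the oracle pieces
  res <- d$value - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(s2 * solve(crossprod(X))[2, 2])
  expect_equal(fit$contrasts$std_error, se, tolerance = 1e-10)
  expect_equal(fit$contrasts$p_value,
               2 * pt(abs(beta[2] / se), df = 9, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("treatment contrasts are shift-invariant and scale-equivariant", {
  m <- instant_model(0, 7, sigma_o = 2)
  obs <- observations(simulate(m, seed = 9))
  base <- n1_fit(obs)$contrasts$estimate
  shifted <- obs; shifted$value <- shifted$value + 100
  scaled <- obs; scaled$value <- scaled$value * 3
  expect_equal(n1_fit(shifted)$contrasts$estimate, base, tolerance = 1e-10)
  expect_equal(n1_fit(scaled)$contrasts$estimate, 3 * base, tolerance = 1e-10)
})

test_that("degenerate regression inputs raise informative errors", {
  one_trt <- data.frame(block = 1, treatment = 1, value = rnorm(5))
  expect_error(n1_fit(one_trt), "two treatments")
  # a block confounded with a treatment makes the design rank-deficient
  conf <- data.frame(block = rep(1:2, each = 4),
                     treatment = rep(1:2, each = 4), value = rnorm(8))
  expect_error(n1_fit(conf), "rank-deficient")
  tiny <- data.frame(block = c(1, 1, 2), treatment = c(1, 2, 2),
                     value = rnorm(3))
  expect_error(n1_fit(tiny), "fewer observations|rank-deficient")
  expect_error(n1_fit(data.frame(treatment = 1:2)), "lacks column")
  expect_error(n1_fit(one_trt, level = 1.5), "level")
})

test_that("fit methods expose estimates, intervals and predictions", {
  m <- instant_model(0, 10, sigma_o = 1)
  fit <- n1_fit(observations(simulate(m, seed = 4)))
  expect_named(coef(fit), "treatment2")
  ci <- confint(fit)
  expect_equal(nrow(ci), 1)
  expect_true(ci[1] < fit$contrasts$estimate &&
              fit$contrasts$estimate < ci[2])
  pr <- predict(fit, newdata = data.frame(treatment = c(1, 2), block = 1))
  expect_equal(unname(diff(pr)), fit$contrasts$estimate, tolerance = 1e-10)
  expect_length(residuals(fit), fit$n_obs)
  expect_output(print(fit), "treatment 2 vs 1")
})

test_that("median differencing applies the threshold rule over per-block medians", {
  # five blocks whose (interest, comparator) medians are
  # (2,4) (2,4) (3,4) (3,4) (4,4): four blocks meet the 1-point rule
  vals <- list(c(2, 4), c(2, 4), c(3, 4), c(3, 4), c(4, 4))
  d <- do.call(rbind, lapply(seq_along(vals), function(b)
    data.frame(time = c(b, b + 0.5), block = b, treatment = c(1L, 2L),
               value = vals[[b]])))
  md <- median_differencing(d, 1, 2, point_threshold = 1, required_blocks = 4)
  expect_equal(md$count, 4)
  expect_true(md$recommended)
  expect_equal(md$per_block$difference, c(2, 2, 1, 1, 0))

  # identical data under both labels: nothing qualifies
  d2 <- d; d2$value <- 3
  md2 <- median_differencing(d2, 1, 2, 1, 4)
  expect_equal(md2$count, 0)
  expect_false(md2$recommended)

  # vacuous rule always recommends
  expect_true(median_differencing(d2, 1, 2, point_threshold = 0,
                                  required_blocks = 0)$recommended)

  # a tie with the threshold counts as meeting it
  md3 <- median_differencing(d, 1, 2, point_threshold = 2,
                             required_blocks = 2)
  expect_equal(md3$count, 2)
})

test_that("median differencing depends only on per-block medians", {
  set.seed(55)
  d <- do.call(rbind, lapply(1:5, function(b)
    data.frame(time = seq(0.1, 1.4, 0.1) + 2 * (b - 1), block = b,
               treatment = rep(1:2, each = 7),
               value = c(rnorm(7, 2), rnorm(7, 4)))))
  base <- median_differencing(d, 1, 2, 1, 4)
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(median_differencing(shuffled, 1, 2, 1, 4)$count, base$count)
})

test_that("the analysis window keeps only each period's tail", {
  m <- pain_study()
  obs <- observations(simulate(m, seed = 8))
  kept <- n1sim:::filter_period_tail(obs, 7)
  expect_equal(nrow(kept), 70)  # last 7 of 14 days, 10 periods
  # every kept time is within 7 days of its period's end (multiples of 14)
  expect_true(all((ceiling(kept$time / 14) * 14 - kept$time) <= 7))
  # missing treatment in a block is reported with the block id
  sub <- obs[!(obs$block == 3 & obs$treatment == 1), ]
  expect_error(median_differencing(sub, 1, 2, 1, 4), "block 3")
})
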