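# Independent oracles used across tests.

# Forward-Euler integration of the treatment-effect kinetics
#   dx/dt = (E - x)/tau          while administered
#   dx/dt = -x/gamma             while washed out
# kept deliberately naive (fixed fine step) so it is independent of the
# closed-form stepper it checks.
euler_effect <- function(x0, effect, tau, gamma, active, t_end,
                         dt = 1e-4) {
  x <- x0
  for (i in seq_len(round(t_end / dt))) {
    x <- if (active) x + (effect - x) / tau * dt else x - x / gamma * dt
  }
  x
}

# Normal-equations OLS oracle: beta = (X'X)^{-1} X'y.
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

# A tiny noise-free, fast-dynamics two-treatment model: the observed
# contrast equals effect2 - effect1 up to negligible carryover.
instant_model <- function(effect1 = 0, effect2 = 10, n_blocks = 2,
                          period_length = 5, sigma_o = 0, sigma_p = 0,
                          sigma_b = 0) {
  design <- n1_design(n_blocks, 2, period_length,
                      block_orders = rep(list(c(1L, 2L)), n_blocks),
                      sampling_times = seq_len(n_blocks * 2 * period_length),
                      dt = 1)
  n1_model(design,
           list(treatment_profile(effect1, 0.01, 0.01),
                treatment_profile(effect2, 0.01, 0.01)),
           outcome_model(0, sensitivity = 50, sigma_b = sigma_b,
                         sigma_p = sigma_p, sigma_o = sigma_o))
}
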