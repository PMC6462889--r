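#' One step of the latent treatment-effect dynamics
#'
#' Advances one treatment's latent effect `x` by `dt` days using the exact
#' solution of the linear kinetics on an interval where the administration
#' indicator is constant: while active the effect decays toward the
#' asymptote `E` with time constant `tau`; while inactive it decays toward
#' zero with time constant `gamma`.
#'
#' @param x Current latent effect.
#' @param profile A [treatment_profile()].
#' @param active Logical; is the treatment administered during this step?
#' @param dt Step length, days.
#' @return The effect after `dt` days.
#' @export
treatment_effect_step <- function(x, profile, active, dt) {
  stopifnot(dt > 0)
  if (active)
    profile$effect + (x - profile$effect) * exp(-dt / profile$wash_in_tau)
  else
    x * exp(-dt / profile$wash_out_gamma)
}

#' One step of the baseline Wiener process
#'
#' Adds a Gaussian increment of mean zero and variance `sigma_b^2 * dt` to
#' the baseline, the discretization of a Wiener process with diffusion
#' scale `sigma_b`.
#'
#' @param b Current baseline.
#' @param sigma_b Drift scale, outcome units per sqrt(day); >= 0.
#' @param dt Step length, days.
#' @return The baseline after `dt` days.
#' @export
baseline_step <- function(b, sigma_b, dt) {
  stopifnot(dt > 0, sigma_b >= 0)
  b + stats::rnorm(1L, 0, sigma_b * sqrt(dt))
}

#' One step of the true outcome state
#'
#' The true state relaxes toward the target `q` (baseline plus total
#' treatment effect) at rate `alpha`: the deterministic part of the update
#' is `q + (z - q) * exp(-alpha * dt)`, to which a Gaussian process-noise
#' increment of variance `sigma_p^2 * dt` is added.
#'
#' @param z Current true state.
#' @param q Current target, `B(t) + sum_j X_j(t)`.
#' @param alpha Relaxation rate (sensitivity to treatment effect), 1/day.
#' @param sigma_p Process-noise scale; >= 0.
#' @param dt Step length, days.
#' @return The true state after `dt` days.
#' @export
outcome_step <- function(z, q, alpha, sigma_p, dt) {
  stopifnot(dt > 0, alpha > 0, sigma_p >= 0)
  q + (z - q) * exp(-alpha * dt) + stats::rnorm(1L, 0, sigma_p * sqrt(dt))
}

#' Observe the true state with instrument noise
#'
#' @param z True state value(s).
#' @param sigma_o Observation-noise standard deviation; >= 0.
#' @return `z` plus independent Gaussian noise of standard deviation
#'   `sigma_o`.
#' @export
observe_outcome <- function(z, sigma_o) {
  stopifnot(sigma_o >= 0)
  z + stats::rnorm(length(z), 0, sigma_o)
}

#' Transform a continuous observation to the requested outcome type
#'
#' Maps the noisy continuous observation `y` onto the outcome scale:
#' \describe{
#'   \item{numeric}{identity;}
#'   \item{score}{`round(y)` truncated into `[0, outcome_max]`;}
#'   \item{count}{a Poisson draw with rate `exp(y)`;}
#'   \item{proportion}{a Binomial(`outcome_max`, p) draw with
#'     `p = plogis(y)`;}
#'   \item{binary}{a Bernoulli draw with `p = plogis(y)`.}
#' }
#'
#' @param y Numeric vector of continuous observations.
#' @param outcome_type One of `"numeric"`, `"score"`, `"count"`,
#'   `"proportion"`, `"binary"`.
#' @param outcome_max Range bound M; required for `"score"` and
#'   `"proportion"`.
#' @return Numeric (or integer) vector on the outcome scale.
#' @export
transform_outcome <- function(y, outcome_type, outcome_max = NULL) {
  outcome_type <- match.arg(outcome_type, OUTCOME_TYPES)
  if (outcome_type %in% c("score", "proportion") && is.null(outcome_max))
    stop(sprintf("`outcome_max` is required for outcome_type \"%s\"",
                 outcome_type), call. = FALSE)
  switch(outcome_type,
    numeric = y,
    score = pmin(pmax(round(y), 0), outcome_max),
    count = stats::rpois(length(y), lambda = exp(y)),
    proportion = stats::rbinom(length(y), size = outcome_max,
                               prob = stats::plogis(y)),
    binary = stats::rbinom(length(y), size = 1L, prob = stats::plogis(y)))
}
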