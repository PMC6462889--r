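#' Treatment pharmacodynamic profile
#'
#' Each treatment's latent effect follows first-order kinetics: while the
#' treatment is administered the effect decays exponentially toward its
#' asymptote `effect` with wash-in time constant `wash_in_tau`; when it is
#' discontinued the effect decays back toward zero with wash-out time
#' constant `wash_out_gamma`. A slow wash-out produces carryover into the
#' following treatment period.
#'
#' @param effect Asymptotic effect size (E), outcome units. The long-run
#'   change from baseline under continued administration.
#' @param wash_in_tau Wash-in (run-in) time constant (tau), days; > 0.
#' @param wash_out_gamma Wash-out time constant (gamma), days; > 0.
#' @return An object of class `"n1_treatment"`.
#' @examples
#' treatment_profile(effect = -40, wash_in_tau = 6, wash_out_gamma = 3)
#' @export
treatment_profile <- function(effect, wash_in_tau, wash_out_gamma) {
  if (!is.finite(effect))
    stop("`effect` must be a finite number", call. = FALSE)
  if (!is.finite(wash_in_tau) || wash_in_tau <= 0)
    stop("`wash_in_tau` must be > 0", call. = FALSE)
  if (!is.finite(wash_out_gamma) || wash_out_gamma <= 0)
    stop("`wash_out_gamma` must be > 0", call. = FALSE)
  structure(list(effect = effect, wash_in_tau = wash_in_tau,
                 wash_out_gamma = wash_out_gamma),
            class = "n1_treatment")
}

#' @export
print.n1_treatment <- function(x, ...) {
  cat(sprintf("treatment profile: E = %g, wash-in tau = %g d, wash-out gamma = %g d\n",
              x$effect, x$wash_in_tau, x$wash_out_gamma))
  invisible(x)
}

OUTCOME_TYPES <- c("numeric", "score", "count", "proportion", "binary")

#' Outcome and noise model for a simulated patient
#'
#' Describes the patient-side parameters of the stochastic time-series
#' model: the initial baseline, the rate at which the true outcome state
#' tracks the baseline-plus-treatment target, the three noise sources, and
#' the type of the observed outcome.
#'
#' The true state `Z(t)` relaxes toward the target `Q(t) = B(t) + sum_j
#' X_j(t)` at rate `sensitivity` (units 1/day): over one step `dt` the gap
#' shrinks by `exp(-sensitivity * dt)`, and a Gaussian process-noise
#' increment of variance `sigma_p^2 * dt` is added. The baseline `B(t)` is
#' a discretized Wiener process with increment variance `sigma_b^2 * dt`.
#' Observations add Gaussian instrument noise with standard deviation
#' `sigma_o`, then apply the outcome-type transformation (see
#' [transform_outcome()]).
#'
#' @param baseline_init Initial baseline (and initial true state), outcome
#'   units. The patient starts untreated at this level.
#' @param sensitivity Relaxation rate of the true state toward its target
#'   (alpha), 1/day; > 0. Large values (e.g. 10) give near-instantaneous
#'   response to treatment changes; small values give a sluggish response.
#' @param sigma_b Baseline drift scale, outcome units per sqrt(day); >= 0.
#' @param sigma_p Process-noise scale (short-term biological fluctuation),
#'   outcome units per sqrt(day); >= 0.
#' @param sigma_o Observation-noise standard deviation (instrument error),
#'   outcome units; >= 0.
#' @param outcome_type One of `"numeric"`, `"score"`, `"count"`,
#'   `"proportion"`, `"binary"`.
#' @param outcome_max Upper bound M of the outcome range; required for
#'   `"score"` (range 0..M) and `"proportion"` (Binomial size M).
#' @return An object of class `"n1_outcome"`.
#' @examples
#' outcome_model(baseline_init = 160, sensitivity = 0.5,
#'               sigma_b = 0.9, sigma_p = 1, sigma_o = 4)
#' @export
outcome_model <- function(baseline_init, sensitivity, sigma_b = 0,
                          sigma_p = 0, sigma_o = 0,
                          outcome_type = "numeric", outcome_max = NULL) {
  if (!is.finite(baseline_init))
    stop("`baseline_init` must be a finite number", call. = FALSE)
  if (!is.finite(sensitivity) || sensitivity <= 0)
    stop("`sensitivity` must be > 0", call. = FALSE)
  for (nm in c("sigma_b", "sigma_p", "sigma_o")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0)
      stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  }
  outcome_type <- match.arg(outcome_type, OUTCOME_TYPES)
  if (outcome_type %in% c("score", "proportion")) {
    if (is.null(outcome_max))
      stop(sprintf("`outcome_max` is required for outcome_type \"%s\"",
                   outcome_type), call. = FALSE)
    outcome_max <- as.integer(outcome_max)
    if (is.na(outcome_max) || outcome_max < 1)
      stop("`outcome_max` must be a positive integer", call. = FALSE)
  } else {
    outcome_max <- NULL
  }
  structure(list(baseline_init = baseline_init, sensitivity = sensitivity,
                 sigma_b = sigma_b, sigma_p = sigma_p, sigma_o = sigma_o,
                 outcome_type = outcome_type, outcome_max = outcome_max),
            class = "n1_outcome")
}

#' @export
print.n1_outcome <- function(x, ...) {
  cat(sprintf(
    "outcome model: baseline %g, alpha = %g/d, sigma_b = %g, sigma_p = %g, sigma_o = %g\n",
    x$baseline_init, x$sensitivity, x$sigma_b, x$sigma_p, x$sigma_o))
  cat(sprintf("  outcome type: %s%s\n", x$outcome_type,
              if (!is.null(x$outcome_max))
                sprintf(" (range 0..%d)", x$outcome_max) else ""))
  invisible(x)
}

#' Assemble a full N-of-1 study model
#'
#' Binds a study design, one treatment profile per treatment, and an
#' outcome model into a single object that can be simulated with
#' [simulate()][simulate.n1_model].
#'
#' @param design An [n1_design()] object.
#' @param treatments A list with one [treatment_profile()] per treatment
#'   index (length `design$n_treatments`), or a single profile when there
#'   is one treatment.
#' @param outcome An [outcome_model()] object.
#' @return An object of class `"n1_model"`.
#' @examples
#' m <- n1_model(
#'   n1_design(2, 2, 30),
#'   list(treatment_profile(-40, 6, 3), treatment_profile(-30, 2, 10)),
#'   outcome_model(160, 0.5, sigma_b = 0.9, sigma_p = 1, sigma_o = 4))
#' tr <- simulate(m, seed = 1)
#' head(observations(tr))
#' @export
n1_model <- function(design, treatments, outcome) {
  stopifnot(inherits(design, "n1_design"), inherits(outcome, "n1_outcome"))
  if (inherits(treatments, "n1_treatment")) treatments <- list(treatments)
  if (length(treatments) == 0)
    stop("at least one treatment profile is required", call. = FALSE)
  ok <- vapply(treatments, inherits, TRUE, what = "n1_treatment")
  if (!all(ok))
    stop("`treatments` must be a list of treatment_profile() objects",
         call. = FALSE)
  if (length(treatments) != design$n_treatments)
    stop(sprintf("design has %d treatments but %d profiles were supplied",
                 design$n_treatments, length(treatments)), call. = FALSE)
  structure(list(design = design, treatments = treatments, outcome = outcome),
            class = "n1_model")
}

#' @export
print.n1_model <- function(x, ...) {
  cat("N-of-1 study model\n")
  print(x$design)
  for (j in seq_along(x$treatments)) {
    cat(sprintf("  [%d] ", j)); print(x$treatments[[j]])
  }
  print(x$outcome)
  invisible(x)
}
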