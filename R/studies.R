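#' Blood-pressure (hypertension) case-study model
#'
#' A two-treatment N-of-1 study of systolic blood pressure comparing two
#' antihypertensives. Treatment 1 is the more effective drug (long-run
#' effect -40 from a baseline of 160) but washes in slowly (tau = 6 d) and
#' out quickly (gamma = 3 d); treatment 2 is weaker (-30) but fast to act
#' (tau = 2 d) and slow to wash out (gamma = 10 d), so the true long-run
#' contrast of treatment 2 versus treatment 1 is +10 mmHg. Baseline drift
#' (sigma_b = 0.9), process noise (sigma_p = 1) and cuff measurement noise
#' (sigma_o = 4) are all present. The default design is 2 blocks of
#' 30-day periods in order 2 1 | 2 1 with one sample per day.
#'
#' @param n_blocks Number of blocks (default 2).
#' @param period_length Treatment period length, days (default 30).
#' @param block_orders List of per-block treatment orders; default
#'   `c(2, 1)` in every block.
#' @param sampling_interval Days between samples (default 1, i.e. daily).
#' @param per_period_end If `TRUE`, ignore `sampling_interval` and take a
#'   single sample at the end of each treatment period.
#' @param dt Simulation step, days (default 0.1).
#' @return An [n1_model()] object.
#' @examples
#' m <- hypertension_study()
#' tr <- simulate(m, seed = 1)
#' n1_fit(observations(tr))
#' @export
hypertension_study <- function(n_blocks = 2, period_length = 30,
                               block_orders = NULL, sampling_interval = 1,
                               per_period_end = FALSE, dt = 0.1) {
  if (is.null(block_orders))
    block_orders <- rep(list(c(2L, 1L)), n_blocks)
  total <- n_blocks * 2 * period_length
  design <- n1_design(
    n_blocks = n_blocks, n_treatments = 2, period_length = period_length,
    block_orders = block_orders,
    sampling_times = if (per_period_end) period_length * seq_len(2 * n_blocks) - dt
                     else regular_sampling_times(total, sampling_interval),
    dt = dt)
  n1_model(
    design,
    list(treatment_profile(effect = -40, wash_in_tau = 6, wash_out_gamma = 3),
         treatment_profile(effect = -30, wash_in_tau = 2, wash_out_gamma = 10)),
    outcome_model(baseline_init = 160, sensitivity = 0.5,
                  sigma_b = 0.9, sigma_p = 1, sigma_o = 4))
}

#' Pain-management (diary score) case-study model
#'
#' A two-treatment N-of-1 study modeled on published single-patient
#' NSAID-versus-paracetamol trials: the outcome is a daily pain diary
#' score from 0 (no complaints) to 6 (unbearable complaints), simulated
#' by rounding and truncating the continuous state. Treatment 1 is the
#' NSAID, treatment 2 paracetamol. Paracetamol is taken as the reference
#' state: the baseline equals the patient's true score on paracetamol and
#' the NSAID's effect is the score difference. Both drugs are
#' short-acting (tau = 1 d, gamma = 3.5 d); there is no baseline drift,
#' moderate process noise (sigma_p = 0.5) and one point of reporting
#' noise (sigma_o = 1). The default design is 5 blocks of two 14-day
#' periods with daily scores; the customary analysis uses only the last
#' week of each period.
#'
#' @param nsaid_score True long-run diary score on the NSAID (default 2).
#' @param paracetamol_score True long-run diary score on paracetamol
#'   (default 4).
#' @param n_blocks Number of blocks (default 5).
#' @param period_length Treatment period length, days (default 14).
#' @param block_orders Per-block treatment orders; default `c(1, 2)` in
#'   every block. Pass `randomize_orders = TRUE` to
#'   [simulate()][simulate.n1_model] or the experiment functions to
#'   re-randomize per replicate.
#' @param dt Simulation step, days (default 0.1).
#' @return An [n1_model()] object.
#' @export
pain_study <- function(nsaid_score = 2, paracetamol_score = 4,
                       n_blocks = 5, period_length = 14,
                       block_orders = NULL, dt = 0.1) {
  if (is.null(block_orders))
    block_orders <- rep(list(c(1L, 2L)), n_blocks)
  design <- n1_design(
    n_blocks = n_blocks, n_treatments = 2, period_length = period_length,
    block_orders = block_orders,
    sampling_times = regular_sampling_times(
      n_blocks * 2 * period_length, 1),
    dt = dt)
  n1_model(
    design,
    list(treatment_profile(effect = nsaid_score - paracetamol_score,
                           wash_in_tau = 1, wash_out_gamma = 3.5),
         treatment_profile(effect = 0, wash_in_tau = 1,
                           wash_out_gamma = 3.5)),
    outcome_model(baseline_init = paracetamol_score, sensitivity = 1,
                  sigma_b = 0, sigma_p = 0.5, sigma_o = 1,
                  outcome_type = "score", outcome_max = 6))
}

#' Signal-to-noise (best-case) scenario for design recommendations
#'
#' A dimensionless placebo-versus-treatment scenario with effectively
#' instantaneous dynamics, used to study how many samples per treatment a
#' design needs: time constants of 0.01, relaxation rate alpha = 10,
#' baseline 0, treatment 1 a placebo (effect 0) and treatment 2 with the
#' given effect. Time is in sampling units: one sample and one simulation
#' step per time unit, so `sigma_p` is the standard deviation of the
#' process-noise increment between consecutive samples and the effect
#' size is a signal-to-noise ratio when `sigma_o = 1`.
#'
#' @param samples_per_treatment Treatment period length in time units
#'   (one sample per unit).
#' @param effect True effect of treatment 2 (treatment 1 is placebo).
#' @param sigma_o Observation-noise SD (default 1).
#' @param sigma_p Process-noise scale (default 0).
#' @param sigma_b Baseline-drift scale (default 0).
#' @param alpha Relaxation rate (default 10, near-instantaneous).
#' @param n_blocks Number of blocks (default 1; block design is
#'   irrelevant when observation noise is the only noise source).
#' @param block_orders Per-block orders; default `c(1, 2)` each block.
#' @return An [n1_model()] object.
#' @export
snr_study <- function(samples_per_treatment, effect, sigma_o = 1,
                      sigma_p = 0, sigma_b = 0, alpha = 10,
                      n_blocks = 1, block_orders = NULL) {
  if (is.null(block_orders))
    block_orders <- rep(list(c(1L, 2L)), n_blocks)
  total <- n_blocks * 2 * samples_per_treatment
  design <- n1_design(
    n_blocks = n_blocks, n_treatments = 2,
    period_length = samples_per_treatment,
    block_orders = block_orders,
    sampling_times = seq_len(total),
    dt = 1)
  n1_model(
    design,
    list(treatment_profile(effect = 0, wash_in_tau = 0.01,
                           wash_out_gamma = 0.01),
         treatment_profile(effect = effect, wash_in_tau = 0.01,
                           wash_out_gamma = 0.01)),
    outcome_model(baseline_init = 0, sensitivity = alpha,
                  sigma_b = sigma_b, sigma_p = sigma_p, sigma_o = sigma_o))
}

#' Fixed-length drift scenario for block-count recommendations
#'
#' A study of fixed total length split into `n_blocks` blocks of two
#' periods (placebo first half of each block order `c(2, 1)`), with
#' instantaneous dynamics and baseline drift as the only noise source by
#' default. Used to measure how block structure protects the effect
#' estimate against drift.
#'
#' @param n_blocks Number of blocks.
#' @param sigma_b Baseline-drift scale.
#' @param total_length Total study length in time units (default 240).
#' @param effect True effect of treatment 2 (default 1).
#' @param sigma_o,sigma_p Other noise scales (default 0).
#' @param alpha Relaxation rate (default 10).
#' @return An [n1_model()] object.
#' @export
drift_study <- function(n_blocks, sigma_b, total_length = 240, effect = 1,
                        sigma_o = 0, sigma_p = 0, alpha = 10) {
  period <- total_length / (2 * n_blocks)
  design <- n1_design(
    n_blocks = n_blocks, n_treatments = 2, period_length = period,
    block_orders = rep(list(c(2L, 1L)), n_blocks),
    sampling_times = seq_len(total_length),
    dt = 1)
  n1_model(
    design,
    list(treatment_profile(effect = 0, wash_in_tau = 0.01,
                           wash_out_gamma = 0.01),
         treatment_profile(effect = effect, wash_in_tau = 0.01,
                           wash_out_gamma = 0.01)),
    outcome_model(baseline_init = 0, sensitivity = alpha,
                  sigma_b = sigma_b, sigma_p = sigma_p, sigma_o = sigma_o))
}
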