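#' Estimate power and effect-estimate accuracy by replicated simulation
#'
#' Runs `replicates` independent simulate-then-analyze cycles of an N-of-1
#' study model and summarizes the results: the fraction of replicates in
#' which the treatment contrast is significant (the estimated power), and
#' the mean, median and standard deviation of the effect estimates,
#' together with the median estimate among significant replicates only.
#' Replicate seeds are drawn deterministically from the root `seed`, so a
#' fixed seed reproduces the summary exactly.
#'
#' Replicates in which the regression cannot be fitted (degenerate data)
#' are excluded from every summary and counted in `n_failed`, with a
#' warning.
#'
#' @param model An [n1_model()] object.
#' @param replicates Number of simulation replicates (default 50).
#' @param seed Integer root seed.
#' @param level Significance level for the power count (default 0.05).
#' @param contrast Treatment label whose contrast against treatment 1 is
#'   summarized (default 2).
#' @param true_effect If supplied, the mean absolute deviation of the
#'   estimates from this value is reported as `mean_abs_deviation`.
#' @param randomize_orders Logical; redraw block orders per replicate.
#' @return A one-row data frame of class `"n1_power"` with columns
#'   `power`, `mean_estimate`, `median_estimate`, `sd_estimate`,
#'   `median_significant_estimate`, `mean_abs_deviation`, `replicates`,
#'   `n_failed`, `seed`. The per-replicate estimates and p-values are
#'   attached as attribute `"replicates"`.
#' @examples
#' estimate_power(snr_study(20, effect = 1), replicates = 20, seed = 1)
#' @export
estimate_power <- function(model, replicates = 50, seed = 1, level = 0.05,
                           contrast = 2, true_effect = NULL,
                           randomize_orders = FALSE) {
  stopifnot(inherits(model, "n1_model"), replicates >= 1)
  rep_seeds <- with_seed(seed, sample.int(2147483646L, replicates))
  est <- pval <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    tr <- simulate_trace(model, rep_seeds[r], randomize_orders)
    fit <- tryCatch(n1_fit(tr$observations, level = level),
                    error = function(e) NULL)
    if (is.null(fit)) next
    row <- match(contrast, fit$contrasts$treatment)
    est[r] <- fit$contrasts$estimate[row]
    pval[r] <- fit$contrasts$p_value[row]
  }
  ok <- !is.na(est)
  n_failed <- sum(!ok)
  if (n_failed > 0)
    warning(sprintf("%d of %d replicates failed analysis and were excluded",
                    n_failed, replicates), call. = FALSE)
  sig <- ok & pval < level
  out <- data.frame(
    power = mean(pval[ok] < level),
    mean_estimate = mean(est[ok]),
    median_estimate = stats::median(est[ok]),
    sd_estimate = stats::sd(est[ok]),
    median_significant_estimate =
      if (any(sig)) stats::median(est[sig]) else NA_real_,
    mean_abs_deviation =
      if (is.null(true_effect)) NA_real_ else mean(abs(est[ok] - true_effect)),
    replicates = sum(ok),
    n_failed = n_failed,
    seed = seed)
  attr(out, "replicates") <- data.frame(estimate = est, p_value = pval)
  class(out) <- c("n1_power", "data.frame")
  out
}

#' Estimate power across a grid of study designs
#'
#' Applies [estimate_power()] to each scenario in a named list of models
#' and binds the summaries into one tidy table. Each grid point gets its
#' own root seed, derived deterministically from `seed`, so the whole
#' sweep is reproducible.
#'
#' @param scenarios Named list of [n1_model()] objects (one per grid
#'   point).
#' @param replicates,level,contrast,true_effect,randomize_orders Passed to
#'   [estimate_power()].
#' @param seed Integer root seed for the sweep.
#' @return A data frame with one row per scenario; first column
#'   `scenario`.
#' @examples
#' sweep_power(list(short = snr_study(10, 1), long = snr_study(40, 1)),
#'             replicates = 20, seed = 1)
#' @export
sweep_power <- function(scenarios, replicates = 50, seed = 1, level = 0.05,
                        contrast = 2, true_effect = NULL,
                        randomize_orders = FALSE) {
  stopifnot(is.list(scenarios), length(scenarios) > 0)
  if (is.null(names(scenarios)))
    names(scenarios) <- seq_along(scenarios)
  grid_seeds <- with_seed(seed, sample.int(2147483646L, length(scenarios)))
  rows <- lapply(seq_along(scenarios), function(g) {
    row <- estimate_power(scenarios[[g]], replicates = replicates,
                          seed = grid_seeds[g], level = level,
                          contrast = contrast, true_effect = true_effect,
                          randomize_orders = randomize_orders)
    attr(row, "replicates") <- NULL
    class(row) <- "data.frame"
    cbind(scenario = names(scenarios)[g], row)
  })
  do.call(rbind, rows)
}

#' Smallest number of samples per treatment reaching a target power
#'
#' Estimates power on a grid of samples-per-treatment values (period
#' length at one sample per time unit) and returns the smallest grid
#' value whose estimated power reaches `target_power`, along with the
#' full raw power curve (no smoothing is applied).
#'
#' @param make_model A function taking a samples-per-treatment value and
#'   returning an [n1_model()], e.g. a wrapper around [snr_study()].
#' @param sample_grid Increasing integer grid of samples per treatment.
#' @param target_power Power to reach (default 0.8).
#' @param replicates,seed,level,contrast Passed to the underlying power
#'   estimation.
#' @return A list with `min_samples` (the smallest grid value reaching
#'   the target) and `curve` (data frame `samples`, `power`).
#' @examples
#' min_samples_for_power(function(n) snr_study(n, effect = 2),
#'                       sample_grid = c(4, 8, 12), replicates = 40,
#'                       seed = 1)
#' @export
min_samples_for_power <- function(make_model, sample_grid,
                                  target_power = 0.8, replicates = 50,
                                  seed = 1, level = 0.05, contrast = 2) {
  stopifnot(is.function(make_model), length(sample_grid) > 0,
            !is.unsorted(sample_grid), target_power > 0, target_power < 1)
  scenarios <- lapply(sample_grid, make_model)
  names(scenarios) <- sample_grid
  tab <- sweep_power(scenarios, replicates = replicates, seed = seed,
                     level = level, contrast = contrast)
  curve <- data.frame(samples = sample_grid, power = tab$power)
  hit <- which(curve$power >= target_power)
  if (length(hit) == 0)
    stop(sprintf(
      "target power %.2f not reached on the grid (max attained %.3f)",
      target_power, max(curve$power)), call. = FALSE)
  list(min_samples = sample_grid[hit[1]], curve = curve)
}

#' Effect-estimate deviation under baseline drift, by block count
#'
#' For each combination of drift scale and block count, simulates a study
#' of fixed total length (via [drift_study()]) and reports the mean
#' absolute deviation of the fitted treatment contrast from the true
#' effect. More blocks shorten the within-block comparison span, so the
#' estimate is progressively protected against drift.
#'
#' @param sigma_b_grid Numeric vector of drift scales.
#' @param blocks_grid Integer vector of block counts.
#' @param total_length Total study length, time units (default 240).
#' @param effect True effect of treatment 2 versus placebo (default 1).
#' @param sigma_o,sigma_p Other noise scales (default 0).
#' @param replicates,seed,level Passed to [estimate_power()].
#' @return A data frame with columns `sigma_b`, `n_blocks`,
#'   `mean_abs_deviation`, `power`, `sd_estimate`, `replicates`.
#' @export
estimate_bias_under_drift <- function(sigma_b_grid, blocks_grid,
                                      total_length = 240, effect = 1,
                                      sigma_o = 0, sigma_p = 0,
                                      replicates = 50, seed = 1,
                                      level = 0.05) {
  grid <- expand.grid(sigma_b = sigma_b_grid, n_blocks = blocks_grid)
  scenarios <- lapply(seq_len(nrow(grid)), function(i)
    drift_study(n_blocks = grid$n_blocks[i], sigma_b = grid$sigma_b[i],
                total_length = total_length, effect = effect,
                sigma_o = sigma_o, sigma_p = sigma_p))
  tab <- sweep_power(scenarios, replicates = replicates, seed = seed,
                     level = level, true_effect = effect)
  data.frame(grid,
             mean_abs_deviation = tab$mean_abs_deviation,
             power = tab$power,
             sd_estimate = tab$sd_estimate,
             replicates = tab$replicates)
}

#' Compare analysis methods on identical simulated data
#'
#' Simulates the same study repeatedly and applies, per replicate, both
#' the median-differencing rule and the fixed-effects regression to the
#' identical data set, recording how often each recommends the treatment
#' of interest. The regression recommends when the fitted contrast of the
#' treatment of interest against the comparator is negative (a benefit,
#' for outcomes where lower is better) *and* significant at `level`; the
#' rate under a sign-only rule (negative contrast, significance ignored)
#' is reported alongside.
#'
#' @param model A two-treatment [n1_model()], e.g. [pain_study()].
#' @param treatment_of_interest,comparator Treatment labels (defaults 1
#'   and 2, i.e. NSAID versus paracetamol in [pain_study()]).
#' @param replicates,seed,level As in [estimate_power()].
#' @param point_threshold,required_blocks,analysis_window Passed to
#'   [median_differencing()]; the analysis window also restricts the
#'   regression's data, so both methods see the same observations.
#' @param randomize_orders Logical; redraw block orders per replicate
#'   (default `TRUE`, as in designs randomized per block).
#' @return A list of class `"n1_method_comparison"` with `rates` (named
#'   recommendation fractions: `median_differencing`, `regression`,
#'   `regression_sign_only`), the per-replicate decision table, and the
#'   call parameters.
#' @export
compare_analysis_methods <- function(model, treatment_of_interest = 1,
                                     comparator = 2, replicates = 50,
                                     seed = 1, level = 0.05,
                                     point_threshold = 1,
                                     required_blocks = 4,
                                     analysis_window = 7,
                                     randomize_orders = TRUE) {
  stopifnot(inherits(model, "n1_model"),
            model$design$n_treatments == 2)
  rep_seeds <- with_seed(seed, sample.int(2147483646L, replicates))
  dec <- data.frame(median_differencing = rep(NA, replicates),
                    regression = NA, regression_sign_only = NA)
  for (r in seq_len(replicates)) {
    tr <- simulate_trace(model, rep_seeds[r], randomize_orders)
    obs <- tr$observations
    md <- median_differencing(obs, treatment_of_interest, comparator,
                              point_threshold = point_threshold,
                              required_blocks = required_blocks,
                              analysis_window = analysis_window)
    dec$median_differencing[r] <- md$recommended

    obs_win <- if (is.null(analysis_window)) obs
               else filter_period_tail(obs, analysis_window)
    fit <- tryCatch(n1_fit(obs_win, level = level),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      # contrast is reported as (other treatment) minus (treatment 1)
      cc <- fit$contrasts[1, ]
      delta <- if (treatment_of_interest == cc$reference) -cc$estimate
               else cc$estimate
      dec$regression_sign_only[r] <- delta < 0
      dec$regression[r] <- delta < 0 && cc$p_value < level
    }
  }
  rates <- vapply(dec, mean, 0, na.rm = TRUE)
  structure(
    list(rates = rates, decisions = dec, replicates = replicates,
         seed = seed, level = level, point_threshold = point_threshold,
         required_blocks = required_blocks,
         analysis_window = analysis_window),
    class = "n1_method_comparison")
}

#' @export
print.n1_method_comparison <- function(x, ...) {
  cat(sprintf("analysis-method comparison over %d replicates:\n",
              x$replicates))
  cat(sprintf("  median differencing      : recommended %5.1f%% of the time\n",
              100 * x$rates[["median_differencing"]]))
  cat(sprintf("  regression (sign + p<%g): recommended %5.1f%% of the time\n",
              x$level, 100 * x$rates[["regression"]]))
  cat(sprintf("  regression (sign only)   : recommended %5.1f%% of the time\n",
              100 * x$rates[["regression_sign_only"]]))
  invisible(x)
}

#' @export
print.n1_power <- function(x, ...) {
  cat(sprintf(
    "estimated power %.3f over %d replicates (%d failed); estimates: mean %.3g, median %.3g, sd %.3g\n",
    x$power, x$replicates + x$n_failed, x$n_failed, x$mean_estimate,
    x$median_estimate, x$sd_estimate))
  invisible(x)
}
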