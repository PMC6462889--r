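#' Simulate an N-of-1 study
#'
#' Generates the latent trajectories and observed outcomes of an N-of-1
#' study model on its simulation grid. Initial conditions are `X_j(0) = 0`
#' for every treatment, `B(0) = Z(0) = baseline_init` (the patient starts
#' untreated at baseline). Per step the treatment effects are advanced
#' with their exact exponential solution (treatment switches are
#' grid-aligned, so the administration indicator is constant within a
#' step), the baseline receives its Wiener increment, and the true state
#' relaxes toward the updated target `Q = B + sum_j X_j` with a Gaussian
#' process-noise increment. At each sampling time the true state is
#' observed with instrument noise and mapped through the outcome-type
#' transformation.
#'
#' The root seed is split into independent sub-streams for the baseline,
#' the process noise, the observation noise (plus any discrete-outcome
#' draws), and the optional re-randomization of block orders, so turning
#' one noise source on or off does not perturb the draws of the others.
#'
#' @param object An [n1_model()] object.
#' @param nsim Number of traces to generate.
#' @param seed Integer root seed. If `NULL`, one is drawn from the current
#'   RNG state. When `nsim > 1` the trace for replicate `r` uses seed
#'   `seed + r - 1`.
#' @param randomize_orders Logical; if `TRUE`, block orders are redrawn
#'   uniformly at random (from the trace's own seed) before simulating,
#'   as in designs whose within-block order is randomized per patient.
#' @param ... Unused.
#' @return For `nsim = 1` an object of class `"n1_trace"`; otherwise a
#'   list of such objects. A trace holds the grid `times`, the
#'   per-treatment `effects` matrix, the `baseline`, `target` and `state`
#'   trajectories, the `observations` data frame (columns `time`, `block`,
#'   `treatment`, `value`), the continuous pre-transformation observations
#'   `y_continuous`, the `seed`, and the realized `schedule`.
#' @examples
#' m <- n1_model(n1_design(1, 1, 10),
#'               treatment_profile(5, 0.5, 0.5),
#'               outcome_model(0, 10))
#' simulate(m, seed = 42)
#' @export
simulate.n1_model <- function(object, nsim = 1, seed = NULL,
                              randomize_orders = FALSE, ...) {
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  seed <- as.integer(seed)
  if (nsim > 1) {
    return(lapply(seq_len(nsim), function(r)
      simulate_trace(object, seed + r - 1L, randomize_orders)))
  }
  simulate_trace(object, seed, randomize_orders)
}

simulate_trace <- function(model, seed, randomize_orders = FALSE) {
  design <- model$design
  outc <- model$outcome
  dt <- design$dt
  n_steps <- as.integer(round(design$total_length / dt))
  times <- seq(0, by = dt, length.out = n_steps + 1L)

  sub <- with_seed(seed, sample.int(2147483646L, 4L))

  if (randomize_orders) {
    design$block_orders <- randomize_block_orders(
      design$n_blocks, design$n_treatments, seed = sub[4L])
  }
  schedule <- build_schedule(design)

  # latent treatment effects: exact piecewise-exponential solution
  X <- latent_effects(model$treatments, schedule, dt, n_steps)
  x_total <- rowSums(X)

  # baseline: discretized Wiener process
  db <- with_seed(sub[1L], stats::rnorm(n_steps, 0, outc$sigma_b * sqrt(dt)))
  baseline <- outc$baseline_init + c(0, cumsum(db))

  # true state: relaxation toward the target plus process noise
  target <- baseline + x_total
  a <- exp(-outc$sensitivity * dt)
  eps <- with_seed(sub[2L], stats::rnorm(n_steps, 0, outc$sigma_p * sqrt(dt)))
  input <- target[-1L] * (1 - a) + eps
  state <- c(outc$baseline_init,
             as.numeric(stats::filter(input, a, method = "recursive",
                                      init = outc$baseline_init)))

  # observations at the sampling times
  st <- design$sampling_times
  idx <- as.integer(round(st / dt)) + 1L
  obs_val <- with_seed(sub[3L], {
    y <- observe_outcome(state[idx], outc$sigma_o)
    list(y = y,
         value = transform_outcome(y, outc$outcome_type, outc$outcome_max))
  })
  # label each sample by the treatment in effect during the step that
  # produced it: a sample taken exactly at a crossover instant reflects
  # the outgoing treatment, since the incoming one has not yet acted
  lab_t <- pmax(st - dt / 2, 0)
  observations <- data.frame(
    time = st,
    block = block_at(schedule, lab_t),
    treatment = treatment_at(schedule, lab_t),
    value = obs_val$value)

  structure(
    list(times = times, effects = X, baseline = baseline, target = target,
         state = state, observations = observations,
         y_continuous = obs_val$y, schedule = schedule, seed = seed,
         model = model),
    class = "n1_trace")
}

# Exact closed-form latent effect trajectories on the grid. Within each
# period the administration indicator is constant, so
# X_j(t) = target + (X_j(t0) - target) * exp(-(t - t0) / tc).
latent_effects <- function(treatments, schedule, dt, n_steps) {
  J <- length(treatments)
  X <- matrix(0, nrow = n_steps + 1L, ncol = J)
  cur <- numeric(J)
  for (p in seq_len(nrow(schedule))) {
    i0 <- as.integer(round(schedule$start[p] / dt))
    i1 <- as.integer(round(schedule$end[p] / dt))
    i1 <- min(i1, n_steps)
    rel <- (0:(i1 - i0)) * dt
    rows <- (i0 + 1L):(i1 + 1L)
    for (j in seq_len(J)) {
      pr <- treatments[[j]]
      if (schedule$treatment[p] == j) {
        tgt <- pr$effect; tc <- pr$wash_in_tau
      } else {
        tgt <- 0; tc <- pr$wash_out_gamma
      }
      X[rows, j] <- tgt + (cur[j] - tgt) * exp(-rel / tc)
      cur[j] <- X[i1 + 1L, j]
    }
  }
  X
}

#' Extract the observed data of a simulated trace
#'
#' @param trace An `"n1_trace"` object.
#' @return A data frame with columns `time`, `block`, `treatment`,
#'   `value`, suitable for [n1_fit()] and [median_differencing()].
#' @export
observations <- function(trace) {
  stopifnot(inherits(trace, "n1_trace"))
  trace$observations
}

#' @export
print.n1_trace <- function(x, ...) {
  cat(sprintf(
    "simulated N-of-1 trace: %d grid points over %g days, %d observations (seed %d)\n",
    length(x$times), max(x$times), nrow(x$observations), x$seed))
  print(utils::head(x$observations))
  if (nrow(x$observations) > 6) cat("  ...\n")
  invisible(x)
}

#' Tidy data frame of a simulated trace
#'
#' One row per grid point with the latent trajectories; observed values
#' are filled in on sampling rows and `NA` elsewhere.
#'
#' @param x An `"n1_trace"` object.
#' @param row.names,optional,... Passed over from the generic; unused.
#' @param latent Logical; include the latent columns (default `TRUE`).
#' @return A data frame with columns `time_day`, `block`, `treatment`,
#'   `X_total`, `baseline`, `Z_true`, `Y_observed`.
#' @export
as.data.frame.n1_trace <- function(x, row.names = NULL, optional = FALSE,
                                   latent = TRUE, ...) {
  lab_t <- pmax(x$times - x$model$design$dt / 2, 0)
  out <- data.frame(
    time_day = x$times,
    block = block_at(x$schedule, lab_t),
    treatment = treatment_at(x$schedule, lab_t),
    X_total = rowSums(x$effects),
    baseline = x$baseline,
    Z_true = x$state,
    Y_observed = NA_real_)
  idx <- as.integer(round(x$observations$time / x$model$design$dt)) + 1L
  out$Y_observed[idx] <- x$observations$value
  if (!latent) out[c("X_total", "baseline", "Z_true")] <- NULL
  out
}

#' Plot a simulated trace
#'
#' Draws the latent true state and baseline over time with the observed
#' samples overlaid, colored by treatment; period boundaries are marked.
#'
#' @param x An `"n1_trace"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.n1_trace <- function(x, ...) {
  obs <- x$observations
  ylim <- range(x$state, obs$value, x$baseline, finite = TRUE)
  graphics::plot(x$times, x$state, type = "l", col = "grey40",
                 xlab = "time (days)", ylab = "outcome", ylim = ylim, ...)
  graphics::lines(x$times, x$baseline, lty = 2, col = "grey70")
  graphics::abline(v = x$schedule$start[-1], col = "grey85", lty = 3)
  graphics::points(obs$time, obs$value, pch = 19, cex = 0.6,
                   col = obs$treatment + 1L)
  graphics::legend("topright", bty = "n", pch = 19,
                   col = sort(unique(obs$treatment)) + 1L,
                   legend = paste("treatment", sort(unique(obs$treatment))))
  invisible(x)
}
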