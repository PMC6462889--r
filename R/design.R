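#' Construct an N-of-1 study design
#'
#' An N-of-1 study consists of `n_blocks` blocks, each containing one
#' treatment period per treatment (so `n_treatments` periods of length
#' `period_length` days per block). The order of the periods within each
#' block is given by `block_orders`, one permutation of `1:n_treatments`
#' per block. Outcomes are observed at `sampling_times` (days from study
#' start); the latent processes are simulated on a regular grid of step
#' `dt`.
#'
#' Time is continuous in days. Treatment periods are half-open intervals
#' `[start, end)`, so a sampling time falling exactly on an interior period
#' boundary is attributed to the *next* period; a sampling time at the very
#' end of the study is attributed to the last period. Sampling times are
#' snapped to the simulation grid (nearest multiple of `dt`, ties toward
#' zero). `period_length` must be a multiple of `dt`; if it is not, it is
#' snapped to the nearest multiple with a warning so that treatment
#' switches always fall on grid points.
#'
#' @param n_blocks Number of blocks (N), a positive integer.
#' @param n_treatments Number of treatments per block (J), a positive
#'   integer.
#' @param period_length Duration of one treatment period (P), days.
#' @param block_orders List of `n_blocks` permutations of
#'   `1:n_treatments`, or `NULL` to repeat the identity order in every
#'   block. See [randomize_block_orders()] for random orders.
#' @param sampling_times Strictly increasing numeric vector of observation
#'   times in days, all within `[0, n_blocks * n_treatments *
#'   period_length]`. Defaults to one sample per day starting at day 1.
#'   See [regular_sampling_times()] and [per_period_end_times()].
#' @param dt Simulation step, days. Must satisfy `0 < dt <=
#'   period_length`. Default `min(0.1, period_length / 10)`, which resolves
#'   wash-in/wash-out time constants down to about a day with at least ten
#'   steps; scenario constructors working in dimensionless time units set
#'   `dt` explicitly.
#'
#' @return An object of class `"n1_design"`.
#' @seealso [build_schedule()], [n1_model()]
#' @examples
#' d <- n1_design(n_blocks = 2, n_treatments = 2, period_length = 30)
#' build_schedule(d)
#' @export
n1_design <- function(n_blocks, n_treatments, period_length,
                      block_orders = NULL, sampling_times = NULL,
                      dt = NULL) {
  stopifnot(length(n_blocks) == 1, length(n_treatments) == 1,
            length(period_length) == 1)
  n_blocks <- as.integer(n_blocks)
  n_treatments <- as.integer(n_treatments)
  if (is.na(n_blocks) || n_blocks < 1)
    stop("`n_blocks` must be a positive integer", call. = FALSE)
  if (is.na(n_treatments) || n_treatments < 1)
    stop("`n_treatments` must be a positive integer", call. = FALSE)
  if (!is.finite(period_length) || period_length <= 0)
    stop("`period_length` must be a positive number of days", call. = FALSE)

  if (is.null(dt)) dt <- min(0.1, period_length / 10)
  if (!is.finite(dt) || dt <= 0 || dt > period_length)
    stop("`dt` must satisfy 0 < dt <= period_length", call. = FALSE)

  # treatment switches must be grid-aligned
  k <- round(period_length / dt)
  if (abs(k * dt - period_length) > 1e-8 * max(1, period_length)) {
    period_length <- k * dt
    warning(sprintf("period_length snapped to %g (nearest multiple of dt)",
                    period_length), call. = FALSE)
  }

  if (is.null(block_orders))
    block_orders <- rep(list(seq_len(n_treatments)), n_blocks)
  if (!is.list(block_orders)) block_orders <- list(block_orders)
  if (length(block_orders) != n_blocks)
    stop(sprintf("`block_orders` must contain %d permutations, got %d",
                 n_blocks, length(block_orders)), call. = FALSE)
  for (b in seq_len(n_blocks)) {
    ord <- as.integer(block_orders[[b]])
    if (length(ord) != n_treatments ||
        !setequal(ord, seq_len(n_treatments)))
      stop(sprintf(
        "block %d: order (%s) is not a permutation of 1..%d",
        b, paste(block_orders[[b]], collapse = " "), n_treatments),
        call. = FALSE)
    block_orders[[b]] <- ord
  }

  total <- n_blocks * n_treatments * period_length
  if (is.null(sampling_times))
    sampling_times <- regular_sampling_times(total, interval = 1, offset = 1)
  sampling_times <- snap_to_grid(sampling_times, dt)
  if (any(diff(sampling_times) <= 0))
    stop("`sampling_times` must be strictly increasing (after grid snapping)",
         call. = FALSE)
  if (any(sampling_times < 0) || any(sampling_times > total + 1e-9))
    stop(sprintf("all sampling times must lie in [0, %g]", total),
         call. = FALSE)

  structure(
    list(n_blocks = n_blocks, n_treatments = n_treatments,
         period_length = period_length, block_orders = block_orders,
         sampling_times = sampling_times, dt = dt, total_length = total),
    class = "n1_design")
}

#' @export
print.n1_design <- function(x, ...) {
  cat(sprintf(
    "N-of-1 study design: %d block(s) x %d treatment(s), period %g d (total %g d)\n",
    x$n_blocks, x$n_treatments, x$period_length, x$total_length))
  cat("  block orders:",
      paste(vapply(x$block_orders, paste, "", collapse = " "),
            collapse = " | "), "\n")
  cat(sprintf("  %d sampling times in [%g, %g], dt = %g d\n",
              length(x$sampling_times), min(x$sampling_times),
              max(x$sampling_times), x$dt))
  invisible(x)
}

# Snap times to the simulation grid: nearest multiple of dt, ties toward 0.
snap_to_grid <- function(times, dt) {
  dt * ceiling(times / dt - 0.5 - 1e-12)
}

#' Draw random treatment orders for each block
#'
#' Returns `n_blocks` independent uniformly random permutations of
#' `1:n_treatments` (Fisher--Yates via [sample()]), reproducible for a
#' fixed seed.
#'
#' @param n_blocks Number of blocks.
#' @param n_treatments Number of treatments.
#' @param seed Optional integer seed; if supplied, the draw is performed in
#'   a local RNG state that does not disturb the caller's.
#' @return A list of `n_blocks` integer permutations.
#' @export
randomize_block_orders <- function(n_blocks, n_treatments, seed = NULL) {
  stopifnot(n_blocks >= 1, n_treatments >= 1)
  draw <- function() replicate(n_blocks, sample.int(n_treatments),
                               simplify = FALSE)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Regularly spaced sampling times
#'
#' Times `offset, offset + interval, ...` up to `total_length` (inclusive
#' of a final point falling exactly at the end of the study).
#'
#' @param total_length Study length, days.
#' @param interval Sampling interval, days.
#' @param offset Time of the first sample, days (default `interval`).
#' @return Numeric vector of sampling times.
#' @seealso [per_period_end_times()] for the one-sample-per-period pattern.
#' @export
regular_sampling_times <- function(total_length, interval, offset = interval) {
  stopifnot(interval > 0, offset >= 0)
  if (offset > total_length)
    stop("no sampling time fits in the study: offset beyond study end",
         call. = FALSE)
  times <- seq(offset, total_length + 1e-9, by = interval)
  if (length(times) == 0)
    stop("no sampling time fits in the study", call. = FALSE)
  times
}

#' Sampling times at the end of each treatment period
#'
#' One sample per treatment period, taken at the last simulated grid point
#' inside the period (`end - dt`). Sampling exactly at the boundary would
#' attribute the observation to the following treatment under the
#' half-open period convention, so the last interior point is used.
#'
#' @param design An [n1_design()] object.
#' @return Numeric vector of `n_blocks * n_treatments` times.
#' @export
per_period_end_times <- function(design) {
  stopifnot(inherits(design, "n1_design"))
  n_periods <- design$n_blocks * design$n_treatments
  design$period_length * seq_len(n_periods) - design$dt
}

#' Expand a design into its treatment schedule
#'
#' Concatenates blocks in order and periods within each block in that
#' block's stated order, producing one row per treatment period. Interval
#' `k` (0-based) spans `[k * P, (k + 1) * P)`.
#'
#' @param design An [n1_design()] object.
#' @return A data frame of class `"n1_schedule"` with columns `start`,
#'   `end`, `treatment`, `block` (one row per period, in time order).
#' @export
build_schedule <- function(design) {
  stopifnot(inherits(design, "n1_design"))
  trt <- unlist(design$block_orders, use.names = FALSE)
  k <- seq_along(trt) - 1
  out <- data.frame(
    start = k * design$period_length,
    end = (k + 1) * design$period_length,
    treatment = trt,
    block = rep(seq_len(design$n_blocks), each = design$n_treatments))
  class(out) <- c("n1_schedule", "data.frame")
  out
}

# Treatment in progress at each time (half-open periods; times at or past
# the study end fall in the last period).
treatment_at <- function(schedule, times) {
  idx <- findInterval(times + 1e-12, schedule$start)
  idx[idx < 1] <- 1L
  idx[idx > nrow(schedule)] <- nrow(schedule)
  schedule$treatment[idx]
}

block_at <- function(schedule, times) {
  idx <- findInterval(times + 1e-12, schedule$start)
  idx[idx < 1] <- 1L
  idx[idx > nrow(schedule)] <- nrow(schedule)
  schedule$block[idx]
}
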