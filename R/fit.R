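#' Fixed-effects regression of outcome on treatment and block
#'
#' Fits the AHRQ-style model for N-of-1 data by ordinary least squares:
#' the observed value regressed on an intercept, `J - 1` treatment
#' indicators (treatment 1 is the reference), and `N - 1` block indicators
#' (block 1 is the reference). The treatment coefficients estimate each
#' treatment's effect contrast against treatment 1; classical
#' (homoskedastic) standard errors and two-sided t-tests are reported. No
#' autocorrelation correction is applied, matching standard practice for
#' these models even though simulated data are autocorrelated.
#'
#' @param data A data frame with columns `treatment`, `value`, and (when
#'   more than one block is present) `block`, e.g. from [observations()].
#' @param level Significance level for the `significant` flag (default
#'   0.05).
#' @return An object of class `"n1_fit"` with components `contrasts` (a
#'   data frame of per-treatment estimates, standard errors, t statistics
#'   and p-values), `level`, `significant`, and the underlying `lm` fit.
#' @examples
#' d <- data.frame(block = rep(1:2, each = 4),
#'                 treatment = rep(c(1, 2, 2, 1), each = 2),
#'                 value = c(1, 2, 11, 12, 12, 13, 2, 3))
#' fit <- n1_fit(d)
#' coef(fit)
#' @export
n1_fit <- function(data, level = 0.05) {
  data <- validate_observations(data)
  if (level <= 0 || level >= 1)
    stop("`level` must lie in (0, 1)", call. = FALSE)
  trts <- sort(unique(data$treatment))
  if (length(trts) < 2)
    stop("regression requires at least two treatments in the data",
         call. = FALSE)
  blocks <- sort(unique(data$block))

  data$.trt <- factor(data$treatment, levels = trts)
  data$.blk <- factor(data$block, levels = blocks)
  fml <- if (length(blocks) > 1) value ~ .trt + .blk else value ~ .trt
  fit <- stats::lm(fml, data = data)

  if (anyNA(stats::coef(fit)))
    stop(paste("rank-deficient design: some treatment/block combination is",
               "not identifiable (each treatment and block must be observed",
               "in an overlapping layout)"), call. = FALSE)
  if (stats::df.residual(fit) < 1)
    stop("fewer observations than model parameters", call. = FALSE)

  sm <- summary(fit)$coefficients
  rows <- paste0(".trt", trts[-1])
  contrasts <- data.frame(
    treatment = trts[-1],
    reference = trts[1],
    estimate = sm[rows, "Estimate"],
    std_error = sm[rows, "Std. Error"],
    t_value = sm[rows, "t value"],
    p_value = sm[rows, "Pr(>|t|)"],
    row.names = NULL)

  structure(
    list(contrasts = contrasts, level = level,
         significant = contrasts$p_value < level,
         n_obs = nrow(data), n_blocks = length(blocks), lm = fit),
    class = "n1_fit")
}

validate_observations <- function(data) {
  data <- as.data.frame(data)
  if (!"block" %in% names(data)) data$block <- 1L
  need <- c("treatment", "value", "block")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("observation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0) stop("observation table is empty", call. = FALSE)
  if (anyNA(data$value)) stop("observed values contain NA", call. = FALSE)
  data
}

#' @export
print.n1_fit <- function(x, ...) {
  cat(sprintf("N-of-1 fixed-effects fit: %d observations, %d block(s)\n",
              x$n_obs, x$n_blocks))
  cc <- x$contrasts
  for (i in seq_len(nrow(cc)))
    cat(sprintf(
      "  treatment %s vs %s: estimate %.4g (SE %.4g), p = %.3g%s\n",
      cc$treatment[i], cc$reference[i], cc$estimate[i], cc$std_error[i],
      cc$p_value[i],
      if (x$significant[i]) sprintf(" *(p < %g)", x$level) else ""))
  invisible(x)
}

#' @export
summary.n1_fit <- function(object, ...) summary(object$lm, ...)

#' @export
coef.n1_fit <- function(object, ...) {
  stats::setNames(object$contrasts$estimate,
                  paste0("treatment", object$contrasts$treatment))
}

#' @export
confint.n1_fit <- function(object, parm, level = 0.95, ...) {
  ci <- stats::confint(object$lm, level = level, ...)
  ci[grep("^\\.trt", rownames(ci)), , drop = FALSE]
}

#' @export
residuals.n1_fit <- function(object, ...) stats::residuals(object$lm, ...)

#' @export
predict.n1_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$lm, ...))
  newdata <- validate_observations(
    cbind(newdata, if (!"value" %in% names(newdata)) data.frame(value = 0)))
  newdata$.trt <- factor(newdata$treatment,
                         levels = levels(object$lm$model$.trt))
  if (".blk" %in% names(object$lm$model))
    newdata$.blk <- factor(newdata$block,
                           levels = levels(object$lm$model$.blk))
  stats::predict(object$lm, newdata = newdata, ...)
}

#' Median-differencing decision rule
#'
#' The analysis protocol of the pain-management case study: within each
#' block, compute the median observed outcome under the treatment of
#' interest and under the comparator (optionally restricted to the last
#' `analysis_window` days of each treatment period), count the blocks in
#' which the interest median is at least `point_threshold` points *lower*
#' than the comparator median (lower = better, as for pain scores), and
#' recommend the treatment of interest when that holds in at least
#' `required_blocks` blocks. A difference exactly equal to the threshold
#' counts as meeting it.
#'
#' Treatment periods are identified as maximal runs of a constant
#' treatment label within each block when the data are ordered by time, so
#' the window filter needs no explicit schedule.
#'
#' @param data Observation data frame with columns `time`, `block`,
#'   `treatment`, `value`.
#' @param treatment_of_interest,comparator Treatment labels to compare;
#'   both must occur in every block.
#' @param point_threshold Minimum median advantage, outcome points
#'   (default 1).
#' @param required_blocks Number of blocks that must show the advantage
#'   (default 4, the 4-of-5 rule).
#' @param analysis_window If non-`NULL`, only observations within the last
#'   `analysis_window` days of each treatment period are used (e.g. 7 for
#'   a last-week analysis).
#' @return An object of class `"n1_mdiff"` with the per-block medians and
#'   differences, the qualifying-block `count`, and the `recommended`
#'   flag.
#' @export
median_differencing <- function(data, treatment_of_interest, comparator,
                                point_threshold = 1, required_blocks = 4,
                                analysis_window = NULL) {
  data <- validate_observations(data)
  if (!"time" %in% names(data))
    stop("observation table lacks column(s): time", call. = FALSE)
  blocks <- sort(unique(data$block))
  if (required_blocks > length(blocks))
    stop("`required_blocks` exceeds the number of blocks", call. = FALSE)

  if (!is.null(analysis_window))
    data <- filter_period_tail(data, analysis_window)

  per_block <- lapply(blocks, function(b) {
    d <- data[data$block == b, ]
    vi <- d$value[d$treatment == treatment_of_interest]
    vc <- d$value[d$treatment == comparator]
    if (length(vi) == 0 || length(vc) == 0)
      stop(sprintf(
        "block %s lacks observations for treatment %s within the analysis window",
        b, if (length(vi) == 0) treatment_of_interest else comparator),
        call. = FALSE)
    data.frame(block = b, median_interest = stats::median(vi),
               median_comparator = stats::median(vc))
  })
  per_block <- do.call(rbind, per_block)
  per_block$difference <- per_block$median_comparator -
    per_block$median_interest
  per_block$meets <- per_block$difference >= point_threshold
  count <- sum(per_block$meets)

  structure(
    list(per_block = per_block, count = count,
         point_threshold = point_threshold,
         required_blocks = required_blocks,
         recommended = count >= required_blocks),
    class = "n1_mdiff")
}

# Keep only rows in the last `window` days of their treatment period,
# with periods inferred as time-ordered runs of a constant treatment.
filter_period_tail <- function(data, window) {
  ord <- order(data$block, data$time)
  d <- data[ord, ]
  run <- cumsum(c(1, diff(d$block) != 0 | diff(d$treatment) != 0))
  keep <- unlist(lapply(split(seq_len(nrow(d)), run), function(i) {
    i[d$time[i] > max(d$time[i]) - window]
  }), use.names = FALSE)
  d[sort(keep), ]
}

#' @export
print.n1_mdiff <- function(x, ...) {
  cat(sprintf(
    "median differencing: %d of %d block(s) show a >= %g-point advantage (need %d)\n",
    x$count, nrow(x$per_block), x$point_threshold, x$required_blocks))
  print(x$per_block, row.names = FALSE)
  cat(if (x$recommended) "=> treatment of interest recommended\n"
      else "=> treatment of interest not recommended\n")
  invisible(x)
}
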