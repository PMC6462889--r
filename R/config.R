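#' Load a study configuration file
#'
#' Reads a YAML or JSON document describing a full N-of-1 study --- the
#' design (blocks, periods, orderings, sampling, step), the list of
#' treatment profiles, and the outcome/noise model --- validates it, and
#' returns the assembled [n1_model()]. Every violation is reported by
#' name in a single error; unknown keys are rejected.
#'
#' The schema (YAML shown; JSON is equivalent):
#' \preformatted{
#' design:
#'   n_blocks: 2
#'   n_treatments: 2
#'   period_length_days: 30
#'   block_orders: [[2, 1], [2, 1]]   # or "random" with order_seed
#'   sampling:
#'     mode: regular                   # regular | per_period_end | explicit
#'     interval_days: 1                # regular mode
#'     offset_days: 1                  # optional, defaults to the interval
#'     times: [1, 2, 3]                # explicit mode
#'   dt_days: 0.1                      # optional
#' treatments:
#'   - {effect: -40, wash_in_tau: 6, wash_out_gamma: 3}
#'   - {effect: -30, wash_in_tau: 2, wash_out_gamma: 10}
#' outcome:
#'   baseline_init: 160
#'   sensitivity: 0.5
#'   sigma_b: 0.9
#'   sigma_p: 1.0
#'   sigma_o: 4.0
#'   outcome_type: numeric             # optional, default numeric
#'   outcome_max: 6                    # score / proportion only
#' }
#'
#' @param path Path to a `.yaml`, `.yml` or `.json` configuration file.
#' @return An [n1_model()] object.
#' @seealso [write_n1_config()] for the inverse.
#' @export
read_n1_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  build_model_from_config(cfg)
}

build_model_from_config <- function(cfg) {
  errs <- character()
  note <- function(...) errs <<- c(errs, sprintf(...))

  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      note("%s: unknown key(s) %s", where, paste(unknown, collapse = ", "))
  }
  check_keys(cfg, c("design", "treatments", "outcome"), "config")
  for (sect in c("design", "treatments", "outcome"))
    if (is.null(cfg[[sect]])) note("config: missing section '%s'", sect)
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  d <- cfg$design
  check_keys(d, c("n_blocks", "n_treatments", "period_length_days",
                  "block_orders", "order_seed", "sampling", "dt_days"),
             "design")
  for (k in c("n_blocks", "n_treatments", "period_length_days"))
    if (is.null(d[[k]])) note("design: missing key '%s'", k)

  o <- cfg$outcome
  check_keys(o, c("baseline_init", "sensitivity", "sigma_b", "sigma_p",
                  "sigma_o", "outcome_type", "outcome_max"), "outcome")
  for (k in c("baseline_init", "sensitivity"))
    if (is.null(o[[k]])) note("outcome: missing key '%s'", k)

  trts <- cfg$treatments
  if (is.data.frame(trts)) trts <- split(trts, seq_len(nrow(trts)))
  if (!is.list(trts) || length(trts) == 0)
    note("treatments: must be a non-empty list")
  else for (j in seq_along(trts)) {
    check_keys(trts[[j]], c("effect", "wash_in_tau", "wash_out_gamma"),
               sprintf("treatments[%d]", j))
    for (k in c("effect", "wash_in_tau", "wash_out_gamma"))
      if (is.null(trts[[j]][[k]]))
        note("treatments[%d]: missing key '%s'", j, k)
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  total <- d$n_blocks * d$n_treatments * d$period_length_days
  dt <- if (is.null(d$dt_days)) min(0.1, d$period_length_days / 10)
        else d$dt_days

  orders <- d$block_orders
  if (is.character(orders) && identical(orders, "random")) {
    orders <- randomize_block_orders(d$n_blocks, d$n_treatments,
                                     seed = d$order_seed)
  } else if (!is.null(orders) && !is.list(orders)) {
    orders <- apply(orders, 1, identity, simplify = FALSE)
  }

  s <- d$sampling
  times <- if (is.null(s)) {
    regular_sampling_times(total, 1, 1)
  } else {
    check_keys(s, c("mode", "interval_days", "offset_days", "times"),
               "design$sampling")
    if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
    mode <- if (is.null(s$mode)) "regular" else s$mode
    switch(mode,
      regular = regular_sampling_times(
        total, s$interval_days,
        if (is.null(s$offset_days)) s$interval_days else s$offset_days),
      per_period_end = d$period_length_days *
        seq_len(d$n_blocks * d$n_treatments) - dt,
      explicit = as.numeric(s$times),
      stop("design$sampling: unknown mode '", mode, "'", call. = FALSE))
  }

  design <- n1_design(d$n_blocks, d$n_treatments, d$period_length_days,
                      block_orders = orders, sampling_times = times,
                      dt = dt)
  profiles <- unname(lapply(trts, function(t)
    treatment_profile(t$effect, t$wash_in_tau, t$wash_out_gamma)))
  outcome <- outcome_model(
    o$baseline_init, o$sensitivity,
    sigma_b = if (is.null(o$sigma_b)) 0 else o$sigma_b,
    sigma_p = if (is.null(o$sigma_p)) 0 else o$sigma_p,
    sigma_o = if (is.null(o$sigma_o)) 0 else o$sigma_o,
    outcome_type = if (is.null(o$outcome_type)) "numeric" else o$outcome_type,
    outcome_max = o$outcome_max)
  n1_model(design, profiles, outcome)
}

#' Write a study model back to a configuration file
#'
#' Serializes an [n1_model()] to the schema read by [read_n1_config()],
#' with explicit sampling times (so the round trip is exact regardless of
#' how the times were first produced).
#'
#' @param model An [n1_model()] object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_n1_config <- function(model, path) {
  stopifnot(inherits(model, "n1_model"))
  d <- model$design
  o <- model$outcome
  cfg <- list(
    design = list(
      n_blocks = d$n_blocks,
      n_treatments = d$n_treatments,
      period_length_days = d$period_length,
      block_orders = d$block_orders,
      sampling = list(mode = "explicit", times = d$sampling_times),
      dt_days = d$dt),
    treatments = lapply(model$treatments, function(t)
      list(effect = t$effect, wash_in_tau = t$wash_in_tau,
           wash_out_gamma = t$wash_out_gamma)),
    outcome = c(
      list(baseline_init = o$baseline_init, sensitivity = o$sensitivity,
           sigma_b = o$sigma_b, sigma_p = o$sigma_p, sigma_o = o$sigma_o,
           outcome_type = o$outcome_type),
      if (!is.null(o$outcome_max)) list(outcome_max = o$outcome_max)))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Write / read a tidy table as CSV at full numeric precision
#'
#' Plain-text CSV round trip for simulation and sweep tables: numeric
#' columns are written with 17 significant digits so that reading the
#' file back reproduces the doubles bit for bit; a header row is always
#' present and column order is preserved.
#'
#' @param table A data frame.
#' @param path Output file path.
#' @return `write_tidy_csv()` returns `path` invisibly;
#'   `read_tidy_csv()` returns a data frame.
#' @export
write_tidy_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- as.data.frame(lapply(table, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), optional = TRUE)
  names(out) <- names(table)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = TRUE)
  invisible(path)
}

#' @rdname write_tidy_csv
#' @export
read_tidy_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) == 0) stop("empty file: ", path, call. = FALSE)
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("malformed CSV %s: line %d has %d fields, expected %d",
                 path, bad[1], nf[bad[1]], nf[1]), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
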