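#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a command-line or scripted run
#' exactly: the command name, the full parameter set, the root seed, the
#' package and R versions, and a timestamp. The companion CLI writes one
#' manifest next to every output file.
#'
#' @param path Output path for the JSON manifest.
#' @param command Short name of the operation performed.
#' @param seed Integer root seed used for the run.
#' @param params Named list of the remaining parameters (config echo,
#'   grids, replicate counts, output paths, ...).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, seed, params = list()) {
  manifest <- list(
    command = command,
    seed = seed,
    params = params,
    package = "n1sim",
    package_version = as.character(utils::packageVersion("n1sim")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
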