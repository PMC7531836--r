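#' Load a scenario configuration from YAML or JSON
#'
#' Unknown fields and unknown knockout names are schema errors reported
#' with the offending field; missing fields take the [scenario_config()]
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` document.
#' @return A validated [scenario_config()].
#' @export
load_scenario <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(doc)) stop("scenario document must be a mapping")
  allowed <- setdiff(names(formals(scenario_config)), "")
  bad <- setdiff(names(doc), allowed)
  if (length(bad))
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  if (!is.null(doc$overrides)) doc$overrides <- unlist(doc$overrides)
  if (!is.null(doc$knockouts)) doc$knockouts <- as.character(doc$knockouts)
  if (!is.null(doc$regimen)) {
    rg <- doc$regimen
    doc$regimen <- regimen(rg$time %||% rg$day, rg$dose_mg)
  }
  do.call(scenario_config, doc)
}

#' Save a scenario configuration as YAML
#'
#' `save_scenario()` followed by [load_scenario()] reproduces the
#' configuration.
#'
#' @param cfg A [scenario_config()].
#' @param path Output path (`.yaml`).
#' @return The path, invisibly.
#' @export
save_scenario <- function(cfg, path) {
  doc <- unclass(cfg)
  doc <- doc[!vapply(doc, is.null, TRUE)]
  if (!is.null(doc$regimen))
    doc$regimen <- list(time = doc$regimen$time, dose_mg = doc$regimen$dose_mg)
  if (!is.null(doc$overrides)) doc$overrides <- as.list(doc$overrides)
  if (length(doc$knockouts) == 0) doc$knockouts <- NULL
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Run record for reproducibility
#'
#' Snapshot of everything a rerun needs: the scenario, a digest of
#' parameter provenance, solver options and the package version.
#'
#' @param cfg A [scenario_config()].
#' @param opts Solver options.
#' @param outputs Character vector of output file names produced by the run.
#' @return List of class `run_record`.
#' @export
run_record <- function(cfg, opts = ap_solver_options(), outputs = character(0)) {
  params <- ap_parameters(cfg$context)
  prov <- table(params$table$provenance)
  structure(list(
    scenario = unclass(cfg),
    parameter_provenance = as.list(prov),
    n_parameters = length(params$values),
    solver = unclass(opts),
    package_version = as.character(utils::packageVersion("altpathsim")),
    outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "run_record")
}

#' Write a run record as JSON
#' @param rec A [run_record()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_record <- function(rec, path) {
  rec <- unclass(rec)
  rec$scenario$regimen <- if (!is.null(rec$scenario$regimen))
    as.data.frame(rec$scenario$regimen) else NULL
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
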