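#' Normalized sum of squared residuals for one dataset
#'
#' `SSR = sum((y - m)^2) / n`; normalization by the number of observations
#' gives every study equal weight in a multi-study objective.
#'
#' @param dataset List (or data frame) with an element `y` of observations
#'   and either `m` (precomputed model values) or `predict`, a function of
#'   a parameter vector returning model values.
#' @param x Parameter vector forwarded to `dataset$predict`.
#' @return Non-negative scalar.
#' @export
ssr <- function(dataset, x = NULL) {
  y <- dataset$y
  if (length(y) == 0) stop("empty dataset")
  m <- if (!is.null(dataset$predict)) dataset$predict(x) else dataset$m
  if (length(m) != length(y))
    stop("model prediction length != observation length")
  sum((y - m)^2) / length(y)
}

#' Multi-dataset objective: sum of per-dataset SSRs
#'
#' @param problem A [calibration_problem()] (or list with `datasets`).
#' @param x Parameter vector.
#' @return Scalar objective value.
#' @export
ssr_sum <- function(problem, x = NULL) {
  ds <- problem$datasets
  if (length(ds) == 0) stop("calibration problem has no datasets")
  sum(vapply(ds, ssr, 0, x = x))
}

#' Define a calibration problem
#'
#' @param datasets List of datasets, each with observations `y` and a
#'   `predict(x)` function mapping the named free-parameter vector to model
#'   values.
#' @param start Named numeric vector of starting values for the free
#'   parameters (> 0: the search runs on the log10 scale).
#' @param span Half-width of the search box in decades around the start
#'   (default, and maximum, 7).
#' @return List of class `calibration_problem`.
#' @export
calibration_problem <- function(datasets, start, span = 7) {
  if (span <= 0 || span > 7)
    stop("search span must be in (0, 7] decades")
  if (is.null(names(start)) || any(!nzchar(names(start))))
    stop("start values must be named")
  if (any(start <= 0))
    stop("log-scale search requires positive starting values")
  structure(list(datasets = datasets, start = start, span = span),
            class = "calibration_problem")
}

#' Iterative one-parameter-at-a-time least-squares optimization
#'
#' At each iteration every free parameter is optimized alone by a bounded
#' scalar search on the log10 scale within +/- `span` decades of its
#' current value; only the single parameter producing the lowest objective
#' is updated.  Iterations stop when the relative improvement of the
#' objective falls below `tolfun_rel` (1%).  The scalar searches use
#' [stats::optimize()] with absolute tolerance `tolx` on the log10 scale.
#'
#' By construction the objective is non-increasing across iterations.
#'
#' @param problem A [calibration_problem()].
#' @param tolx Scalar-search tolerance on log10 parameters (default 0.01).
#' @param tolfun_rel Relative objective-improvement stopping threshold
#'   (default 0.01, i.e. stop below 1% improvement).
#' @param max_iter Safety cap on iterations.
#' @return List: `par` (fitted named vector), `objective`, `log`
#'   (data frame: iteration, parameter, value, objective), `converged`.
#' @export
coordinate_descent <- function(problem, tolx = 0.01, tolfun_rel = 0.01,
                               max_iter = 50) {
  par <- problem$start
  if (length(par) < 1) stop("need at least one free parameter")
  f <- function(p) ssr_sum(problem, p)
  obj <- f(par)
  log_rows <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    best <- list(obj = obj, name = NA_character_, value = NA_real_)
    for (nm in names(par)) {
      lo <- log10(par[[nm]]) - problem$span
      hi <- log10(par[[nm]]) + problem$span
      res <- tryCatch(
        stats::optimize(function(lx) {
          p <- par; p[[nm]] <- 10^lx; f(p)
        }, lower = lo, upper = hi, tol = tolx),
        error = function(e) NULL)
      if (!is.null(res) && res$objective < best$obj) {
        best <- list(obj = res$objective, name = nm, value = 10^res$minimum)
      }
    }
    if (is.na(best$name)) { converged <- TRUE; break }
    improvement <- (obj - best$obj) / max(obj, .Machine$double.eps)
    par[[best$name]] <- best$value
    obj <- best$obj
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(iteration = it, parameter = best$name, value = best$value,
                 objective = obj)
    if (improvement < tolfun_rel) { converged <- TRUE; break }
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(iteration = integer(0), parameter = character(0),
               value = numeric(0), objective = numeric(0))
  list(par = par, objective = obj, log = log_df, converged = converged)
}

#' Local one-at-a-time sensitivity analysis
#'
#' Perturbs each parameter by the requested fractions (both directions) and
#' reports the relative change of a scalar model output.
#'
#' @param evaluate Function of a named parameter vector returning the
#'   scalar target (e.g. the multi-study objective, or MAC formation in a
#'   reference assay).
#' @param par Named baseline parameter vector.
#' @param deltas Perturbation fractions (default 1, 5, 10, 20%).
#' @return Data frame: parameter, delta (signed fraction), value,
#'   relative_change (of the target vs. baseline).
#' @export
local_sensitivity <- function(evaluate, par,
                              deltas = c(0.01, 0.05, 0.10, 0.20)) {
  base <- evaluate(par)
  rows <- list()
  for (nm in names(par)) {
    for (d in c(-deltas, deltas)) {
      p <- par
      p[[nm]] <- par[[nm]] * (1 + d)
      val <- evaluate(p)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, delta = d, value = val,
        relative_change = if (base != 0) (val - base) / base else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity of rabbit-assay MAC formation
#'
#' Local sensitivity of terminal-pathway activation, quantified as MAC
#' formation in the standard rabbit erythrocyte assay (30 min readout, 20%
#' serum, 1e11 cells/L), to initial concentrations of AP proteins.
#'
#' @param species Character vector of species whose initial concentration
#'   is perturbed.
#' @param deltas Perturbation fractions.
#' @param opts Solver options.
#' @return Data frame as in [local_sensitivity()] (parameter column holds
#'   species names; value is MAC per cell).
#' @export
rabbit_assay_sensitivity <- function(species = c("C3", "FB", "FD", "FH",
                                                 "C5", "C6", "C7", "C8",
                                                 "C9", "P", "FI"),
                                     deltas = c(0.10),
                                     opts = ap_solver_options()) {
  cfg <- scenario_config(context = "in_vitro", serum_fraction = 0.2,
                         cell_type = "rabbit", cell_conc = 1e11,
                         readout_time = 1800)
  sc <- build_scenario(cfg)
  base_init <- sc$init
  run_mac <- function(init) {
    tr <- ap_simulate(sc$net, init = init,
                      times = seq(0, cfg$readout_time, length.out = 7),
                      opts = opts, time_unit = "s")
    macs_per_cell(tr$state[.MAC_SPECIES, ncol(tr$state)], cfg$cell_conc)
  }
  base <- run_mac(base_init)
  rows <- list()
  for (nm in species) {
    for (d in c(-deltas, deltas)) {
      init <- base_init
      init[[nm]] <- init[[nm]] * (1 + d)
      val <- run_mac(init)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, delta = d, value = val,
        relative_change = if (base != 0) (val - base) / base else NA_real_)
    }
  }
  do.call(rbind, rows)
}
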