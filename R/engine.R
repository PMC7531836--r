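#' Solver options
#'
#' Defaults reflect the stiffness of the system: species concentrations span
#' picomolar to micromolar and elementary time scales span the 60-microsecond
#' nascent-C3b hydrolysis to 60-day cell turnover.
#'
#' @param rtol Relative tolerance.
#' @param atol Absolute tolerance (molar).
#' @param max_step Maximum solver step (same unit as the time grid).
#' @param ss_residual Steady-state residual threshold: the largest relative
#'   rate of change (per slowest-turnover half-life) accepted as stationary.
#' @return A list of class `ap_solver_options`.
#' @export
ap_solver_options <- function(rtol = 1e-8, atol = 1e-16, max_step = Inf,
                              ss_residual = 1e-4) {
  stopifnot(rtol > 0, atol > 0, ss_residual > 0)
  structure(list(rtol = rtol, atol = atol, max_step = max_step,
                 ss_residual = ss_residual), class = "ap_solver_options")
}

## Compile a network into index structures for fast derivative evaluation.
## time_unit "s" keeps the catalogued second-based constants; "day"
## multiplies every rate constant (not the Michaelis constants) by 86400.
.compile_network <- function(net, time_unit = c("s", "day")) {
  time_unit <- match.arg(time_unit)
  tf <- if (time_unit == "day") 86400 else 1
  ids <- net$species$id
  n_sp <- length(ids)
  idx <- stats::setNames(seq_len(n_sp), ids)
  pv <- net$params$values

  n_rx <- length(net$reactions)
  kind <- integer(n_rx); i1 <- integer(n_rx); i2 <- integer(n_rx)
  ie <- integer(n_rx); k1 <- numeric(n_rx); k2 <- numeric(n_rx)
  for (j in seq_len(n_rx)) {
    r <- net$reactions[[j]]
    ks <- unname(pv[r$params])
    fac <- if (is.null(r$factor)) 1 else r$factor
    re <- names(r$reactants)
    switch(r$kind,
      mass_action_order1 = { kind[j] <- 1L; i1[j] <- idx[[re[1]]]
        k1[j] <- ks[1] * tf * fac },
      mass_action_order2 = { kind[j] <- 2L; i1[j] <- idx[[re[1]]]
        i2[j] <- idx[[re[2]]]; k1[j] <- ks[1] * tf * fac },
      michaelis_menten = { kind[j] <- 3L
        sub <- setdiff(re, r$enzyme); if (!length(sub)) sub <- re[1]
        i1[j] <- idx[[sub[1]]]; ie[j] <- idx[[r$enzyme]]
        k1[j] <- ks[1] * tf * fac; k2[j] <- ks[2] },
      zero_order_synthesis = { kind[j] <- 4L; k1[j] <- ks[1] * tf * fac },
      mass_action_reversible = { kind[j] <- 5L; i1[j] <- idx[[re[1]]]
        i2[j] <- idx[[re[2]]]; ie[j] <- idx[[names(r$products)[1]]]
        k1[j] <- ks[1] * tf; k2[j] <- ks[2] * tf },
      stop("unknown rate-law kind: ", r$kind))
  }
  S <- stoichiometry_matrix(net)
  storage.mode(S) <- "double"
  nz <- which(S != 0, arr.ind = TRUE)
  ti <- nz[, 1] - 1L; tj <- nz[, 2] - 1L; tv <- S[nz]

  ## state-dependent hemolytic elimination (in vivo only): surface-bound
  ## species and the cells themselves are cleared at ks + kH(state)
  hemo_on <- identical(net$context, "in_vivo") && "E" %in% ids &&
    .MAC_SPECIES %in% ids
  if (hemo_on) {
    mask <- which(net$species$surface_bound | ids == "E") - 1L
    mac_i <- idx[[.MAC_SPECIES]] - 1L
    e_i <- idx[["E"]] - 1L
    gamma <- pv[["gamma_hill"]]; mac50 <- pv[["mac50"]]
    tau <- pv[["tau_hemolysis"]] * ifelse(time_unit == "day", 1, 86400)
  } else {
    mask <- integer(0); mac_i <- 0L; e_i <- 0L
    gamma <- 1; mac50 <- 1; tau <- 1
  }
  i1c <- i1 - 1L; i2c <- pmax(i2 - 1L, 0L); iec <- pmax(ie - 1L, 0L)

  rhs_core <- function(t, y) {
    ap_rhs_eval(y, kind, i1c, i2c, iec, k1, k2, ti, tj, tv, n_sp,
                hemo_on, mask, mac_i, e_i, gamma, mac50, tau, 99.9)
  }
  list(rhs = rhs_core, species = ids, n = n_sp, time_unit = time_unit,
       S = S)
}

#' Evaluate the derivative (right-hand side) of a network
#'
#' Mass-action and Michaelis-Menten rates assembled through the
#' stoichiometry matrix; for in-vivo networks the state-dependent
#' hemolytic elimination `k_el,S = k_s + k_H(state)` is applied to all
#' surface-bound species and the cells inside the derivative itself.
#'
#' @param net An `ap_network`.
#' @param state Named or unnamed concentration vector (molar), length equal
#'   to the number of species.
#' @param t Time (unused by the autonomous laws; kept for the ODE contract).
#' @param time_unit `"s"` or `"day"`.
#' @return Numeric derivative vector (molar per time unit).
#' @export
rhs <- function(net, state, t = 0, time_unit = "s") {
  cmp <- .compile_network(net, time_unit)
  if (length(state) != cmp$n)
    stop("state length ", length(state), " != number of species ", cmp$n)
  if (any(state < -1e-12))
    stop("negative state beyond tolerance in species: ",
         paste(cmp$species[state < -1e-12], collapse = ", "))
  if (!is.null(names(state))) state <- state[cmp$species]
  stats::setNames(cmp$rhs(t, as.numeric(state)), cmp$species)
}

#' Integrate a network over a time grid
#'
#' Stiff integration with `deSolve::lsoda`.  Dosing events (intravenous
#' boluses) are applied as instantaneous additions to the drug species.
#'
#' @param net An `ap_network`.
#' @param init Named initial concentration vector; defaults to
#'   [initial_state()] of the network.
#' @param times Strictly increasing time grid (seconds for in-vitro, days
#'   for in-vivo).
#' @param opts Solver options, see [ap_solver_options()].
#' @param time_unit `"s"` or `"day"`.
#' @param events Optional data frame with columns `var`, `time`, `value`,
#'   `method` (deSolve event specification); used for bolus doses.
#' @return An object of class `ap_trajectory`: list with `times`, `state`
#'   (species x times matrix, molar), `species`, `time_unit`, `events`.
#' @export
ap_simulate <- function(net, init = NULL, times, opts = ap_solver_options(),
                     time_unit = "s", events = NULL) {
  cmp <- .compile_network(net, time_unit)
  if (is.null(init)) init <- initial_state(net)
  if (!is.null(names(init))) {
    y0 <- stats::setNames(numeric(cmp$n), cmp$species)
    common <- intersect(names(init), cmp$species)
    y0[common] <- init[common]
  } else {
    stopifnot(length(init) == cmp$n)
    y0 <- stats::setNames(as.numeric(init), cmp$species)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  req_times <- times
  if (!is.null(events))
    times <- sort(unique(c(times, events$time)))
  f <- function(t, y, parms) list(cmp$rhs(t, y))
  ev <- if (!is.null(events)) list(data = events) else NULL
  hmax <- if (is.finite(opts$max_step)) opts$max_step else NULL
  sol <- NULL
  last_err <- NULL
  ## sparse BDF first; fall back to dense BDF on the rare step failure
  for (method in c("lsodes", "vode")) {
    sol <- tryCatch(
      suppressWarnings(deSolve::ode(
        y = y0, times = times, func = f, parms = NULL, method = method,
        rtol = opts$rtol, atol = opts$atol, hmax = hmax,
        events = ev, maxsteps = 2e5)),
      error = function(e) e)
    if (!inherits(sol, "error")) {
      di <- attr(sol, "istate")
      if (is.null(di) || di[1] >= 0) break
      last_err <- paste0("istate ", di[1], " near t = ", sol[nrow(sol), 1])
      sol <- NULL
    } else {
      last_err <- conditionMessage(sol)
      sol <- NULL
    }
  }
  if (is.null(sol))
    stop("stiff integration failed (", last_err, ")")
  keep <- match(req_times, sol[, 1])
  sol <- sol[keep, , drop = FALSE]
  st <- t(unclass(sol)[, -1, drop = FALSE])
  structure(list(times = sol[, 1], state = st, species = cmp$species,
                 time_unit = time_unit, events = events),
            class = "ap_trajectory")
}

#' Extract one species' time course from a trajectory
#' @param traj An `ap_trajectory`.
#' @param species Species id.
#' @return Numeric vector along the time grid.
#' @export
trajectory_species <- function(traj, species) {
  if (!species %in% traj$species) stop("unknown species '", species, "'")
  traj$state[species, ]
}

#' Write a trajectory as tidy CSV (time, species, concentration)
#' @param traj An `ap_trajectory`.
#' @param path Output path.
#' @param species Optional subset of species ids.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path, species = NULL) {
  sp <- if (is.null(species)) traj$species else species
  df <- do.call(rbind, lapply(sp, function(s)
    data.frame(time = traj$times, species = s,
               concentration = traj$state[s, ],
               time_unit = traj$time_unit)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Steady state of an open (synthesis + elimination) network
#'
#' Integrates over at least ten times the slowest turnover half-life
#' (erythrocytes, 60 days), doubling the horizon until the largest relative
#' rate of change falls below the residual threshold.
#'
#' @param net An in-vivo `ap_network`.
#' @param init Optional initial state (defaults to the catalogue levels).
#' @param opts Solver options; `ss_residual` is the acceptance threshold on
#'   `max |dx/dt| * T / max(|x|, atol)` with `T` = 60 days.
#' @param t_start Initial integration horizon in days.
#' @param max_horizon Give up (with an error reporting the residual) beyond
#'   this horizon in days.
#' @return Named steady-state concentration vector (molar).
#' @export
steady_state <- function(net, init = NULL, opts = ap_solver_options(),
                         t_start = 600, max_horizon = 4800) {
  has_syn <- any(vapply(net$reactions, function(r)
    r$kind == "zero_order_synthesis", TRUE))
  if (!has_syn)
    stop("steady_state requires an open system with synthesis reactions")
  cmp <- .compile_network(net, "day")
  y <- init
  horizon <- t_start
  repeat {
    tr <- ap_simulate(net, init = y, times = c(0, horizon / 2, horizon),
                   opts = opts, time_unit = "day")
    y <- tr$state[, ncol(tr$state)]
    d <- cmp$rhs(0, y)
    resid <- max(abs(d) * 60 / pmax(abs(y), opts$atol * 1e3))
    if (resid < opts$ss_residual) return(stats::setNames(y, cmp$species))
    if (horizon >= max_horizon)
      stop(sprintf(
        "steady state not reached by t = %g days (relative residual %.3g)",
        horizon, resid))
    horizon <- horizon * 2
  }
}

#' @export
print.ap_trajectory <- function(x, ...) {
  cat("<ap_trajectory> ", length(x$species), " species x ", length(x$times),
      " times [", x$time_unit, "], t in [", min(x$times), ", ",
      max(x$times), "]\n", sep = "")
  invisible(x)
}
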