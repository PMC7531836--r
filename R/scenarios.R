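.KNOCKOUTS <- c("FH_surface", "FH_total", "FI", "CR1", "DAF", "CD59",
                "Vn", "Cn", "P")

#' Declarative scenario configuration
#'
#' One in-silico experiment: assay context, serum fraction, cell type and
#' concentration, regulator knockouts, readout time, optional
#' initial-concentration overrides, eculizumab concentration or dosing
#' regimen, and normalization mode for hemolysis readouts.
#'
#' Knockouts are total ("complete blockage"): a knocked-out regulator is
#' removed from the system, except `FH_surface`, which abolishes only the
#' surface regulatory function of factor H (the association constant
#' `kp_C3bH_surf` is set to 0) while fluid-phase control is preserved.
#'
#' @param context `"in_vitro"` or `"in_vivo"` (in vivo implies undiluted
#'   serum).
#' @param serum_fraction Fraction of normal human serum in (0, 1].
#' @param cell_type `"none"`, `"rabbit"`, `"human"`, `"pnh2"` or `"pnh3"`.
#' @param cell_conc Cells per litre (ignored for `cell_type = "none"`).
#' @param knockouts Character vector drawn from
#'   `FH_surface, FH_total, FI, CR1, DAF, CD59, Vn, Cn, P`.
#' @param readout_time Readout time: seconds in vitro (default 30 minutes),
#'   days in vivo.
#' @param overrides Named numeric vector of initial-concentration overrides
#'   (molar, applied after serum scaling).
#' @param eculizumab Initial eculizumab concentration (molar, in-vitro
#'   inhibition assays).
#' @param regimen An [regimen()] object (in-vivo treatment runs).
#' @param normalization `"water"` (readout is absolute percent lysis),
#'   `"NHS_control"` (normalized to a reference activity) or `"none"`.
#' @param reference_percent Reference lysis for `NHS_control` normalization.
#' @param clone_fraction Fraction of erythrocytes carrying the PNH defect
#'   (fixed at 1 in the reported scenarios; exposed for extension).
#' @param seed Integer seed recorded in the configuration.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(context = c("in_vitro", "in_vivo"),
                            serum_fraction = 1,
                            cell_type = c("none", "rabbit", "human",
                                          "pnh2", "pnh3"),
                            cell_conc = 1e11,
                            knockouts = character(0),
                            readout_time = 1800,
                            overrides = NULL,
                            eculizumab = 0,
                            regimen = NULL,
                            normalization = c("water", "NHS_control", "none"),
                            reference_percent = NULL,
                            clone_fraction = 1,
                            seed = 1L) {
  context <- match.arg(context)
  cell_type <- match.arg(cell_type)
  normalization <- match.arg(normalization)
  if (serum_fraction <= 0 || serum_fraction > 1)
    stop("serum_fraction must be in (0, 1]")
  if (context == "in_vivo" && serum_fraction != 1)
    stop("in-vivo scenarios use undiluted serum (serum_fraction = 1)")
  bad <- setdiff(knockouts, .KNOCKOUTS)
  if (length(bad))
    stop("unknown knockout(s): ", paste(bad, collapse = ", "),
         "; known: ", paste(.KNOCKOUTS, collapse = ", "))
  if (readout_time <= 0) stop("readout_time must be positive")
  structure(list(context = context, serum_fraction = serum_fraction,
                 cell_type = cell_type, cell_conc = cell_conc,
                 knockouts = knockouts, readout_time = readout_time,
                 overrides = overrides, eculizumab = eculizumab,
                 regimen = regimen, normalization = normalization,
                 reference_percent = reference_percent,
                 clone_fraction = clone_fraction, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Build the network and initial state for a scenario
#'
#' @param cfg A [scenario_config()].
#' @return List with elements `net` (configured `ap_network`) and `init`
#'   (named initial state, molar).
#' @export
build_scenario <- function(cfg) {
  params <- ap_parameters(context = cfg$context)
  net <- build_full_network(params)
  if (cfg$context == "in_vitro") {
    tags <- if (cfg$cell_type == "none") "ap_fluid" else
      c("ap_fluid", "ap_surface")
    extra <- if (cfg$eculizumab > 0) 224L else integer(0)
    net <- subset_reactions(net, tags = tags, extra_ids = extra)
    net$context <- "in_vitro"
  }
  if (cfg$cell_type != "none")
    net <- configure_surface(net, cfg$cell_type, cfg$cell_conc)
  ## knockouts (absolute, applied after surface configuration)
  for (ko in cfg$knockouts) {
    if (ko == "FH_surface") {
      net$params <- set_parameter(net$params, "kp_C3bH_surf", 0)
    } else {
      sp <- if (ko == "FH_total") "FH" else ko
      if (sp %in% net$species$id)
        net$species$init_conc[net$species$id == sp] <- 0
      syn <- paste0("s_", sp)
      if (cfg$context == "in_vivo" && syn %in% names(net$params$values))
        net$params <- set_parameter(net$params, syn, 0)
    }
  }
  init <- initial_state(net, cfg$serum_fraction)
  if (!is.null(cfg$overrides)) {
    bad <- setdiff(names(cfg$overrides), names(init))
    if (length(bad))
      stop("override for unknown species: ", paste(bad, collapse = ", "))
    init[names(cfg$overrides)] <- cfg$overrides
  }
  if (cfg$eculizumab > 0 && "Ecu" %in% names(init))
    init[["Ecu"]] <- cfg$eculizumab
  list(net = net, init = init)
}

#' Fluid-phase activation assay
#'
#' Simulates the closed fluid-phase system (no cells, no turnover) and
#' returns the time courses of the canonical activation markers.
#'
#' @param cfg A [scenario_config()] with `cell_type = "none"`.
#' @param n_points Number of output times.
#' @param opts Solver options.
#' @return Data frame: `time_s` plus marker columns
#'   (C3, C3b, iC3b, C3a, Ba, Bb, C3dg), molar.
#' @export
run_fluid_phase_assay <- function(cfg, n_points = 61,
                                  opts = ap_solver_options()) {
  if (cfg$cell_type != "none")
    stop("fluid-phase assay configuration must not contain cells")
  sc <- build_scenario(cfg)
  times <- seq(0, cfg$readout_time, length.out = n_points)
  tr <- ap_simulate(sc$net, init = sc$init, times = times, opts = opts,
                    time_unit = "s")
  markers <- intersect(c("C3", "C3b", "iC3b", "C3a", "Ba", "Bb", "C3dg"),
                       tr$species)
  out <- data.frame(time_s = tr$times)
  for (m in markers) out[[m]] <- tr$state[m, ]
  out
}

#' Hemolytic assay
#'
#' Simulates the fluid and surface AP on the configured cells and evaluates
#' the Hill dose-response at the readout time.  In vitro, lysed cells are
#' not removed from the incubation (erythrocyte turnover is an in-vivo
#' process); the readout is the percent of cells carrying a lytic MAC load.
#'
#' @param cfg A [scenario_config()] with cells and `context = "in_vitro"`.
#' @param opts Solver options.
#' @param model Hemolysis dose-response parameters.
#' @return List: `percent` (normalized per `cfg$normalization`),
#'   `raw_percent`, `mac_per_cell`, `trajectory`.
#' @export
run_hemolytic_assay <- function(cfg, opts = ap_solver_options(),
                                model = NULL) {
  if (cfg$cell_type == "none")
    stop("hemolytic assay needs cells; got cell_type = 'none'")
  if (cfg$context != "in_vitro")
    stop("hemolytic assays are in-vitro scenarios")
  sc <- build_scenario(cfg)
  if (is.null(model)) {
    pv <- sc$net$params$values
    model <- hemolysis_model(gamma = pv[["gamma_hill"]],
                             mac50 = pv[["mac50"]],
                             tau = pv[["tau_hemolysis"]] / 86400)
  }
  times <- seq(0, cfg$readout_time, length.out = 31)
  tr <- ap_simulate(sc$net, init = sc$init, times = times, opts = opts,
                    time_unit = "s")
  mac_conc <- unname(tr$state[.MAC_SPECIES, ncol(tr$state)])
  mac <- macs_per_cell(mac_conc, cfg$cell_conc)
  raw <- percent_hemolysis(mac, model)
  pct <- normalize_hemolysis(raw, reference = cfg$reference_percent,
                             mode = cfg$normalization)
  list(percent = pct, raw_percent = raw, mac_per_cell = mac,
       trajectory = tr)
}

#' Normalize a hemolysis readout
#'
#' @param raw Raw percent hemolysis.
#' @param reference Reference activity (percent) for `NHS_control` mode.
#' @param mode `"water"` (identity: lysis in water defines 100%),
#'   `"NHS_control"` (percent of the reference serum's activity) or
#'   `"none"`.
#' @return Normalized percent.
#' @export
normalize_hemolysis <- function(raw, reference = NULL,
                                mode = c("water", "NHS_control", "none")) {
  mode <- match.arg(mode)
  if (mode %in% c("water", "none")) return(raw)
  if (is.null(reference) || !is.numeric(reference) || reference <= 0)
    stop("NHS_control normalization requires a positive reference activity")
  100 * raw / reference
}

#' Pairwise regulator-knockout hemolysis grid
#'
#' Simulates single and pairwise suppression of AP regulators on human
#' erythrocytes; the diagonal holds the single knockouts and the matrix is
#' symmetric by construction.
#'
#' @param base_cfg A human-cell in-vitro [scenario_config()].
#' @param regulators Regulator names (subset of the knockout vocabulary).
#' @param opts Solver options.
#' @return Numeric matrix of percent hemolysis with regulator dimnames.
#' @export
run_knockout_grid <- function(base_cfg,
                              regulators = c("FH_total", "FH_surface", "FI",
                                             "CD59", "DAF", "CR1", "P",
                                             "Vn", "Cn"),
                              opts = ap_solver_options()) {
  if (base_cfg$cell_type != "human")
    stop("knockout grid is defined for human erythrocytes")
  bad <- setdiff(regulators, .KNOCKOUTS)
  if (length(bad)) stop("unknown regulator(s): ", paste(bad, collapse = ", "))
  n <- length(regulators)
  M <- matrix(NA_real_, n, n, dimnames = list(regulators, regulators))
  for (i in seq_len(n)) {
    for (j in i:n) {
      kos <- unique(c(regulators[i], regulators[j]))
      cfg <- base_cfg
      cfg$knockouts <- kos
      M[i, j] <- M[j, i] <- run_hemolytic_assay(cfg, opts = opts)$percent
    }
  }
  M
}

#' PNH (or healthy) in-vivo steady state with biomarker panel
#'
#' Runs the full in-vivo model (fluid + surface AP, hemolysis-coupled cell
#' elimination, protein and cell turnover) to homeostasis for the given
#' erythrocyte phenotype and reports the hematological biomarkers.
#'
#' @param type `2` or `3` for PNH type 2/3, or `"healthy"`.
#' @param opts Solver options.
#' @param t_start,max_horizon Passed to [steady_state()].
#' @return List: `panel` (one-row biomarker data frame), `state` (named
#'   steady-state concentrations), `mac_per_cell`, `percent_hemolysis`.
#' @export
run_pnh_steady_state <- function(type = 3,
                                 opts = ap_solver_options(atol = 1e-18),
                                 t_start = 600, max_horizon = 4800) {
  cell_type <- if (identical(type, "healthy")) "human"
               else paste0("pnh", type)
  if (!cell_type %in% c("human", "pnh2", "pnh3"))
    stop("type must be 2, 3 or 'healthy'")
  params <- ap_parameters("in_vivo")
  net <- build_full_network(params)
  net <- configure_surface(net, cell_type, cell_conc = 5e12)
  ss <- steady_state(net, init = initial_state(net), opts = opts,
                     t_start = t_start, max_horizon = max_horizon)
  cells_uL <- ss[["E"]] * 6.02214076e23 * 1e-6   # cells per microlitre
  mac <- macs_per_cell(ss[[.MAC_SPECIES]], ss[["E"]] * 6.02214076e23)
  pv <- params$values
  model <- hemolysis_model(pv[["gamma_hill"]], pv[["mac50"]],
                           pv[["tau_hemolysis"]])
  list(panel = biomarker_panel(cells_uL), state = ss,
       mac_per_cell = mac,
       percent_hemolysis = percent_hemolysis(mac, model))
}

#' Eculizumab treatment of a PNH patient
#'
#' Starts from the untreated PNH steady state, applies the dosing regimen
#' as intravenous boluses and follows the hematological biomarkers.
#'
#' @param type PNH type (2 or 3).
#' @param reg An [regimen()] object; `NULL` uses the clinical default for
#'   `months` months.  An empty regimen is an error.
#' @param months Simulated horizon in months.
#' @param opts Solver options.
#' @param n_points Output grid size.
#' @param drug [drug_params()].
#' @return Data frame: `time_day`, `hb_g_dL`, `hct_pct`, `ldh_U_L`,
#'   `cells_per_uL`, `ecu_free_M`, `c5_free_M`.
#' @export
run_treatment <- function(type = 2, reg = NULL, months = 36,
                          opts = ap_solver_options(atol = 1e-18),
                          n_points = 145, drug = drug_params()) {
  if (is.null(reg)) reg <- default_regimen(months)
  if (nrow(reg) == 0) stop("empty regimen")
  ss <- run_pnh_steady_state(type, opts = opts)
  params <- ap_parameters("in_vivo")
  net <- build_full_network(params)
  net <- configure_surface(net, paste0("pnh", type), cell_conc = 5e12)
  horizon <- months * 30.44
  times <- sort(unique(c(seq(0, horizon, length.out = n_points))))
  ev <- regimen_events(reg[reg$time <= horizon, , drop = FALSE], drug)
  tr <- ap_simulate(net, init = ss$state, times = times, opts = opts,
                    time_unit = "day", events = ev)
  cells_uL <- tr$state["E", ] * 6.02214076e23 * 1e-6
  hb <- hemoglobin(cells_uL)
  data.frame(time_day = tr$times, hb_g_dL = hb,
             hct_pct = hematocrit(cells_uL), ldh_U_L = ldh(hb),
             cells_per_uL = cells_uL,
             ecu_free_M = tr$state["Ecu", ], c5_free_M = tr$state["C5", ])
}

#' In-vitro eculizumab inhibition curve
#'
#' Dose scan of in-vitro hemolysis inhibition on PNH erythrocytes in
#' acidified serum, reported relative to the drug-free assay.
#'
#' @param concentrations Eculizumab concentrations (molar).
#' @param cfg Base assay configuration (default: PNH type-2 cells, 60%
#'   acidified serum, 1e11 cells/L, 30-minute readout).
#' @param opts Solver options.
#' @return Data frame: `ecu_M`, `percent` (absolute lysis),
#'   `percent_of_control`.
#' @export
run_inhibition_curve <- function(concentrations,
                                 cfg = scenario_config(
                                   context = "in_vitro",
                                   serum_fraction = 0.6,
                                   cell_type = "pnh2",
                                   cell_conc = 1e11,
                                   readout_time = 1800),
                                 opts = ap_solver_options()) {
  base <- run_hemolytic_assay(cfg, opts = opts)$raw_percent
  pct <- vapply(concentrations, function(cc) {
    cfg$eculizumab <- cc
    run_hemolytic_assay(cfg, opts = opts)$raw_percent
  }, 0)
  data.frame(ecu_M = concentrations, percent = pct,
             percent_of_control = if (base > 0) 100 * pct / base else NA)
}

#' Half-maximal inhibitory concentration from an inhibition curve
#'
#' Log-linear interpolation of the concentration at which lysis falls to
#' half the drug-free control.
#'
#' @param curve Output of [run_inhibition_curve()].
#' @return IC50 (molar), `NA` if the curve does not cross 50%.
#' @export
ic50_from_curve <- function(curve) {
  x <- curve$ecu_M; y <- curve$percent_of_control
  ok <- x > 0 & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!any(y <= 50) || !any(y >= 50)) return(NA_real_)
  o <- order(x)
  x <- x[o]; y <- y[o]
  i <- which(y <= 50)[1]
  if (i == 1) return(x[1])
  10^(stats::approx(y[c(i - 1, i)], log10(x[c(i - 1, i)]), xout = 50)$y)
}
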