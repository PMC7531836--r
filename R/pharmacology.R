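#' Eculizumab drug parameters
#'
#' @param KD Equilibrium dissociation constant for C5 binding (molar);
#'   default 120 pM.
#' @param kon On-rate (M^-1 day^-1); default 20 nM^-1 day^-1.
#' @param t_half Elimination half-life (days); default 14.3.
#' @param MW Molecular weight (kDa); default 148.
#' @param Vd Volume of distribution (litres); default 6.5.
#' @return List of class `drug_params`; `koff = KD * kon` (day^-1).
#' @export
drug_params <- function(KD = 120e-12, kon = 20e9, t_half = 14.3,
                        MW = 148, Vd = 6.5) {
  stopifnot(KD > 0, kon > 0, t_half > 0, MW > 0, Vd > 0)
  structure(list(KD = KD, kon = kon, koff = KD * kon, t_half = t_half,
                 MW = MW, Vd = Vd), class = "drug_params")
}

#' Drug-target binding reactions
#'
#' Returns the reversible mass-action binding pair for eculizumab and C5.
#' Drug-bound C5 participates in no convertase reaction: it is completely
#' inhibited and functionally inactive, which in the network simply means
#' the complex appears as substrate of no downstream reaction.
#'
#' @param p [drug_params()].
#' @return A reaction record (id 224) in the network's internal format,
#'   with `kon`/`koff` given in second-based units.
#' @export
binding_reactions <- function(p = drug_params()) {
  .rxn(224, "drug", "mass_action_reversible",
       stats::setNames(c(1L, 1L), c("Ecu", "C5")),
       stats::setNames(1L, "EcuC5"),
       c("kon_ecu", "koff_ecu"))
}

#' Convert an intravenous dose to a molar concentration increment
#'
#' `dose / (MW * Vd)`; infusions are treated as instantaneous boluses
#' (infusion duration is negligible against the 14.3-day half-life).
#'
#' @param dose_mg Dose in milligrams (> 0).
#' @param p [drug_params()].
#' @return Molar concentration increment.
#' @examples
#' dose_to_concentration(600)   # about 6.2e-7 M
#' @export
dose_to_concentration <- function(dose_mg, p = drug_params()) {
  if (any(dose_mg <= 0)) stop("dose must be positive")
  (dose_mg / 1e3) / (p$MW * 1e3) / p$Vd
}

#' First-order pharmacokinetic elimination rate
#'
#' @param p [drug_params()].
#' @return `ln(2) / t_half` in day^-1 (about 0.0485 for eculizumab).
#' @export
pk_elimination <- function(p = drug_params()) {
  log(2) / p$t_half
}

#' Dosing regimen
#'
#' @param times Dose times (days), non-decreasing.
#' @param doses_mg Doses in mg (> 0), recycled to `length(times)`.
#' @param route Administration route (only `"iv"` supported).
#' @return Data frame of class `ap_regimen` with columns `time`, `dose_mg`,
#'   `route`.
#' @export
regimen <- function(times, doses_mg, route = "iv") {
  if (length(times) == 0) stop("empty regimen")
  if (is.unsorted(times)) stop("dose times must be non-decreasing")
  if (any(doses_mg <= 0)) stop("doses must be positive")
  structure(data.frame(time = times,
                       dose_mg = rep_len(doses_mg, length(times)),
                       route = route),
            class = c("ap_regimen", "data.frame"))
}

#' The clinical eculizumab regimen
#'
#' 600 mg once weekly for the first 4 weeks, then 900 mg once every 2 weeks
#' from week 5, continued for the requested number of months.
#'
#' @param months Treatment duration in months (30.44-day months).
#' @return An [regimen()] object.
#' @export
default_regimen <- function(months = 36) {
  horizon <- months * 30.44
  t_induction <- c(0, 7, 14, 21)
  t_maint <- seq(28, horizon, by = 14)
  regimen(c(t_induction, t_maint),
          c(rep(600, length(t_induction)), rep(900, length(t_maint))))
}

#' Read a regimen from CSV (columns day, dose_mg)
#' @param path CSV path.
#' @return An [regimen()] object.
#' @export
read_regimen <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("day", "dose_mg") %in% names(df)))
  regimen(df$day, df$dose_mg)
}

#' deSolve event table for a regimen
#' @param reg An [regimen()] object.
#' @param p [drug_params()].
#' @return Data frame usable as `events` in [ap_simulate()] (time in days).
#' @keywords internal
regimen_events <- function(reg, p = drug_params()) {
  data.frame(var = "Ecu", time = reg$time,
             value = dose_to_concentration(reg$dose_mg, p),
             method = "add")
}
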