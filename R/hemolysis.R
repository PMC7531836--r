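#' Hemolysis dose-response model
#'
#' Percent lysis as a sigmoid (Hill) function of the number of complete
#' membrane-attack complexes per cell,
#' \deqn{H = 100 / (1 + (MAC_{50}/MAC)^\gamma)}
#' with the accompanying scaling constant `tau` that converts percent
#' hemolysis into a first-order elimination rate in vivo.
#'
#' @param gamma Hill coefficient (> 0); default 1.60.
#' @param mac50 MAC density giving 50% lysis (> 0); default 1.15 MAC/cell.
#' @param tau Scaling time constant of the hemolytic elimination rate, in
#'   days (> 0).
#' @return A list of class `hemolysis_model`.
#' @export
hemolysis_model <- function(gamma = 1.60, mac50 = 1.15, tau = 2.0) {
  stopifnot(gamma > 0, mac50 > 0, tau > 0)
  structure(list(gamma = gamma, mac50 = mac50, tau = tau),
            class = "hemolysis_model")
}

#' MAC copies per cell from molar concentrations
#'
#' Unit bridge between the molar MAC pool tracked by the reaction network
#' and the per-cell pore count entering the dose-response.
#'
#' @param mac_conc MAC concentration (molar).
#' @param cell_conc Cell concentration (cells per litre).
#' @return MAC copies per cell.
#' @examples
#' macs_per_cell(1e-12, 1e11)   # 6.022 MAC/cell
#' @export
macs_per_cell <- function(mac_conc, cell_conc) {
  if (any(cell_conc <= 0))
    stop("cell concentration must be positive; MAC density is undefined at zero cells")
  mac_conc * 6.02214076e23 / cell_conc
}

#' Percent hemolysis from MAC density
#'
#' @param mac MAC copies per cell (>= 0); vectorized.
#' @param model A [hemolysis_model()].
#' @return Percent of cells lysed, in \\[0, 100).
#' @examples
#' percent_hemolysis(1.15)   # 50
#' @export
percent_hemolysis <- function(mac, model = hemolysis_model()) {
  stopifnot(all(mac >= 0))
  ifelse(mac == 0, 0, 100 / (1 + (model$mac50 / mac)^model$gamma))
}

#' Hemolytic elimination rate from percent hemolysis
#'
#' \deqn{k_H = -\ln(1 - H/100)/\tau}
#'
#' @param H Percent hemolysis in \\[0, 100\\].
#' @param tau Scaling time constant (days).
#' @param cap Maximum rate returned when `H >= 100` (the expression is
#'   singular there); a warning is emitted.
#' @return Rate in day^-1.
#' @export
hemolysis_rate <- function(H, tau, cap = -log(1 - 0.9999) / tau) {
  stopifnot(all(H >= 0), tau > 0)
  out <- numeric(length(H))
  sing <- H >= 100
  if (any(sing)) {
    warning("H >= 100%: hemolytic rate capped at ", signif(cap, 4), " per day")
    out[sing] <- cap
  }
  out[!sing] <- pmin(-log(1 - H[!sing] / 100) / tau, cap)
  out
}

#' Fit the Hill hemolysis model to a dose-response curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of percent hemolysis
#' against MAC density, estimating `gamma` and `mac50` on the log scale.
#'
#' @param curve Data frame (or list) with components `mac_per_cell` and
#'   `percent`; at least 3 points spanning the transition.
#' @param start Optional starting values `c(gamma=, mac50=)`.
#' @return A [hemolysis_model()] with fitted `gamma` and `mac50` (the `tau`
#'   slot keeps its default; it is not identified by a dose-response curve).
#' @export
fit_hill <- function(curve, start = c(gamma = 1.5, mac50 = 1)) {
  mac <- curve$mac_per_cell
  pct <- curve$percent
  keep <- mac > 0
  mac <- mac[keep]; pct <- pct[keep]
  if (length(mac) < 3)
    stop("need at least 3 points with positive MAC density")
  if (max(pct) - min(pct) < 1)
    stop("degenerate hemolysis curve: no transition to fit")
  fit <- minpack.lm::nlsLM(
    pct ~ 100 / (1 + (exp(lmac50) / mac)^exp(lg)),
    start = list(lg = log(start[["gamma"]]), lmac50 = log(start[["mac50"]])),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  hemolysis_model(gamma = exp(cf[["lg"]]), mac50 = exp(cf[["lmac50"]]))
}

#' Read / write hemolysis curves as two-column CSV
#' @param path CSV path with columns `mac_per_cell`, `percent`.
#' @return Data frame.
#' @export
read_hemolysis_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mac_per_cell", "percent") %in% names(df)))
  df
}

#' @rdname read_hemolysis_curve
#' @param curve Data frame with columns `mac_per_cell`, `percent`.
#' @export
write_hemolysis_curve <- function(curve, path) {
  utils::write.csv(curve[, c("mac_per_cell", "percent")], path,
                   row.names = FALSE)
  invisible(path)
}
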