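#' Hematological biomarker parameters
#'
#' @param Ve Mean corpuscular volume (fL).
#' @param Nhe Hemoglobin molecules per erythrocyte.
#' @param MWh Hemoglobin molecular weight (kDa).
#' @param LDHmax Amplitude of the LDH-hemoglobin sigmoid (U/L).
#' @param HLDH50 Hemoglobin at half-maximal LDH (g/dL).
#' @param LDH0 Baseline LDH (U/L).
#' @return List of class `biomarker_params`.
#' @export
biomarker_params <- function(Ve = 90, Nhe = 270e6, MWh = 64.5,
                             LDHmax = 1495, HLDH50 = 7.94, LDH0 = 296) {
  stopifnot(Ve > 0, Nhe > 0, MWh > 0, LDHmax > 0, HLDH50 > 0, LDH0 > 0)
  structure(list(Ve = Ve, Nhe = Nhe, MWh = MWh, LDHmax = LDHmax,
                 HLDH50 = HLDH50, LDH0 = LDH0), class = "biomarker_params")
}

#' Hematocrit from erythrocyte concentration
#'
#' `Hct = Ce * Ve * 100%`.
#'
#' @param cell_conc Erythrocyte concentration (cells per microlitre).
#' @param p [biomarker_params()].
#' @return Hematocrit in percent.
#' @examples
#' hematocrit(5e6)   # 45
#' @export
hematocrit <- function(cell_conc, p = biomarker_params()) {
  stopifnot(all(cell_conc >= 0))
  cell_conc * 1e6 * p$Ve * 1e-15 * 100
}

#' Hemoglobin concentration from erythrocyte concentration
#'
#' `Ch = Ce * Nhe * MWh / NA`, converted to g/dL.
#'
#' @inheritParams hematocrit
#' @return Hemoglobin in g/dL.
#' @examples
#' hemoglobin(5e6)   # about 14.5
#' @export
hemoglobin <- function(cell_conc, p = biomarker_params()) {
  stopifnot(all(cell_conc >= 0))
  g_per_L <- cell_conc * 1e6 * p$Nhe * (p$MWh * 1e3) / 6.02214076e23
  g_per_L / 10
}

#' LDH level from hemoglobin concentration
#'
#' `LDH = LDHmax / (1 + exp(Ch - HLDH50)) + LDH0`; monotone decreasing in
#' hemoglobin (lower hemoglobin, i.e. stronger hemolysis, gives higher LDH).
#' The exponent is dimensionally implicit with hemoglobin in g/dL.
#'
#' @param hb Hemoglobin (g/dL).
#' @param p [biomarker_params()].
#' @return LDH in U/L.
#' @examples
#' ldh(14)   # about 300
#' @export
ldh <- function(hb, p = biomarker_params()) {
  stopifnot(all(hb >= 0))
  p$LDHmax / (1 + exp(hb - p$HLDH50)) + p$LDH0
}

#' Fit the LDH-hemoglobin sigmoid
#'
#' Least-squares estimation of `LDHmax`, `HLDH50` and `LDH0` from paired
#' hemoglobin/LDH observations.
#'
#' @param pairs Data frame with columns `hb` (g/dL) and `ldh` (U/L); at
#'   least 4 points spanning the sigmoid.
#' @return Named vector `c(LDHmax, HLDH50, LDH0)`.
#' @export
fit_ldh_curve <- function(pairs) {
  hb <- pairs$hb; y <- pairs$ldh
  if (length(hb) < 4) stop("need at least 4 (hb, ldh) points")
  if (stats::sd(y) < 1e-8 || diff(range(y)) < 1)
    stop("non-identifiable flat LDH data")
  fit <- minpack.lm::nlsLM(
    y ~ Lmax / (1 + exp(hb - h50)) + L0,
    start = list(Lmax = max(y) - min(y), h50 = stats::median(hb),
                 L0 = min(y)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  c(LDHmax = unname(cf[["Lmax"]]), HLDH50 = unname(cf[["h50"]]),
    LDH0 = unname(cf[["L0"]]))
}

#' Biomarker panel from a cell concentration
#'
#' @param cell_conc Erythrocytes per microlitre.
#' @param p [biomarker_params()].
#' @param time Optional time stamp attached to the row.
#' @return One-row data frame: time, cells_per_uL, hb_g_dL, hct_pct, ldh_U_L.
#' @export
biomarker_panel <- function(cell_conc, p = biomarker_params(), time = NA) {
  hb <- hemoglobin(cell_conc, p)
  data.frame(time = time, cells_per_uL = cell_conc, hb_g_dL = hb,
             hct_pct = hematocrit(cell_conc, p), ldh_U_L = ldh(hb, p))
}
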