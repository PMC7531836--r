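#' Specification for a synthetic dataset
#'
#' Seeded generators emulating the structure of the digitized literature
#' datasets the model is calibrated against, so that every pipeline stage
#' is testable offline.  Noise is additive Gaussian (standard deviation
#' expressed as a fraction of full scale) clipped to the valid range of the
#' quantity.
#'
#' @param kind One of `"hill_curve"`, `"hemolysis_timecourse"`,
#'   `"dose_response"`, `"marker_timecourse"`, `"ldh_hb_pairs"`.
#' @param truth Named list of generating parameters (defaults per kind).
#' @param sigma Noise standard deviation as a fraction of full scale
#'   (>= 0).
#' @param n Number of points.
#' @param seed Integer seed; fixes the output exactly.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("hill_curve", "hemolysis_timecourse",
                                  "dose_response", "marker_timecourse",
                                  "ldh_hb_pairs"),
                         truth = list(), sigma = 0, n = 20, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0")
  if (n < 2) stop("need at least 2 points")
  structure(list(kind = kind, truth = truth, sigma = sigma, n = n,
                 seed = as.integer(seed)), class = "fixture_spec")
}

.fixture_defaults <- list(
  hill_curve = list(gamma = 1.60, mac50 = 1.15, mac_min = 0.05, mac_max = 20),
  hemolysis_timecourse = list(rate = 0.15, t_max = 30),   # per-minute scale
  dose_response = list(ec50 = 0.1, hill = 2, top = 100, dose_min = 1e-3,
                       dose_max = 10),
  marker_timecourse = list(plateau = 1e-7, rate = 0.1, t_max = 60),
  ldh_hb_pairs = list(LDHmax = 1495, HLDH50 = 7.94, LDH0 = 296,
                      hb_min = 3, hb_max = 15)
)

#' Generate a synthetic dataset
#'
#' With `sigma = 0` the points lie exactly on the generating model; the
#' same spec and seed always reproduce the identical table.  The RNG state
#' of the session is left untouched.
#'
#' @param spec A [fixture_spec()].
#' @return Data frame whose columns depend on `kind`.
#' @export
generate_fixture <- function(spec) {
  tr <- utils::modifyList(.fixture_defaults[[spec$kind]], spec$truth)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(spec$seed)
  noise <- function(scale) stats::rnorm(spec$n, 0, spec$sigma * scale)
  out <- switch(spec$kind,
    hill_curve = {
      mac <- exp(seq(log(tr$mac_min), log(tr$mac_max), length.out = spec$n))
      pct <- 100 / (1 + (tr$mac50 / mac)^tr$gamma) + noise(100)
      data.frame(mac_per_cell = mac, percent = pmin(pmax(pct, 0), 100))
    },
    hemolysis_timecourse = {
      t <- seq(0, tr$t_max, length.out = spec$n)
      pct <- 100 * (1 - exp(-tr$rate * t)) + noise(100)
      data.frame(time_min = t, percent = pmin(pmax(pct, 0), 100))
    },
    dose_response = {
      dose <- exp(seq(log(tr$dose_min), log(tr$dose_max), length.out = spec$n))
      pct <- tr$top / (1 + (tr$ec50 / dose)^tr$hill) + noise(tr$top)
      data.frame(dose = dose, percent = pmin(pmax(pct, 0), tr$top))
    },
    marker_timecourse = {
      t <- seq(0, tr$t_max, length.out = spec$n)
      conc <- tr$plateau * (1 - exp(-tr$rate * t)) + noise(tr$plateau)
      data.frame(time_min = t, concentration = pmax(conc, 0))
    },
    ldh_hb_pairs = {
      hb <- seq(tr$hb_min, tr$hb_max, length.out = spec$n)
      y <- tr$LDHmax / (1 + exp(hb - tr$HLDH50)) + tr$LDH0 +
        noise(tr$LDHmax)
      data.frame(hb = hb, ldh = pmax(y, 0))
    })
  out
}

#' Packaged MAC-vs-lysis calibration curve (synthetic stand-in)
#'
#' Returns the packaged dose-response table relating MAC density to percent
#' lysis of antibody-sensitized erythrocytes.  The shipped file is a
#' synthetic look-alike generated from the published sigmoid (gamma = 1.60,
#' MAC50 = 1.15) with small measurement noise, standing in for the
#' digitized historical dataset, as recorded in its provenance column.
#'
#' @return Data frame with columns `mac_per_cell`, `percent`.
#' @export
takeda_hemolysis_fixture <- function() {
  path <- system.file("extdata", "mac_lysis_curve_synthetic.csv",
                      package = "altpathsim")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
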