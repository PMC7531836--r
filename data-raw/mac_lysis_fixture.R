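## Generates inst/extdata/mac_lysis_curve_synthetic.csv: synthetic stand-in
## for the digitized MAC-density vs percent-lysis calibration curve
## (sheep-erythrocyte C5b-7 + C8/C9 titration design).  Points generated
## from the published sigmoid (gamma = 1.60, MAC50 = 1.15 MAC/cell) with
## 2% full-scale Gaussian noise, fixed seed.
devtools::load_all(".", quiet = TRUE)
spec <- fixture_spec("hill_curve",
                     truth = list(gamma = 1.60, mac50 = 1.15,
                                  mac_min = 0.1, mac_max = 12),
                     sigma = 0.02, n = 14, seed = 42L)
df <- generate_fixture(spec)
df$provenance <- "synthetic look-alike; generated from the fitted sigmoid, seed 42"
dir.create(file.path("inst", "extdata"), showWarnings = FALSE, recursive = TRUE)
write.csv(df, file.path("inst", "extdata", "mac_lysis_curve_synthetic.csv"),
          row.names = FALSE)
fit <- fit_hill(df)
cat(sprintf("recovered gamma = %.4f, mac50 = %.4f\n", fit$gamma, fit$mac50))
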