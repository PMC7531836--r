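test_that("scenario configuration validates its fields", {
  expect_error(scenario_config(serum_fraction = 0), "serum_fraction")
  expect_error(scenario_config(serum_fraction = 1.2), "serum_fraction")
  expect_error(scenario_config(context = "in_vivo", serum_fraction = 0.5),
               "undiluted")
  expect_error(scenario_config(knockouts = "CD55"), "unknown knockout")
  expect_error(scenario_config(readout_time = -1), "positive")
})

test_that("fluid-phase assay honours its contracts", {
  ## cells are not allowed in a fluid-phase configuration
  cfg_bad <- scenario_config(context = "in_vitro", cell_type = "rabbit")
  expect_error(run_fluid_phase_assay(cfg_bad), "cells")
  ## all-zero input stays identically zero
  zero_ov <- setNames(rep(0, 11), c("C3", "FB", "FD", "FH", "FI", "P", "C5",
                                    "C6", "C7", "Vn", "Cn"))
  cfg0 <- scenario_config(context = "in_vitro", serum_fraction = 1,
                          cell_type = "none", readout_time = 600,
                          overrides = zero_ov)
  tr0 <- run_fluid_phase_assay(cfg0, n_points = 5, opts = fast_opts)
  expect_true(all(abs(as.matrix(tr0[, -1])) < 1e-20))
  ## purified C3 alone decays only by slow spontaneous hydrolysis
  c3_ov <- zero_ov; c3_ov[["C3"]] <- 1e-6
  cfg1 <- scenario_config(context = "in_vitro", serum_fraction = 1,
                          cell_type = "none", readout_time = 3600,
                          overrides = c3_ov)
  tr1 <- run_fluid_phase_assay(cfg1, n_points = 5, opts = fast_opts)
  k <- ap_parameters()$values[["kp_C3_H2O"]]
  expect_equal(tr1$C3, 1e-6 * exp(-k * tr1$time_s), tolerance = 1e-4)
  expect_true(all(tr1$C3a == 0))   # no convertase without FB/FD
  ## whole serum: the anaphylatoxin C3a rises and decelerates toward plateau
  cfg2 <- scenario_config(context = "in_vitro", serum_fraction = 1,
                          cell_type = "none", readout_time = 7200)
  tr2 <- run_fluid_phase_assay(cfg2, n_points = 13, opts = fast_opts)
  expect_true(all(diff(tr2$C3a) > 0))
  first_half <- tr2$C3a[7] - tr2$C3a[1]
  second_half <- tr2$C3a[13] - tr2$C3a[7]
  expect_lt(second_half, first_half)
})

test_that("hemolysis increases with serum fraction and readout time", {
  mac_at <- function(serum, t) {
    cfg <- scenario_config(context = "in_vitro", serum_fraction = serum,
                           cell_type = "rabbit", cell_conc = 1e11,
                           readout_time = t)
    run_hemolytic_assay(cfg, opts = fast_opts)$mac_per_cell
  }
  m <- c(mac_at(0.05, 1200), mac_at(0.1, 1200), mac_at(0.2, 1200))
  expect_true(all(diff(m) > 0))
  mt <- c(mac_at(0.1, 600), mac_at(0.1, 1200), mac_at(0.1, 1800))
  expect_true(all(diff(mt) > 0))
})

test_that("normalization modes behave as specified", {
  expect_equal(normalize_hemolysis(40, reference = 80, mode = "NHS_control"), 50)
  expect_equal(normalize_hemolysis(40, mode = "water"), 40)
  expect_error(normalize_hemolysis(40, reference = 0, mode = "NHS_control"),
               "reference")
  expect_error(normalize_hemolysis(40, reference = NULL, mode = "NHS_control"),
               "reference")
})

test_that("knockout grid is symmetric with single knockouts on the diagonal", {
  base <- scenario_config(context = "in_vitro", serum_fraction = 0.1,
                          cell_type = "human", cell_conc = 2e11,
                          readout_time = 1800)
  M <- run_knockout_grid(base, regulators = c("CD59", "DAF"),
                         opts = fast_opts)
  expect_equal(M, t(M))
  single <- run_hemolytic_assay({
    cfg <- base; cfg$knockouts <- "CD59"; cfg
  }, opts = fast_opts)$percent
  expect_equal(M["CD59", "CD59"], single, tolerance = 1e-6)
  expect_gt(M["CD59", "DAF"], M["CD59", "CD59"])
  expect_error(run_knockout_grid(base, regulators = "XYZ"), "unknown")
  rabbit_cfg <- scenario_config(context = "in_vitro", cell_type = "rabbit")
  expect_error(run_knockout_grid(rabbit_cfg), "human")
})

test_that("PNH steady states order hemolysis and biomarkers by severity", {
  h <- run_pnh_steady_state("healthy", opts = ap_solver_options(atol = 1e-18))
  p2 <- run_pnh_steady_state(2, opts = ap_solver_options(atol = 1e-18))
  p3 <- run_pnh_steady_state(3, opts = ap_solver_options(atol = 1e-18))
  expect_gt(p3$percent_hemolysis, p2$percent_hemolysis)
  expect_gt(p2$percent_hemolysis, h$percent_hemolysis)
  expect_lt(p3$panel$hb_g_dL, p2$panel$hb_g_dL)
  expect_lt(p2$panel$hb_g_dL, h$panel$hb_g_dL)
  expect_gt(p3$panel$ldh_U_L, p2$panel$ldh_U_L)
  ## healthy homeostasis shows negligible complement-mediated hemolysis
  expect_lt(h$percent_hemolysis, 0.01)
  expect_equal(h$panel$hb_g_dL, 14.46, tolerance = 0.01)
})

test_that("treatment responds monotonically to dose intensity", {
  ## doubling all doses lowers free C5 throughout (short horizon)
  p <- drug_params()
  net <- build_full_network(ap_parameters("in_vivo"))
  net <- configure_surface(net, "pnh2", 5e12)
  base_reg <- regimen(c(0, 7), c(600, 600))
  dbl_reg <- regimen(c(0, 7), c(1200, 1200))
  sim <- function(reg) {
    ev <- altpathsim:::regimen_events(reg, p)
    ap_simulate(net, init = initial_state(net), times = seq(1, 14, by = 1),
                time_unit = "day", events = ev,
                opts = ap_solver_options(atol = 1e-18))
  }
  c5_base <- sim(base_reg)$state["C5", ]
  c5_dbl <- sim(dbl_reg)$state["C5", ]
  expect_true(all(c5_dbl <= c5_base * (1 + 1e-6)))
  expect_error(run_treatment(2, reg = regimen(0, 600)[0, ]), "empty")
})
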