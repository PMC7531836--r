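test_that("drug parameters derive consistently", {
  p <- drug_params()
  expect_equal(p$koff, 120e-12 * 20e9)          # 2.4 per day
  expect_equal(p$koff, 2.4)
  expect_equal(pk_elimination(p), log(2) / 14.3)
  expect_equal(pk_elimination(p), 0.0485, tolerance = 1e-2)
  expect_equal(dose_to_concentration(600, p), 0.6 / 148000 / 6.5,
               tolerance = 1e-12)
  expect_equal(dose_to_concentration(600, p) * 1e6, 0.6237, tolerance = 1e-3)
  expect_equal(dose_to_concentration(900, p) * 1e6, 0.9356, tolerance = 1e-3)
  expect_error(dose_to_concentration(0), "positive")
  expect_error(dose_to_concentration(-10), "positive")
})

test_that("catalogued binding constants match the drug parameters", {
  pv <- ap_parameters()$values
  expect_equal(pv[["kon_ecu"]] * 86400, 20e9)            # 20 per nM per day
  expect_equal(pv[["koff_ecu"]] / pv[["kon_ecu"]], 120e-12)  # KD
  expect_equal(pv[["kel_ecu"]] * 86400, log(2) / 14.3)
})

test_that("at equilibrium with free drug at KD, half of C5 is bound", {
  net <- build_full_network(ap_parameters("in_vivo"))
  net <- subset_reactions(net, tags = character(0), extra_ids = 224L)
  KD <- 120e-12
  ## C5 trace quantity, drug buffered far above the C5 pool
  init <- c(Ecu = KD + 5e-13, C5 = 1e-12, EcuC5 = 0)
  tr <- ap_simulate(net, init = init, times = c(0, 60), time_unit = "day")
  bound_frac <- unname(tr$state["EcuC5", 2] /
                         (tr$state["EcuC5", 2] + tr$state["C5", 2]))
  free_drug <- unname(tr$state["Ecu", 2])
  expect_equal(bound_frac, free_drug / (free_drug + KD), tolerance = 1e-4)
  expect_equal(bound_frac, 0.5, tolerance = 0.05)
})

test_that("without drug the model is identical to the drug-free network", {
  cfg0 <- scenario_config(context = "in_vitro", serum_fraction = 0.2,
                          cell_type = "rabbit", cell_conc = 1e11,
                          readout_time = 300)
  cfg1 <- cfg0; cfg1$eculizumab <- 1e-30   # binding reactions included
  r0 <- run_hemolytic_assay(cfg0, opts = fast_opts)
  r1 <- run_hemolytic_assay(cfg1, opts = fast_opts)
  expect_equal(r1$mac_per_cell, r0$mac_per_cell, tolerance = 1e-6)
})

test_that("multi-dose trough matches the analytic superposition", {
  p <- drug_params()
  net <- build_full_network(ap_parameters("in_vivo"))
  net <- subset_reactions(net, tags = character(0), extra_ids = 225L)
  reg <- regimen(c(0, 7, 14, 21, 28), c(600, 600, 600, 600, 900))
  ev <- altpathsim:::regimen_events(reg, p)
  t_out <- c(0, 10, 20, 27.9, 35, 42)
  tr <- ap_simulate(net, init = c(Ecu = 0), times = t_out,
                    time_unit = "day", events = ev,
                    opts = ap_solver_options(rtol = 1e-10, atol = 1e-18))
  kel <- pk_elimination(p)
  closed <- vapply(t_out, function(t) {
    keep <- reg$time <= t + 1e-9
    sum(dose_to_concentration(reg$dose_mg[keep], p) *
          exp(-kel * (t - reg$time[keep])))
  }, 0)
  expect_equal(unname(tr$state["Ecu", -1]), closed[-1], tolerance = 1e-6)
  ## concentration halves every 14.3 days without binding
  single <- ap_simulate(net, init = c(Ecu = 1e-6), times = c(0, 14.3, 28.6),
                        time_unit = "day")
  expect_equal(unname(single$state["Ecu", ]), 1e-6 * c(1, 0.5, 0.25),
               tolerance = 1e-6)
})

test_that("regimen constructors validate their inputs", {
  expect_error(regimen(numeric(0), 600), "empty")
  expect_error(regimen(c(7, 0), 600), "non-decreasing")
  expect_error(regimen(0, -5), "positive")
  reg <- default_regimen(3)
  expect_equal(reg$dose_mg[1:4], rep(600, 4))
  expect_true(all(reg$dose_mg[-(1:4)] == 900))
  expect_equal(diff(reg$time[1:4]), rep(7, 3))
  expect_true(all(diff(reg$time[-(1:4)]) == 14))
})
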