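test_that("derivative matches the independent per-reaction oracle", {
  set.seed(11)
  ## 100 random small mass-action networks, random states
  for (i in 1:100) {
    net <- random_mass_action_net(sample(3:7, 1), sample(4:12, 1))
    x <- setNames(runif(nrow(net$species), 0, 1e-6), net$species$id)
    expect_equal(unname(rhs(net, x)), unname(oracle_rhs(net, x)),
                 tolerance = 1e-10)
  }
  ## and the full 226-reaction model, including Michaelis-Menten and the
  ## reversible drug-binding law
  full <- build_full_network(ap_parameters())
  full <- configure_surface(full, "human", 1e11)
  x <- initial_state(full)
  x[x == 0] <- runif(sum(x == 0), 0, 1e-9)
  expect_equal(unname(rhs(full, x)), unname(oracle_rhs(full, x)),
               tolerance = 1e-10)
})

test_that("simple rate-law limits behave analytically", {
  ## detailed balance: A <-> B with equal rates and equal concentrations
  net <- random_mass_action_net(2, 2)
  net$reactions <- list(
    list(id = 1L, tag = "ap_fluid", kind = "mass_action_order1",
         reactants = c(S1 = 1L), products = c(S2 = 1L), params = "kf",
         enzyme = NA_character_, factor = 1),
    list(id = 2L, tag = "ap_fluid", kind = "mass_action_order1",
         reactants = c(S2 = 1L), products = c(S1 = 1L), params = "kr",
         enzyme = NA_character_, factor = 1))
  net$params$values <- c(kf = 3, kr = 3)
  expect_equal(unname(rhs(net, c(S1 = 1e-6, S2 = 1e-6))), c(0, 0))
  ## Michaelis-Menten saturation: [S] >> Km gives rate ~ kcat * [E]
  mm <- random_mass_action_net(3, 1)
  mm$reactions[[1]] <- list(id = 1L, tag = "ap_fluid",
                            kind = "michaelis_menten",
                            reactants = c(S1 = 1L), products = c(S2 = 1L),
                            params = c("kcat", "Km"), enzyme = "S3",
                            factor = 1)
  mm$params$values <- c(kcat = 2, Km = 1e-9)
  d <- rhs(mm, c(S1 = 1e-5, S2 = 0, S3 = 1e-8))
  expect_equal(unname(d[["S2"]]), 2 * 1e-8, tolerance = 1e-3)
})

test_that("integration reproduces closed forms", {
  ## synthesis + elimination: x(t) = (s/k)(1 - exp(-kt))
  net <- random_mass_action_net(1, 2)
  net$reactions <- list(
    list(id = 1L, tag = "ap_fluid", kind = "zero_order_synthesis",
         reactants = setNames(integer(0), character(0)),
         products = c(S1 = 1L), params = "s", enzyme = NA_character_,
         factor = 1),
    list(id = 2L, tag = "ap_fluid", kind = "mass_action_order1",
         reactants = c(S1 = 1L), products = setNames(integer(0), character(0)),
         params = "k", enzyme = NA_character_, factor = 1))
  net$params$values <- c(s = 2e-9, k = 0.01)
  tt <- c(0, 50, 200, 1000)
  tr <- ap_simulate(net, init = c(S1 = 0), times = tt)
  expect_equal(unname(tr$state["S1", ]), (2e-9 / 0.01) * (1 - exp(-0.01 * tt)),
               tolerance = 1e-6)
  ## A + B <-> AB equilibrium matches the quadratic binding solution
  bnd <- random_mass_action_net(3, 1)
  bnd$reactions[[1]] <- list(id = 1L, tag = "ap_fluid",
                             kind = "mass_action_reversible",
                             reactants = c(S1 = 1L, S2 = 1L),
                             products = c(S3 = 1L),
                             params = c("kon", "koff"),
                             enzyme = NA_character_, factor = 1)
  bnd$params$values <- c(kon = 1e6, koff = 1e-3)
  A0 <- 5e-8; B0 <- 2e-8; KD <- 1e-3 / 1e6
  tr <- ap_simulate(bnd, init = c(S1 = A0, S2 = B0, S3 = 0),
                    times = c(0, 1e5))
  s <- A0 + B0 + KD
  AB_eq <- (s - sqrt(s^2 - 4 * A0 * B0)) / 2
  expect_equal(unname(tr$state["S3", 2]), AB_eq, tolerance = 1e-6)
})

test_that("solution is converged at the default tolerances", {
  net <- subset_fluid_phase(build_full_network(ap_parameters()))
  init <- initial_state(net, 0.5)
  o1 <- ap_solver_options()
  o2 <- ap_solver_options(rtol = o1$rtol / 2, atol = o1$atol / 2)
  t1 <- ap_simulate(net, init = init, times = c(0, 1800), opts = o1)
  t2 <- ap_simulate(net, init = init, times = c(0, 1800), opts = o2)
  big <- t2$state[, 2] > 1e-15
  expect_lt(max(abs(t1$state[big, 2] - t2$state[big, 2]) / t2$state[big, 2]),
            1e-4)
  ## no species drops below -atol at output times
  expect_true(all(t1$state >= -o1$atol))
})

test_that("an intravenous bolus adds exactly dose/(MW*Vd) to the drug pool", {
  p <- drug_params()
  net <- build_full_network(ap_parameters("in_vivo"))
  net <- subset_reactions(net, tags = character(0), extra_ids = 225L)
  ev <- data.frame(var = "Ecu", time = 5,
                   value = dose_to_concentration(600, p), method = "add")
  tr <- ap_simulate(net, init = c(Ecu = 0), times = c(0, 4.999, 5.001, 10),
                    time_unit = "day", events = ev)
  jump <- unname(tr$state["Ecu", 3] - tr$state["Ecu", 2])
  expect_equal(jump, dose_to_concentration(600, p), tolerance = 1e-6)
})

test_that("turnover-only steady states equal synthesis/elimination ratios", {
  params <- ap_parameters("in_vivo")
  net <- build_full_network(params)
  net <- subset_reactions(net, tags = c("cell_turnover", "synthesis",
                                        "elimination"))
  ss <- steady_state(net, init = NULL, opts = ap_solver_options())
  pv <- params$values
  expect_equal(ss[["E"]], pv[["s_E"]] / pv[["ks_cell"]], tolerance = 1e-6)
  expect_equal(ss[["FH"]], pv[["s_FH"]] / pv[["kel_FH"]], tolerance = 1e-6)
  expect_equal(ss[["FD"]], pv[["s_FD"]] / pv[["kel_FD"]], tolerance = 1e-6)
  ## the production/elimination ratio encodes the healthy cell count exactly
  expect_equal(pv[["s_E"]] / pv[["ks_cell"]] * 6.02214076e23, 5e12,
               tolerance = 1e-12)
  ## closed systems cannot reach a steady state by turnover
  expect_error(steady_state(subset_fluid_phase(build_full_network(
    ap_parameters()))), "synthesis")
})

test_that("healthy in-vivo homeostasis reproduces the catalogued serum levels", {
  net <- build_full_network(ap_parameters("in_vivo"))
  net <- configure_surface(net, "human", cell_conc = 5e12)
  ss <- steady_state(net, init = initial_state(net),
                     opts = ap_solver_options(atol = 1e-18))
  targets <- ap_species()
  targets <- targets[targets$serum_scaled, ]
  for (i in seq_len(nrow(targets))) {
    expect_lt(abs(ss[[targets$id[i]]] - targets$init_conc[i]) /
                targets$init_conc[i], 0.2)
  }
  ## erythrocytes at 5e6 per microlitre
  expect_equal(ss[["E"]] * 6.02214076e23 * 1e-6, 5e6, tolerance = 0.01)
})
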