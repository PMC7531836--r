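test_that("full network has the published reaction and parameter partition", {
  net <- build_full_network(ap_parameters())
  expect_equal(length(net$reactions), 226L)
  tags <- table(vapply(net$reactions, `[[`, "", "tag"))
  expect_equal(unname(tags[["ap_fluid"]]), 36L)
  expect_equal(unname(tags[["ap_surface"]]), 75L)
  expect_equal(sum(tags[c("ap_fluid", "ap_surface")]), 111L)
  expect_equal(sum(tags[c("cell_turnover", "synthesis", "elimination")]), 112L)
  expect_equal(unname(tags[["drug"]]), 3L)
  p <- ap_parameters()
  expect_equal(length(p$values), 121L)
  cls <- table(p$table$class)
  expect_equal(unname(cls[["kinetic"]]), 70L)
  expect_equal(unname(cls[["turnover"]]), 39L)
  expect_equal(unname(cls[["drug"]]), 2L)
  expect_equal(unname(cls[["other"]]), 10L)
})

test_that("final fitted parameter estimates load bit-exactly", {
  pv <- ap_parameters()$values
  expect_identical(pv[["kp_C3b_surface"]], 2.16e9)
  expect_identical(pv[["kp_CD59C5b9"]], 6.03e11)
  expect_identical(pv[["kp_C3bP"]], 1.24e8)
  expect_identical(pv[["kp_C3bBbDAF"]], 2.53e10)
  expect_identical(pv[["Km_C3_C3H2OBb"]], 4.19e-6)
  expect_identical(pv[["km_C3bBbDAF_decay"]], 2.28e-3)
  expect_identical(pv[["kp_CVC5bC6"]], 7.74e4)
  expect_identical(pv[["kp_C3bB"]], 2.23e5)
})

test_that("missing and malformed inputs give named errors", {
  p <- ap_parameters()
  p$values <- p$values[names(p$values) != "kp_C3bB"]
  expect_error(build_full_network(p), "kp_C3bB")
  net <- build_full_network(ap_parameters())
  net$reactions[[2]]$id <- 1
  expect_error(validate_network(net), "duplicate reaction id")
  expect_error(configure_surface(build_full_network(ap_parameters()), "sheep"),
               "unknown cell type")
  expect_error(ap_parameters(overrides = c(not_a_param = 1)), "not_a_param")
})

test_that("fluid-phase subset keeps exactly the 36 fluid reactions and is idempotent", {
  net <- build_full_network(ap_parameters())
  fl <- subset_fluid_phase(net)
  expect_equal(length(fl$reactions), 36L)
  expect_true(all(vapply(fl$reactions, `[[`, "", "tag") == "ap_fluid"))
  expect_false(any(fl$species$phase %in% c("surface", "cell", "drug")))
  fl2 <- subset_fluid_phase(fl)
  expect_identical(vapply(fl2$reactions, `[[`, 0, "id"),
                   vapply(fl$reactions, `[[`, 0, "id"))
  expect_identical(fl2$species$id, fl$species$id)
})

test_that("in-vivo context applies the published parameter reductions", {
  vitro <- ap_parameters("in_vitro")$values
  vivo <- ap_parameters("in_vivo")$values
  expect_equal(vivo[["kp_C3_H2O"]], vitro[["kp_C3_H2O"]] / 1e2)
  expect_equal(vivo[["kp_C3b_surface"]], vitro[["kp_C3b_surface"]] / 1e5)
  expect_equal(vivo[["kcat_FD"]], vitro[["kcat_FD"]])
})

test_that("serum dilution scales serum proteins only", {
  net <- build_full_network(ap_parameters())
  net <- configure_surface(net, "human", cell_conc = 1e11)
  full <- initial_state(net, 1)
  dil <- initial_state(net, 0.37)
  serum <- net$species$id[net$species$serum_scaled]
  expect_equal(unname(dil[serum]), unname(full[serum] * 0.37))
  cellside <- c("E", "DAF", "CD59", "CR1")
  expect_equal(unname(dil[cellside]), unname(full[cellside]))
})

test_that("surface configuration is absolute, not incremental", {
  net <- build_full_network(ap_parameters())
  direct <- configure_surface(net, "rabbit", cell_conc = 1e11)
  via_human <- configure_surface(configure_surface(net, "human", 1e11),
                                 "rabbit", 1e11)
  expect_equal(via_human$species$init_conc, direct$species$init_conc)
  expect_equal(via_human$params$values, direct$params$values)
  ## rabbit surfaces escape the human regulators
  g <- function(n, id) n$species$init_conc[n$species$id == id]
  expect_equal(g(direct, "CR1"), 0)
  expect_equal(g(direct, "DAF"), 0)
  expect_equal(g(direct, "CD59"), 0)
  expect_equal(direct$params$values[["kp_C3bH_surf"]], 0)
  ## PNH type 2 keeps 10% of the GPI-anchored regulators
  pnh2 <- configure_surface(net, "pnh2", 1e11)
  human <- configure_surface(net, "human", 1e11)
  expect_equal(g(pnh2, "CD59"), 0.1 * g(human, "CD59"))
  expect_equal(g(pnh2, "DAF"), 0.1 * g(human, "DAF"))
})

test_that("stoichiometry matrix reports per-reaction net change", {
  net <- random_mass_action_net(3, 1)
  net$reactions[[1]] <- list(id = 1L, tag = "ap_fluid",
                             kind = "mass_action_order2",
                             reactants = c(S1 = 1L, S2 = 1L),
                             products = c(S3 = 1L), params = "k1",
                             enzyme = NA_character_, factor = 1)
  S <- stoichiometry_matrix(net)
  expect_equal(unname(S[, 1]), c(-1, -1, 1))
  full <- build_full_network(ap_parameters())
  expect_equal(ncol(stoichiometry_matrix(full)), 226L)
})

test_that("C3 moiety is conserved in the closed fluid system without FH/FI", {
  net <- subset_fluid_phase(build_full_network(ap_parameters()))
  ## stoichiometric check: every fluid reaction leaves the weighted moiety
  ## count unchanged
  w <- c3_moiety_weights(net)
  S <- stoichiometry_matrix(net)
  expect_equal(max(abs(drop(w %*% S))), 0)
  ## dynamic check along a trajectory
  init <- initial_state(net, 1)
  init[c("FH", "FI")] <- 0
  tr <- ap_simulate(net, init = init, times = seq(0, 1800, length.out = 7),
                    opts = ap_solver_options())
  tot <- drop(w[tr$species] %*% tr$state)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
})
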