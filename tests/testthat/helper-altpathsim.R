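## Shared helpers for the test suite.

## Assay-scale solver settings: looser relative tolerance than the engine
## default (convergence-checked in the engine tests), tight absolute floor
## because surface species sit at sub-picomolar levels.
fast_opts <- ap_solver_options(rtol = 1e-6, atol = 1e-18)

## Run one in-vitro hemolytic assay and return MAC/cell and percent lysis.
run_ko_assay <- function(knockouts = character(0), cell_type = "human",
                         serum = 0.1, cells = 2e11, readout = 1800) {
  cfg <- scenario_config(context = "in_vitro", serum_fraction = serum,
                         cell_type = cell_type, cell_conc = cells,
                         readout_time = readout, knockouts = knockouts)
  run_hemolytic_assay(cfg, opts = fast_opts)
}

## A random small mass-action network in the package's own container, used
## to check the engine against an independently coded oracle.
random_mass_action_net <- function(n_species = 5, n_reactions = 8) {
  ids <- paste0("S", seq_len(n_species))
  species <- data.frame(id = ids, phase = "fluid", surface_bound = FALSE,
                        serum_scaled = FALSE,
                        init_conc = runif(n_species, 0, 1e-6),
                        copies_per_cell = NA_real_, mw_kda = NA_real_,
                        moiety_c3 = 0, kel_param = NA_character_,
                        stringsAsFactors = FALSE)
  rxns <- vector("list", n_reactions)
  pvals <- c()
  for (j in seq_len(n_reactions)) {
    kind <- sample(c("mass_action_order1", "mass_action_order2",
                     "zero_order_synthesis"), 1)
    pn <- paste0("k", j)
    if (kind == "mass_action_order1") {
      re <- setNames(1L, sample(ids, 1))
      pr <- setNames(1L, sample(ids, 1))
      pvals[pn] <- runif(1, 0, 10)
    } else if (kind == "mass_action_order2") {
      re <- setNames(c(1L, 1L), sample(ids, 2))
      pr <- setNames(1L, sample(ids, 1))
      pvals[pn] <- runif(1, 0, 1e6)
    } else {
      re <- setNames(integer(0), character(0))
      pr <- setNames(1L, sample(ids, 1))
      pvals[pn] <- runif(1, 0, 1e-9)
    }
    rxns[[j]] <- list(id = j, tag = "ap_fluid", kind = kind,
                      reactants = re, products = pr, params = pn,
                      enzyme = NA_character_, factor = 1)
  }
  structure(list(species = species, reactions = rxns,
                 params = list(values = pvals, context = "in_vitro"),
                 volume = 1, context = "in_vitro", cell_type = NULL),
            class = "ap_network")
}

## Independent derivative oracle: per-reaction accumulation coded from the
## rate-law definitions, no stoichiometry matrix, no shared code path.
oracle_rhs <- function(net, state) {
  d <- setNames(numeric(nrow(net$species)), net$species$id)
  x <- pmax(state, 0)
  pv <- net$params$values
  for (r in net$reactions) {
    fac <- if (is.null(r$factor)) 1 else r$factor
    rate <- switch(r$kind,
      mass_action_order1 = pv[[r$params[1]]] * fac * x[[names(r$reactants)[1]]],
      mass_action_order2 = pv[[r$params[1]]] * fac *
        x[[names(r$reactants)[1]]] * x[[names(r$reactants)[2]]],
      michaelis_menten = {
        sub <- setdiff(names(r$reactants), r$enzyme)
        if (!length(sub)) sub <- names(r$reactants)[1]
        s <- x[[sub[1]]]
        pv[[r$params[1]]] * fac * x[[r$enzyme]] * s / (pv[[r$params[2]]] + s)
      },
      zero_order_synthesis = pv[[r$params[1]]] * fac,
      mass_action_reversible =
        pv[[r$params[1]]] * x[[names(r$reactants)[1]]] *
          x[[names(r$reactants)[2]]] -
        pv[[r$params[2]]] * x[[names(r$products)[1]]])
    for (nm in names(r$reactants)) d[nm] <- d[nm] - r$reactants[[nm]] * rate
    for (nm in names(r$products)) d[nm] <- d[nm] + r$products[[nm]] * rate
  }
  d
}
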