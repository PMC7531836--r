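#' @importFrom stats optimize setNames rnorm runif median approx
#' @importFrom utils read.csv write.csv modifyList
NULL

## Reaction tag ranges.  All subsetting is done by tag, never by positional
## index; ids are stable bookkeeping labels.
.TAG_RANGES <- list(
  ap_fluid      = 1:36,
  ap_surface    = 37:111,
  cell_turnover = 112:113,
  synthesis     = 114:129,
  elimination   = 130:223,
  drug          = 224:226
)

#' Species catalogue of the alternative-pathway model
#'
#' Returns the full species table: identifier, phase (`fluid`, `surface`,
#' `cell` or `drug`), whether the species is surface-bound (eliminated with
#' its host cell), whether its initial concentration scales with serum
#' dilution, the initial concentration in 100% serum (molar), membrane
#' copies per erythrocyte for cell-anchored regulators, molecular weight
#' (kDa, where meaningful), the number of C3-derived moieties the species
#' carries (used for conservation checks) and the name of the turnover
#' parameter governing its first-order clearance in vivo.
#'
#' Initial serum concentrations are standard plasma levels of the
#' alternative-pathway proteins; activation products and complexes start
#' at zero in vitro.
#'
#' @return A `data.frame`, one row per species (94 rows).
#' @export
ap_species <- function() {
  sp <- function(id, phase, sb, ss, init = 0, copies = NA_real_,
                 mw = NA_real_, c3 = 0, kel = NA_character_) {
    data.frame(id = id, phase = phase, surface_bound = sb,
               serum_scaled = ss, init_conc = init,
               copies_per_cell = copies, mw_kda = mw, moiety_c3 = c3,
               kel_param = kel, stringsAsFactors = FALSE)
  }
  f <- function(id, init = 0, mw = NA, c3 = 0, kel = "kel_C3")
    sp(id, "fluid", FALSE, init > 0, init, NA, mw, c3, kel)
  s <- function(id, c3 = 0) sp(id, "surface", TRUE, FALSE, 0, NA, NA, c3, "ks_cell")

  rbind(
    ## -- fluid phase ----------------------------------------------------
    f("C3",       6.6e-6, 187, 1),
    f("C3H2O",    0,      187, 1),
    f("C3a",      0,      9,   0, "kel_C3a"),
    f("C3adesArg",0,      9,   0, "kel_C3a"),
    f("nfC3b",    0,      177, 1),
    f("C3b",      0,      177, 1),
    f("iC3b",     0,      174, 1),
    f("C3dg",     0,      38,  1, "kel_C3dg"),
    f("FB",       2.2e-6, 93,  0, "kel_FB"),
    f("Ba",       0,      33,  0, "kel_Ba"),
    f("Bb",       0,      63,  0, "kel_Bb"),
    f("FD",       8.3e-8, 24,  0, "kel_FD"),
    f("FH",       3.2e-6, 155, 0, "kel_FH"),
    f("FI",       4.0e-7, 88,  0, "kel_FI"),
    f("P",        4.4e-7, 53,  0, "kel_P"),
    ## CR1 is a cell-anchored receptor; it is carried as a fluid-accessible
    ## regulator whose concentration scales with the cell count.
    sp("CR1", "fluid", FALSE, FALSE, 0, 600, 220, 0, "kel_CR1"),
    f("C3H2OB",   0,      280, 1),
    f("C3H2OBb",  0,      250, 1),
    f("C3bB",     0,      270, 1),
    f("C3bBb",    0,      240, 1),
    f("C3bP",     0,      230, 1),
    f("C3bPB",    0,      323, 1),
    f("C3bBbP",   0,      293, 1),
    f("C3bH",     0,      332, 1),
    f("C3bCR1",   0,      397, 1),
    f("C3bBbH",   0,      395, 1),
    f("C3bBbCR1", 0,      460, 1),
    f("C3bBbC3b_f", 0,    417, 2),
    f("C5",       3.7e-7, 190, 0, "kel_C5"),
    f("C5a",      0,      11,  0, "kel_C5a"),
    f("C5adesArg",0,      11,  0, "kel_C5a"),
    f("C5bf",     0,      179, 0, "kel_C5"),
    f("C6",       4.3e-7, 105, 0, "kel_C6"),
    f("C5b6f",    0,      284, 0, "kel_C5"),
    f("C7",       5.8e-7, 92,  0, "kel_C7"),
    f("C8",       3.7e-7, 150, 0, "kel_C8"),
    f("C9",       8.5e-7, 71,  0, "kel_C9"),
    f("C5b7f",    0,      376, 0, "kel_C5"),
    f("Vn",       3.3e-6, 75,  0, "kel_Vn"),
    f("Cn",       1.25e-6, 80, 0, "kel_Cn"),
    f("C5b7Vn",   0,      451, 0, "kel_C5"),
    f("C5b7Cn",   0,      456, 0, "kel_C5"),
    ## -- erythrocyte surface --------------------------------------------
    sp("E", "cell", FALSE, FALSE, 0, NA, NA, 0, NA),
    sp("DAF",  "surface", TRUE, FALSE, 0, 3000, 70, 0, "ks_cell"),
    sp("CD59", "surface", TRUE, FALSE, 0, 1000, 20, 0, "ks_cell"),
    s("nfC3b_s", 1),
    s("C3b_s", 1), s("C3bB_s", 1), s("C3bBb_s", 1),
    s("C3bP_s", 1), s("C3bPB_s", 1), s("C3bBbP_s", 1),
    s("C3bBbC3b_s", 2), s("C3bBbC3bP_s", 2),
    s("C3bBbC3bC5b", 2), s("C3bBbC3bC5b6", 2), s("C3bBbC3bC5b7", 2),
    s("C3bBbC3bPC5b", 2), s("C3bBbC3bPC5b6", 2), s("C3bBbC3bPC5b7", 2),
    s("C5b7_s"), s("C5b8_s"),
    do.call(rbind, lapply(1:18, function(k) s(sprintf("C5b9_%d", k)))),
    s("C5b8CD59"), s("C5b9CD59"), s("C5b7CD59"),
    s("C3bBbDAF_s", 1), s("C3bBbC3bDAF_s", 2),
    s("C3bH_s", 1), s("iC3b_s", 1), s("C3dg_s", 1),
    s("C3bCR1_s", 1), s("C3bBbH_s", 1), s("C3bBbC3bH_s", 2),
    s("C3bBbCR1_s", 1),
    ## -- eculizumab ------------------------------------------------------
    sp("Ecu",   "drug", FALSE, FALSE, 0, NA, 148, 0, NA),
    sp("EcuC5", "drug", FALSE, FALSE, 0, NA, 338, 0, NA)
  )
}

## The terminal, fully assembled pore: C5b-8 plus 18 C9 molecules.  Only this
## species enters the hemolysis dose-response.
.MAC_SPECIES <- "C5b9_18"

## C3b-acceptor sites per erythrocyte: the attachment rate constant of
## nascent C3b is defined per site, so the effective deposition rate is
## kp_C3b_surface * sites_per_cell * [E].
.C3B_SITES_PER_CELL <- 1e6

## internal reaction constructor; `factor` is a fixed structural multiplier
## folded into the rate constant (used for the per-site attachment rate)
.rxn <- function(id, tag, kind, reactants, products, params,
                 enzyme = NA_character_, factor = 1) {
  list(id = id, tag = tag, kind = kind,
       reactants = reactants, products = products,
       params = params, enzyme = enzyme, factor = factor)
}

#' Full reaction list of the alternative-pathway model
#'
#' Builds the complete declarative reaction table: 36 fluid-phase AP
#' reactions, 75 surface AP reactions, erythrocyte production/elimination,
#' 16 protein synthesis reactions, 94 degradation reactions and the 3
#' eculizumab reactions (binding plus first-order clearance of free and
#' bound antibody).  Rate-law kinds are `mass_action_order1`,
#' `mass_action_order2`, `michaelis_menten`, `zero_order_synthesis` and
#' `mass_action_reversible` (used only for the drug-target binding pair).
#'
#' @return A list of reaction records.
#' @keywords internal
ap_reactions <- function() {
  o1 <- function(id, tag, from, to, k)
    .rxn(id, tag, "mass_action_order1", setNames(1L, from),
         setNames(rep(1L, length(to)), to), k)
  o1s <- function(id, tag, from, to, stoich, k)       # explicit stoichiometry
    .rxn(id, tag, "mass_action_order1", setNames(1L, from),
         setNames(as.integer(stoich), to), k)
  o2 <- function(id, tag, a, b, to, k)
    .rxn(id, tag, "mass_action_order2", setNames(c(1L, 1L), c(a, b)),
         setNames(rep(1L, length(to)), to), k)
  ## catalytic surface attachment / insertion: the cell participates but is
  ## not consumed
  cat2 <- function(id, tag, a, cell, to, k, factor = 1)
    .rxn(id, tag, "mass_action_order2", setNames(c(1L, 1L), c(a, cell)),
         setNames(c(1L, 1L), c(to, cell)), k, factor = factor)
  mm <- function(id, tag, sub, enz, to, kcat, km, consume_enzyme = FALSE) {
    re <- if (consume_enzyme) setNames(c(1L, 1L), c(sub, enz)) else setNames(1L, sub)
    .rxn(id, tag, "michaelis_menten", re,
         setNames(rep(1L, length(to)), to), c(kcat, km), enzyme = enz)
  }
  syn <- function(id, to, s, tag = "synthesis")
    .rxn(id, tag, "zero_order_synthesis", setNames(integer(0), character(0)),
         setNames(1L, to), s)
  el <- function(id, tag, from, k)
    .rxn(id, tag, "mass_action_order1", setNames(1L, from),
         setNames(integer(0), character(0)), k)

  fl <- "ap_fluid"; su <- "ap_surface"

  rx <- list(
    ## ---- fluid phase (1-36) -------------------------------------------
    o1(1, fl, "C3", "C3H2O", "kp_C3_H2O"),                       # tick-over
    o2(2, fl, "C3H2O", "FB", "C3H2OB", "kp_C3H2OB"),
    o1(3, fl, "C3H2OB", c("C3H2O", "FB"), "km_C3H2OB"),
    mm(4, fl, "C3H2OB", "FD", c("C3H2OBb", "Ba"), "kcat_FD", "Km_FD",
       consume_enzyme = FALSE),
    o1(5, fl, "C3H2OBb", c("C3H2O", "Bb"), "km_C3H2OBb_decay"),
    mm(6, fl, "C3", "C3H2OBb", c("nfC3b", "C3a"), "kcat_C3_C3H2OBb",
       "Km_C3_C3H2OBb"),
    o1(7, fl, "nfC3b", "C3b", "k_nfC3b_h2o"),                    # 60 us thioester hydrolysis
    o2(8, fl, "C3b", "FB", "C3bB", "kp_C3bB"),
    o1(9, fl, "C3bB", c("C3b", "FB"), "km_C3bB"),
    mm(10, fl, "C3bB", "FD", c("C3bBb", "Ba"), "kcat_FD", "Km_FD"),
    o1(11, fl, "C3bBb", c("C3b", "Bb"), "km_C3bBb_decay"),
    mm(12, fl, "C3", "C3bBb", c("nfC3b", "C3a"), "kcat_C3_C3bBb", "Km_C3_C3bBb"),
    o2(13, fl, "C3b", "P", "C3bP", "kp_C3bP_fluid"),
    o1(14, fl, "C3bP", c("C3b", "P"), "km_C3bP"),
    o2(15, fl, "C3bP", "FB", "C3bPB", "kp_C3bPB"),
    mm(16, fl, "C3bPB", "FD", c("C3bBbP", "Ba"), "kcat_FD", "Km_FD"),
    o1(17, fl, "C3bBbP", c("C3bP", "Bb"), "km_C3bBbP_decay"),
    mm(18, fl, "C3", "C3bBbP", c("nfC3b", "C3a"), "kcat_C3_C3bBb", "Km_C3_C3bBb"),
    o2(19, fl, "C3b", "FH", "C3bH", "kp_C3bH"),
    o1(20, fl, "C3bH", c("C3b", "FH"), "km_C3bH"),
    mm(21, fl, "C3bH", "FI", c("iC3b", "FH"), "kcat_FI_C3bH", "Km_FI_C3bH"),
    mm(22, fl, "iC3b", "FI", "C3dg", "kcat_FI_iC3b", "Km_FI_iC3b"),
    ## FH-dependent inactivation of C3(H2O) (FI cofactor implicit); keeps
    ## the tick-over pool from recycling indefinitely through the initial
    ## convertase
    .rxn(23, fl, "mass_action_order2",
         setNames(c(1L, 1L), c("C3H2O", "FH")),
         setNames(c(1L, 1L), c("iC3b", "FH")), "kp_C3bH"),
    ## FH displaces properdin from fluid C3bP, returning C3b to the
    ## FH/FI-regulated pool (prevents indefinite properdin recycling)
    o2(24, fl, "C3bP", "FH", c("C3bH", "P"), "kp_C3bH"),
    o2(25, fl, "C3bBb", "FH", "C3bBbH", "kp_C3bBbH"),
    o1(26, fl, "C3bBbH", c("C3bH", "Bb"), "km_C3bBbH_decay"),
    o1(27, fl, "C3bBbH", c("C3bBb", "FH"), "km_C3bBbH_diss"),
    o2(28, fl, "C3bBb", "CR1", "C3bBbCR1", "kp_C3bBbCR1"),
    o1(29, fl, "C3bBbCR1", c("C3bCR1", "Bb"), "km_C3bBbCR1_decay"),
    o2(30, fl, "C3bBb", "C3b", "C3bBbC3b_f", "kp_C5conv_f"),
    o1s(31, fl, "C3bBbC3b_f", c("C3b", "Bb"), c(2L, 1L), "km_C3bBbC3b_f_decay"),
    mm(32, fl, "C5", "C3bBbC3b_f", c("C5bf", "C5a"), "kcat_C5", "Km_C5"),
    o2(33, fl, "C5bf", "C6", "C5b6f", "kp_C5b6"),
    o2(34, fl, "C5b6f", "C7", "C5b7f", "kp_CVC5bC7"),
    o2(35, fl, "C5b7f", "Vn", "C5b7Vn", "kp_C5b7Vn"),
    o2(36, fl, "C5b7f", "Cn", "C5b7Cn", "kp_C5b7Cn"),
    ## ---- erythrocyte surface (37-111) ---------------------------------
    cat2(37, su, "nfC3b", "E", "C3b_s", "kp_C3b_surface",
         factor = .C3B_SITES_PER_CELL),
    o1(38, su, "nfC3b_s", "C3b", "k_nfC3b_h2o"),
    o1(39, su, "nfC3b_s", "C3b_s", "k_attach_local"),
    o2(40, su, "C3b_s", "FB", "C3bB_s", "kp_C3bB"),
    o1(41, su, "C3bB_s", c("C3b_s", "FB"), "km_C3bB_s"),
    mm(42, su, "C3bB_s", "FD", c("C3bBb_s", "Ba"), "kcat_FD", "Km_FD"),
    o1(43, su, "C3bBb_s", c("C3b_s", "Bb"), "km_C3bBb_s_decay"),
    mm(44, su, "C3", "C3bBb_s", c("nfC3b_s", "C3a"), "kcat_C3_conv_s",
       "Km_C3_conv_s"),
    o2(45, su, "C3b_s", "P", "C3bP_s", "kp_C3bP"),
    o1(46, su, "C3bP_s", c("C3b_s", "P"), "km_C3bP"),
    o2(47, su, "C3bP_s", "FB", "C3bPB_s", "kp_C3bB"),
    o2(48, su, "C3bP_s", "FH", c("C3bH_s", "P"), "kp_C3bH_surf"),
    mm(49, su, "C3bPB_s", "FD", c("C3bBbP_s", "Ba"), "kcat_FD", "Km_FD"),
    o1(50, su, "C3bBbP_s", c("C3bP_s", "Bb"), "km_C3bBbP_s_decay"),
    mm(51, su, "C3", "C3bBbP_s", c("nfC3b_s", "C3a"), "kcat_C3_conv_s",
       "Km_C3_conv_s"),
    o2(52, su, "C3bBb_s", "P", "C3bBbP_s", "kp_C3bBbP"),
    o1(53, su, "C3bBbP_s", c("C3bBb_s", "P"), "km_C3bBbP_diss"),
    o2(54, su, "C3bBb_s", "C3b_s", "C3bBbC3b_s", "kp_C5conv"),
    mm(55, su, "C5", "C3bBbC3b_s", c("C3bBbC3bC5b", "C5a"), "kcat_C5_s",
       "Km_C5_s", consume_enzyme = TRUE),
    o1s(56, su, "C3bBbC3b_s", c("C3b_s", "Bb"), c(2L, 1L), "km_C3bBbC3b_decay"),
    o2(57, su, "C3bBbP_s", "C3b_s", "C3bBbC3bP_s", "kp_C5conv"),
    o1(58, su, "C3bBbC3bP_s", c("C3bP_s", "C3b_s", "Bb"), "km_C3bBbP_s_decay"),
    mm(59, su, "C3", "C3bBbC3b_s", c("nfC3b_s", "C3a"), "kcat_C3_conv_s",
       "Km_C3_conv_s"),
    mm(60, su, "C3", "C3bBbC3bP_s", c("nfC3b_s", "C3a"), "kcat_C3_conv_s",
       "Km_C3_conv_s"),
    o2(61, su, "C3bBbC3bC5b", "C6", "C3bBbC3bC5b6", "kp_CVC5bC6"),
    o2(62, su, "C3bBbC3bC5b6", "C7", "C3bBbC3bC5b7", "kp_CVC5bC7"),
    o1(63, su, "C3bBbC3bC5b7", c("C3bBbC3b_s", "C5b7f"), "k_rel_C5b7"),
    cat2(64, su, "C5b7f", "E", "C5b7_s", "kp_C5b7_E"),
    o2(65, su, "C5b7_s", "C8", "C5b8_s", "kp_C5b8"),
    o2(66, su, "C5b8_s", "C9", "C5b9_1", "kp_C9_first")
  )
  ## growing pore: C5b-8 accretes C9 up to the complete 18-C9 MAC
  for (k in 1:17) {
    rx[[length(rx) + 1L]] <-
      o2(66L + k, su, sprintf("C5b9_%d", k), "C9", sprintf("C5b9_%d", k + 1),
         "kp_C9_growth")
  }
  rx <- c(rx, list(
    mm(84, su, "C5", "C3bBbC3bP_s", c("C3bBbC3bPC5b", "C5a"), "kcat_C5_P",
       "Km_C5_P", consume_enzyme = TRUE),
    o2(85, su, "C3bBbC3bPC5b", "C6", "C3bBbC3bPC5b6", "kp_CVC5bC6"),
    o2(86, su, "C3bBbC3bPC5b6", "C7", "C3bBbC3bPC5b7", "kp_CVC5bC7"),
    o1(87, su, "C3bBbC3bPC5b7", c("C3bBbC3bP_s", "C5b7f"), "k_rel_C5b7"),
    o2(88, su, "C5b8_s", "CD59", "C5b8CD59", "kp_CD59C5b9"),
    o2(89, su, "C5b9_1", "CD59", "C5b9CD59", "kp_CD59C5b9"),
    o2(90, su, "C5b7_s", "CD59", "C5b7CD59", "kp_CD59C5b9"),
    o2(91, su, "C3bBb_s", "DAF", "C3bBbDAF_s", "kp_C3bBbDAF"),
    o1s(92, su, "C3bBbDAF_s", c("C3b_s", "Bb", "DAF"), c(1L, 1L, 1L),
        "km_C3bBbDAF_decay"),
    o1(93, su, "C3bBbDAF_s", c("C3bBb_s", "DAF"), "km_C3bBbDAF_diss"),
    ## DAF reversibly caps the properdin-stabilized C5 convertase; fast
    ## cycling makes it a throttle on C5 cleavage rather than a sink
    o2(94, su, "C3bBbC3bP_s", "DAF", "C3bBbC3bDAF_s", "kp_C3bBbDAF"),
    o1s(95, su, "C3bBbC3bDAF_s", c("C3b_s", "Bb", "DAF"), c(2L, 1L, 1L),
        "km_C3bBbDAF_decay"),
    o1(96, su, "C3bBbC3bDAF_s", c("C3bBbC3bP_s", "DAF"), "km_C3bBbDAF_diss"),
    o2(97, su, "C3b_s", "FH", "C3bH_s", "kp_C3bH_surf"),
    o1(98, su, "C3bH_s", c("C3b_s", "FH"), "km_C3bH_s"),
    mm(99, su, "C3bH_s", "FI", c("iC3b_s", "FH"), "kcat_FI_C3bH_s",
       "Km_FI_C3bH"),
    mm(100, su, "iC3b_s", "FI", "C3dg_s", "kcat_FI_iC3b", "Km_FI_iC3b"),
    o2(101, su, "C3b_s", "CR1", "C3bCR1_s", "kp_C3bCR1"),
    o1(102, su, "C3bCR1_s", c("C3b_s", "CR1"), "km_C3bCR1"),
    mm(103, su, "C3bCR1_s", "FI", c("iC3b_s", "CR1"), "kcat_FI_C3bCR1",
       "Km_FI_C3bCR1"),
    o2(104, su, "C3bBb_s", "FH", "C3bBbH_s", "kp_C3bH_surf"),
    o1(105, su, "C3bBbH_s", c("C3bH_s", "Bb"), "km_C3bBbH_decay"),
    o1(106, su, "C3bBbH_s", c("C3bBb_s", "FH"), "km_C3bBbH_diss"),
    o2(107, su, "C3bBbC3b_s", "FH", "C3bBbC3bH_s", "kp_C3bH_surf"),
    o1(108, su, "C3bBbC3bH_s", c("C3bH_s", "C3b_s", "Bb"), "km_C3bBbH_decay"),
    o1(109, su, "C3bBbC3bH_s", c("C3bBbC3b_s", "FH"), "km_C3bBbH_diss"),
    o2(110, su, "C3bBb_s", "CR1", "C3bBbCR1_s", "kp_C3bBbCR1"),
    o1(111, su, "C3bBbCR1_s", c("C3bCR1_s", "Bb"), "km_C3bBbCR1_decay"),
    ## ---- erythrocyte turnover (112-113) --------------------------------
    syn(112, "E", "s_E", tag = "cell_turnover"),
    el(113, "cell_turnover", "E", "ks_cell"),
    ## ---- protein synthesis (114-129) -----------------------------------
    syn(114, "C3", "s_C3"), syn(115, "FB", "s_FB"), syn(116, "FD", "s_FD"),
    syn(117, "FH", "s_FH"), syn(118, "FI", "s_FI"), syn(119, "P", "s_P"),
    syn(120, "C5", "s_C5"), syn(121, "C6", "s_C6"), syn(122, "C7", "s_C7"),
    syn(123, "C8", "s_C8"), syn(124, "C9", "s_C9"), syn(125, "Vn", "s_Vn"),
    syn(126, "Cn", "s_Cn"), syn(127, "CR1", "s_CR1"),
    syn(128, "DAF", "s_DAF"), syn(129, "CD59", "s_CD59"),
    ## ---- catabolic conversions (130-132) --------------------------------
    o1(130, "elimination", "C3a", "C3adesArg", "k_desArg"),
    o1(131, "elimination", "C5a", "C5adesArg", "k_desArg"),
    o1(132, "elimination", "C3dg_s", "C3dg", "k_shed_C3dg")
  ))
  ## -- first-order clearance, one reaction per clearable species (133-223)
  spec <- ap_species()
  clearable <- spec[!is.na(spec$kel_param), ]
  stopifnot(nrow(clearable) == 91L)
  for (i in seq_len(nrow(clearable))) {
    rx[[length(rx) + 1L]] <-
      el(132L + i, "elimination", clearable$id[i], clearable$kel_param[i])
  }
  ## ---- eculizumab (224-226) --------------------------------------------
  rx <- c(rx, list(
    .rxn(224, "drug", "mass_action_reversible",
         setNames(c(1L, 1L), c("Ecu", "C5")), setNames(1L, "EcuC5"),
         c("kon_ecu", "koff_ecu")),
    el(225, "drug", "Ecu", "kel_ecu"),
    el(226, "drug", "EcuC5", "kel_ecu")
  ))
  rx
}

#' Assemble the full alternative-pathway reaction network
#'
#' Builds the complete in-vivo model: 226 reactions partitioned into 111
#' alternative-pathway reactions (36 fluid-phase, 75 surface), 112 turnover
#' reactions (erythrocyte production/elimination, protein synthesis,
#' degradation) and 3 eculizumab reactions.  Every rate-law parameter must
#' resolve in `params`.
#'
#' @param params A parameter set from [ap_parameters()].
#' @param volume Compartment volume in litres (default 1; concentrations are
#'   molar so the volume only matters for dose bookkeeping).
#' @return An object of class `ap_network`.
#' @examples
#' net <- build_full_network(ap_parameters())
#' table(vapply(net$reactions, `[[`, "", "tag"))
#' @export
build_full_network <- function(params = ap_parameters(), volume = 1) {
  net <- structure(
    list(species = ap_species(), reactions = ap_reactions(),
         params = params, volume = volume,
         context = params$context, cell_type = NULL),
    class = "ap_network")
  validate_network(net)
  net
}

#' Validate structural invariants of a reaction network
#'
#' Checks species-id uniqueness, non-negative initial concentrations, tag /
#' id-range consistency, that every rate-law parameter resolves in the
#' parameter set, that Michaelis-Menten reactions carry exactly one enzyme
#' modifier, and that every surface species takes part in at least one
#' surface reaction.
#'
#' @param net An `ap_network`.
#' @return Invisibly `TRUE`; aborts with a descriptive error otherwise.
#' @export
validate_network <- function(net) {
  spec <- net$species
  if (anyDuplicated(spec$id))
    stop("duplicate species ids: ",
         paste(spec$id[duplicated(spec$id)], collapse = ", "))
  if (any(spec$init_conc < 0))
    stop("negative initial concentration")
  if (any(spec$surface_bound & spec$phase != "surface"))
    stop("surface_bound species must have phase 'surface'")

  ids <- vapply(net$reactions, `[[`, 0, "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  tags <- vapply(net$reactions, `[[`, "", "tag")
  for (tg in names(.TAG_RANGES)) {
    bad <- ids[tags == tg & !(ids %in% .TAG_RANGES[[tg]])]
    if (length(bad))
      stop("reaction id outside tag range for ", tg, ": ",
           paste(bad, collapse = ", "))
  }
  all_sp <- spec$id
  pv <- net$params$values
  for (r in net$reactions) {
    touched <- c(names(r$reactants), names(r$products), r$enzyme)
    touched <- touched[!is.na(touched)]
    if (!all(touched %in% all_sp))
      stop("reaction ", r$id, " references unknown species: ",
           paste(setdiff(touched, all_sp), collapse = ", "))
    if (!all(r$params %in% names(pv)))
      stop("missing parameter for reaction ", r$id, ": ",
           paste(setdiff(r$params, names(pv)), collapse = ", "))
    if (r$kind == "michaelis_menten") {
      if (is.na(r$enzyme) || length(r$enzyme) != 1L)
        stop("reaction ", r$id, ": michaelis_menten requires exactly one enzyme")
    }
    if (r$kind == "mass_action_order2" && length(r$reactants) != 2L)
      stop("reaction ", r$id, ": order-2 rate law needs two reactants")
    if (r$kind == "mass_action_order1" && length(r$reactants) != 1L)
      stop("reaction ", r$id, ": order-1 rate law needs one reactant")
  }
  surf_sp <- spec$id[spec$phase == "surface"]
  in_surface_rxn <- unique(unlist(lapply(
    net$reactions[tags == "ap_surface"],
    function(r) c(names(r$reactants), names(r$products)))))
  orphan <- setdiff(surf_sp, in_surface_rxn)
  if (length(orphan))
    stop("surface species never touched by a surface reaction: ",
         paste(orphan, collapse = ", "))
  invisible(TRUE)
}

#' Restrict a network to the fluid phase
#'
#' Keeps only the 36 fluid-phase AP reactions and the species they touch,
#' modelling the closed in-vitro system used for fluid-phase activation
#' assays (no cells, no turnover, no drug).  The operation is idempotent.
#'
#' @param net An `ap_network`.
#' @return The reduced `ap_network`.
#' @export
subset_fluid_phase <- function(net) {
  subset_reactions(net, tags = "ap_fluid")
}

#' Subset a network by reaction tag
#'
#' @param net An `ap_network`.
#' @param tags Character vector of tags to retain.
#' @param extra_ids Additional reaction ids to retain (e.g. the drug-binding
#'   reaction in an in-vitro inhibition assay).
#' @return The reduced `ap_network`; species not touched by any retained
#'   reaction are dropped.
#' @export
subset_reactions <- function(net, tags, extra_ids = integer(0)) {
  keep <- vapply(net$reactions, function(r)
    r$tag %in% tags || r$id %in% extra_ids, TRUE)
  rxns <- net$reactions[keep]
  touched <- unique(unlist(lapply(rxns, function(r)
    c(names(r$reactants), names(r$products), r$enzyme))))
  touched <- touched[!is.na(touched)]
  net$reactions <- rxns
  net$species <- net$species[net$species$id %in% touched, , drop = FALSE]
  rownames(net$species) <- NULL
  net
}

#' Configure the erythrocyte surface for a given cell type
#'
#' Configuration is absolute, not incremental: regulator levels are always
#' recomputed from the species catalogue, so reconfiguring a network gives
#' the same result as configuring it directly.
#'
#' * `rabbit` - rabbit erythrocytes escape regulation by the human
#'   regulators: CR1, DAF and CD59 are set to 0 and the association of FH
#'   with surface-bound proteins (`kp_C3bH_surf`) is turned off.
#' * `human` - healthy human erythrocytes with full regulator complements.
#' * `pnh2` - PNH type 2: subtotal deficiency, DAF and CD59 expression (and
#'   in-vivo synthesis) at 10% of normal.
#' * `pnh3` - PNH type 3: DAF and CD59 completely absent.
#'
#' @param net An `ap_network` containing the surface reactions.
#' @param cell_type One of `"rabbit"`, `"human"`, `"pnh2"`, `"pnh3"`.
#' @param cell_conc Cell concentration (cells per litre).
#' @return The configured network (regulator initial concentrations set,
#'   `cell_type`/`cell_conc` recorded, parameters adjusted).
#' @export
configure_surface <- function(net, cell_type, cell_conc = 1e11) {
  known <- c("rabbit", "human", "pnh2", "pnh3")
  if (!cell_type %in% known)
    stop("unknown cell type '", cell_type, "'; expected one of ",
         paste(known, collapse = ", "))
  if (!any(vapply(net$reactions, `[[`, "", "tag") == "ap_surface"))
    stop("network has no surface reactions; cannot configure a cell type")
  spec <- ap_species()   # absolute reference levels
  frac <- c(rabbit = 0, human = 1, pnh2 = 1, pnh3 = 1)[[cell_type]]
  gpi_frac <- c(rabbit = 0, human = 1, pnh2 = 0.1, pnh3 = 0)[[cell_type]]
  per_cell <- function(id) {
    cp <- spec$copies_per_cell[spec$id == id]
    cp * cell_conc / 6.02214076e23
  }
  set_init <- function(net, id, val) {
    net$species$init_conc[net$species$id == id] <- val
    net
  }
  net <- set_init(net, "E", cell_conc / 6.02214076e23)
  if ("CR1" %in% net$species$id)
    net <- set_init(net, "CR1", frac * per_cell("CR1"))
  if ("DAF" %in% net$species$id)
    net <- set_init(net, "DAF", gpi_frac * per_cell("DAF"))
  if ("CD59" %in% net$species$id)
    net <- set_init(net, "CD59", gpi_frac * per_cell("CD59"))
  ## FH does not recognise rabbit surfaces
  net$params <- set_parameter(net$params, "kp_C3bH_surf",
                              if (cell_type == "rabbit") 0 else
                                base_parameter(net$params, "kp_C3bH_surf"))
  ## in vivo: synthesis maintains the membrane regulator pools
  if (net$context == "in_vivo") {
    for (p in c("s_DAF", "s_CD59"))
      net$params <- set_parameter(net$params, p,
                                  gpi_frac * base_parameter(net$params, p))
    net$params <- set_parameter(net$params, "s_CR1",
                                frac * base_parameter(net$params, "s_CR1"))
  }
  net$cell_type <- cell_type
  net$cell_conc <- cell_conc
  net
}

#' Stoichiometry matrix of a network
#'
#' @param net An `ap_network`.
#' @return Integer matrix (n_species x n_reactions); column j is the net
#'   stoichiometric change effected by reaction j.
#' @export
stoichiometry_matrix <- function(net) {
  ids <- net$species$id
  S <- matrix(0L, nrow = length(ids), ncol = length(net$reactions),
              dimnames = list(ids, vapply(net$reactions, `[[`, 0, "id")))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    for (nm in names(r$reactants))
      S[nm, j] <- S[nm, j] - r$reactants[[nm]]
    for (nm in names(r$products))
      S[nm, j] <- S[nm, j] + r$products[[nm]]
  }
  S
}

#' Apply serum dilution to a vector of initial concentrations
#'
#' Serum dilutions are modelled as equivalent reductions of the initial
#' concentrations of all serum-derived proteins; cell-derived species are
#' untouched.
#'
#' @param net An `ap_network`.
#' @param serum_fraction Fraction of normal human serum in the incubation
#'   (0, 1].
#' @return Named numeric vector of initial concentrations (molar).
#' @export
initial_state <- function(net, serum_fraction = 1) {
  x <- setNames(net$species$init_conc, net$species$id)
  scaled <- net$species$serum_scaled
  x[scaled] <- x[scaled] * serum_fraction
  x
}

#' C3-moiety weight vector
#'
#' Number of C3-derived moieties carried by each species (complexes count
#' their C3b copy number); used for conservation checks in closed systems.
#'
#' @param net An `ap_network`.
#' @return Named numeric vector.
#' @export
c3_moiety_weights <- function(net) {
  setNames(net$species$moiety_c3, net$species$id)
}
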