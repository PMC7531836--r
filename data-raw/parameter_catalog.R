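## Generates inst/extdata/parameter_catalog.csv: the 121-entry parameter
## catalogue of the alternative-pathway model (70 kinetic rate constants,
## 39 turnover parameters, 2 eculizumab binding constants, 10 further
## parameters for hemolysis, biomarkers and drug clearance).
##
## All values are stored on the second/molar scale used by the in-vitro
## parameterization; the engine converts to days for in-vivo runs.
## `in_vivo_scale` holds the multiplicative context adjustment applied when
## a parameter set is requested for the in-vivo context.
##
## Provenance codes:
##   Table1_final - final estimates of the fitting procedure (printed table)
##   baseline     - literature-order baseline kinetic constant
##   derived      - value derived or calibrated within this package

NA_day <- 86400

half_life_d <- c(
  C3 = 2.5, C5 = 6.3, FB = 2.1, FD = 0.1, FH = 6, FI = 3, P = 2.75,
  CR1 = 3, C6 = 2.7, C7 = 3, C8 = 3, C9 = 2.5, Vn = 1.5, Cn = 2,
  C3a = 0.001, C5a = 0.001, C3dg = 0.17, Ba = 0.2, Bb = 0.2)
kel <- log(2) / (half_life_d * NA_day)            # s^-1

conc <- c(C3 = 6.6e-6, FB = 2.2e-6, FD = 8.3e-8, FH = 3.2e-6, FI = 4.0e-7,
          P = 4.4e-7, C5 = 3.7e-7, C6 = 4.3e-7, C7 = 5.8e-7, C8 = 3.7e-7,
          C9 = 8.5e-7, Vn = 3.3e-6, Cn = 1.25e-6)

NAv <- 6.02214076e23
cells_vivo <- 5e12                                 # cells per litre
ks_cell <- log(2) / (60 * NA_day)                  # 60-day erythrocyte half-life
E_vivo <- cells_vivo / NAv
CR1_vivo <- 600  * cells_vivo / NAv
DAF_vivo <- 3000 * cells_vivo / NAv
CD59_vivo <- 1000 * cells_vivo / NAv

row <- function(name, value, units, class, scale = 1, prov = "baseline",
                desc = "") {
  data.frame(name = name, value = value, units = units, class = class,
             in_vivo_scale = scale, provenance = prov, description = desc,
             stringsAsFactors = FALSE)
}
K <- function(...) row(..., class = "kinetic")

cat <- rbind(
  ## ---- kinetic: fluid phase -------------------------------------------
  row("kp_C3_H2O", 6e-6, "s-1", "kinetic", 1e-2, "derived",
      "spontaneous C3 tick-over hydrolysis; reduced 100-fold in vivo"),
  row("kp_C3H2OB", 5e5, "M-1 s-1", "kinetic", 1, "baseline", "FB binding to C3(H2O)"),
  row("km_C3H2OB", 0.1, "s-1", "kinetic", 1, "baseline", "C3(H2O)B dissociation"),
  row("kcat_FD", 2.0, "s-1", "kinetic", 1, "baseline", "FD cleavage of proconvertases"),
  row("Km_FD", 6e-7, "M", "kinetic", 1, "baseline", "FD Michaelis constant"),
  row("km_C3H2OBb_decay", 0.04, "s-1", "kinetic", 1, "derived",
      "initial convertase decay (unstable initiator)"),
  row("kcat_C3_C3H2OBb", 2.5, "s-1", "kinetic", 1, "baseline",
      "C3 cleavage by C3(H2O)Bb"),
  row("Km_C3_C3H2OBb", 4.19e-6, "M", "kinetic", 1, "Table1_final",
      "Michaelis constant of C3 cleavage by C3(H2O)Bb"),
  row("k_nfC3b_h2o", log(2) / 60e-6, "s-1", "kinetic", 1, "baseline",
      "nascent C3b thioester hydrolysis, 60 us half-life"),
  row("kp_C3bB", 2.23e5, "M-1 s-1", "kinetic", 1, "Table1_final",
      "FB association with C3b"),
  row("km_C3bB", 0.1, "s-1", "kinetic", 1, "baseline", "C3bB dissociation"),
  row("km_C3bBb_decay", 7.7e-3, "s-1", "kinetic", 1, "baseline",
      "fluid C3 convertase decay"),
  row("kcat_C3_C3bBb", 2.5, "s-1", "kinetic", 1, "baseline",
      "C3 cleavage by fluid C3bBb"),
  row("Km_C3_C3bBb", 5.9e-6, "M", "kinetic", 1, "baseline",
      "Michaelis constant of C3 cleavage by C3bBb"),
  row("kp_C3bP_fluid", 1e4, "M-1 s-1", "kinetic", 1, "derived",
      "properdin association with fluid C3b (weak; properdin acts mainly on surfaces)"),
  row("km_C3bP", 0.05, "s-1", "kinetic", 1, "baseline", "C3bP dissociation"),
  row("kp_C3bPB", 2.23e5, "M-1 s-1", "kinetic", 1, "baseline",
      "FB association with C3bP"),
  row("km_C3bBbP_decay", 4e-3, "s-1", "kinetic", 1, "derived",
      "properdin-stabilized fluid convertase decay"),
  row("kp_C3bH", 1e6, "M-1 s-1", "kinetic", 1, "baseline",
      "FH association with fluid C3b"),
  row("km_C3bH", 0.1, "s-1", "kinetic", 1, "baseline", "C3bH dissociation"),
  row("kcat_FI_C3bH", 1.0, "s-1", "kinetic", 1, "baseline",
      "FI cleavage of C3b (FH cofactor)"),
  row("Km_FI_C3bH", 1e-6, "M", "kinetic", 1, "baseline", "FI Michaelis constant"),
  row("kcat_FI_iC3b", 0.01, "s-1", "kinetic", 1, "baseline",
      "FI cleavage of iC3b to C3dg"),
  row("Km_FI_iC3b", 1e-6, "M", "kinetic", 1, "baseline", ""),
  row("kp_C3bCR1", 1e6, "M-1 s-1", "kinetic", 1, "baseline",
      "CR1 association with C3b"),
  row("km_C3bCR1", 0.01, "s-1", "kinetic", 1, "baseline", ""),
  row("kp_C3bBbH", 2e6, "M-1 s-1", "kinetic", 1, "baseline",
      "FH association with fluid convertase"),
  row("km_C3bBbH_decay", 0.1, "s-1", "kinetic", 1, "baseline",
      "FH-accelerated convertase decay"),
  row("km_C3bBbH_diss", 0.01, "s-1", "kinetic", 1, "baseline",
      "FH dissociation from C3bBbH"),
  row("kp_C3bBbCR1", 1e6, "M-1 s-1", "kinetic", 1, "baseline",
      "CR1 association with fluid convertase"),
  row("km_C3bBbCR1_decay", 0.1, "s-1", "kinetic", 1, "baseline",
      "CR1-accelerated convertase decay"),
  row("kp_C5conv_f", 3e6, "M-1 s-1", "kinetic", 1, "derived",
      "C3b association with fluid convertase (C5 convertase formation)"),
  row("km_C3bBbC3b_f_decay", 7.7e-3, "s-1", "kinetic", 1, "baseline",
      "fluid C5 convertase decay"),
  row("kcat_C5", 0.01, "s-1", "kinetic", 1, "derived",
      "C5 cleavage by fluid C5 convertase"),
  row("Km_C5", 5.9e-6, "M", "kinetic", 1, "baseline", ""),
  row("kp_C5b6", 1e6, "M-1 s-1", "kinetic", 1, "baseline", "C6 binding to fluid C5b"),
  row("kp_C5b7Vn", 1e4, "M-1 s-1", "kinetic", 1, "baseline",
      "vitronectin scavenging of C5b-7"),
  row("kp_C5b7Cn", 1e4, "M-1 s-1", "kinetic", 1, "baseline",
      "clusterin scavenging of C5b-7"),
  ## ---- kinetic: surface -----------------------------------------------
  row("kp_C3b_surface", 2.16e9, "M-1 s-1", "kinetic", 1e-5, "Table1_final",
      "attachment of nascent fluid C3b to the erythrocyte surface; reduced 1e5-fold in vivo"),
  row("k_attach_local", 60, "s-1", "kinetic", 1e-2, "derived",
      "local deposition of nascent C3b generated by surface convertases (competes with 60 us hydrolysis); reduced in vivo with the surface-attachment channel"),
  row("km_C3bB_s", 0.1, "s-1", "kinetic", 1, "baseline", "surface C3bB dissociation"),
  row("km_C3bBb_s_decay", 7.7e-3, "s-1", "kinetic", 1, "baseline",
      "surface C3 convertase decay"),
  row("kcat_C3_conv_s", 2.5, "s-1", "kinetic", 1, "baseline",
      "C3 cleavage by surface convertases"),
  row("Km_C3_conv_s", 5.9e-6, "M", "kinetic", 1, "baseline", ""),
  row("kp_C3bP", 1.24e8, "M-1 s-1", "kinetic", 1, "Table1_final",
      "properdin association with surface C3b"),
  row("km_C3bBbP_s_decay", 4e-3, "s-1", "kinetic", 1, "derived",
      "properdin-stabilized surface convertase decay"),
  row("kp_C3bBbP", 1e7, "M-1 s-1", "kinetic", 1, "baseline",
      "properdin association with assembled surface convertase"),
  row("km_C3bBbP_diss", 1e-3, "s-1", "kinetic", 1, "baseline",
      "properdin dissociation from surface convertase"),
  row("kp_C5conv", 2.8e8, "M-1 s-1", "kinetic", 1, "derived",
      "surface C3b association with surface convertase; 2D co-localization, above 3D diffusion limit"),
  row("km_C3bBbC3b_decay", 7.7e-3, "s-1", "kinetic", 1, "baseline",
      "surface C5 convertase decay"),
  row("kcat_C5_s", 0.01, "s-1", "kinetic", 1, "derived",
      "C5 cleavage by surface C5 convertase"),
  row("Km_C5_s", 2.4e-7, "M", "kinetic", 1, "baseline", ""),
  row("kcat_C5_P", 0.01, "s-1", "kinetic", 1, "derived",
      "C5 cleavage by properdin-stabilized surface C5 convertase"),
  row("Km_C5_P", 2.4e-7, "M", "kinetic", 1, "baseline", ""),
  row("kp_CVC5bC6", 7.74e4, "M-1 s-1", "kinetic", 1, "Table1_final",
      "C6 association with convertase-bound C5b"),
  row("kp_CVC5bC7", 1e6, "M-1 s-1", "kinetic", 1, "baseline",
      "C7 association with C5b6"),
  row("k_rel_C5b7", 0.1, "s-1", "kinetic", 1, "baseline",
      "release of C5b-7 from the convertase into the fluid phase"),
  row("kp_C5b7_E", 1e12, "M-1 s-1", "kinetic", 1, "derived",
      "membrane insertion of fluid C5b-7 into an erythrocyte; diffusion-limited capture by a cell-sized target"),
  row("kp_C5b8", 2.6e9, "M-1 s-1", "kinetic", 1, "derived",
      "C8 binding to membrane C5b-7; 2D co-localization"),
  row("kp_C9_first", 1.1e9, "M-1 s-1", "kinetic", 1, "derived",
      "first C9 binding to membrane C5b-8"),
  row("kp_C9_growth", 1.1e9, "M-1 s-1", "kinetic", 1, "derived",
      "C9 polymerization steps up to the 18-C9 pore"),
  row("kp_CD59C5b9", 6.03e11, "M-1 s-1", "kinetic", 1, "Table1_final",
      "CD59 capture of nascent membrane C5b-7/8/9"),
  row("kp_C3bBbDAF", 2.53e10, "M-1 s-1", "kinetic", 1, "Table1_final",
      "DAF association with surface convertases"),
  row("km_C3bBbDAF_decay", 2.28e-3, "s-1", "kinetic", 1, "Table1_final",
      "DAF-mediated convertase decay"),
  row("km_C3bBbDAF_diss", 10, "s-1", "kinetic", 1, "derived",
      "DAF dissociation from convertase (fast cycling: DAF throttles rather than destroys)"),
  row("kp_C3bH_surf", 5e5, "M-1 s-1", "kinetic", 1, "derived",
      "FH association with surface-bound C3b and convertases; 0 on rabbit cells"),
  row("km_C3bH_s", 0.1, "s-1", "kinetic", 1, "baseline",
      "FH dissociation from surface C3bH"),
  row("kcat_FI_C3bH_s", 1.0, "s-1", "kinetic", 1, "baseline",
      "FI cleavage of surface C3b (FH cofactor)"),
  row("kcat_FI_C3bCR1", 1.0, "s-1", "kinetic", 1, "baseline",
      "FI cleavage of surface C3b (CR1 cofactor)"),
  row("Km_FI_C3bCR1", 1e-6, "M", "kinetic", 1, "baseline", ""),
  ## ---- turnover: synthesis --------------------------------------------
  row("s_E", ks_cell * E_vivo, "M s-1", "turnover", 1, "derived",
      "erythrocyte production maintaining 5e6 cells/uL at homeostasis"),
  row("s_C3", kel[["C3"]] * conc[["C3"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_FB", kel[["FB"]] * conc[["FB"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_FD", kel[["FD"]] * conc[["FD"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_FH", kel[["FH"]] * conc[["FH"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_FI", kel[["FI"]] * conc[["FI"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_P",  kel[["P"]]  * conc[["P"]],  "M s-1", "turnover", 1, "derived", ""),
  row("s_C5", kel[["C5"]] * conc[["C5"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_C6", kel[["C6"]] * conc[["C6"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_C7", kel[["C7"]] * conc[["C7"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_C8", kel[["C8"]] * conc[["C8"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_C9", kel[["C9"]] * conc[["C9"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_Vn", kel[["Vn"]] * conc[["Vn"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_Cn", kel[["Cn"]] * conc[["Cn"]], "M s-1", "turnover", 1, "derived", ""),
  row("s_CR1", kel[["CR1"]] * CR1_vivo, "M s-1", "turnover", 1, "derived", ""),
  row("s_DAF", ks_cell * DAF_vivo, "M s-1", "turnover", 1, "derived", ""),
  row("s_CD59", ks_cell * CD59_vivo, "M s-1", "turnover", 1, "derived", ""),
  ## ---- turnover: elimination ------------------------------------------
  row("ks_cell", ks_cell, "s-1", "turnover", 1, "baseline",
      "physiological erythrocyte elimination (60-day half-life); also clears surface-bound proteins"),
  row("kel_C3", kel[["C3"]], "s-1", "turnover", 1, "derived",
      "clearance of C3 and fluid C3b-containing complexes"),
  row("kel_C5", kel[["C5"]], "s-1", "turnover", 1, "derived",
      "clearance of C5 and fluid C5b-containing complexes"),
  row("kel_FB", kel[["FB"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_FD", kel[["FD"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_FH", kel[["FH"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_FI", kel[["FI"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_P", kel[["P"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_CR1", kel[["CR1"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_C6", kel[["C6"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_C7", kel[["C7"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_C8", kel[["C8"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_C9", kel[["C9"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_Vn", kel[["Vn"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_Cn", kel[["Cn"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_C3a", kel[["C3a"]], "s-1", "turnover", 1, "baseline", ""),
  row("kel_C5a", kel[["C5a"]], "s-1", "turnover", 1, "baseline", ""),
  row("kel_C3dg", kel[["C3dg"]], "s-1", "turnover", 1, "baseline", ""),
  row("kel_Ba", kel[["Ba"]], "s-1", "turnover", 1, "derived", ""),
  row("kel_Bb", kel[["Bb"]], "s-1", "turnover", 1, "derived", ""),
  row("k_desArg", 0.02, "s-1", "turnover", 1, "baseline",
      "carboxypeptidase-N conversion of anaphylatoxins to des-Arg forms"),
  row("k_shed_C3dg", 1e-5, "s-1", "turnover", 1, "baseline",
      "shedding of surface C3dg into plasma"),
  ## ---- eculizumab binding ---------------------------------------------
  row("kon_ecu", 20e9 / NA_day, "M-1 s-1", "drug", 1, "baseline",
      "eculizumab-C5 on-rate (20 nM-1 day-1)"),
  row("koff_ecu", 1.2e-10 * 20e9 / NA_day, "s-1", "drug", 1, "derived",
      "off-rate from KD = 120 pM and the assumed on-rate"),
  ## ---- hemolysis, biomarkers, drug clearance --------------------------
  row("gamma_hill", 1.60, "1", "other", 1, "Table1_final",
      "Hill coefficient of MAC-mediated lysis"),
  row("mac50", 1.15, "MAC/cell", "other", 1, "Table1_final",
      "MAC density producing 50% hemolysis"),
  row("tau_hemolysis", 0.036, "day", "other", 1, "derived",
      "scaling time constant mapping percent hemolysis to an elimination rate; calibrated to PNH type-3 hemoglobin"),
  row("Ve_mcv", 90, "fL", "other", 1, "baseline", "mean corpuscular volume"),
  row("Nhe_hb_per_cell", 270e6, "1/cell", "other", 1, "baseline",
      "hemoglobin molecules per erythrocyte"),
  row("MWh_hb", 64.5, "kDa", "other", 1, "baseline", "hemoglobin molecular weight"),
  row("LDH_max", 1495, "U L-1", "other", 1, "baseline",
      "amplitude of the LDH-hemoglobin sigmoid"),
  row("H_LDH50", 7.94, "g dL-1", "other", 1, "baseline",
      "hemoglobin at half-maximal LDH"),
  row("LDH_0", 296, "U L-1", "other", 1, "baseline", "baseline LDH"),
  row("kel_ecu", log(2) / (14.3 * NA_day), "s-1", "other", 1, "baseline",
      "eculizumab elimination, 14.3-day half-life")
)

stopifnot(nrow(cat) == 121,
          sum(cat$class == "kinetic") == 70,
          sum(cat$class == "turnover") == 39,
          sum(cat$class == "drug") == 2,
          sum(cat$class == "other") == 10,
          !anyDuplicated(cat$name))

dir.create(file.path("inst", "extdata"), recursive = TRUE, showWarnings = FALSE)
write.csv(cat, file.path("inst", "extdata", "parameter_catalog.csv"),
          row.names = FALSE)
cat("wrote", nrow(cat), "catalog entries\n")
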