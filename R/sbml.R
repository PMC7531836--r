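## Minimal SBML Level 3 export/import for the constructs this model uses.
## Rate-law parameters are written as reaction-local parameters so that a
## round trip preserves counts and values exactly.

.mathml_ci <- function(x) sprintf("<ci> %s </ci>", x)

.mathml_rate <- function(r) {
  k <- .mathml_ci
  times <- function(...) paste0("<apply><times/>", paste0(...), "</apply>")
  switch(r$kind,
    mass_action_order1 = times(k("k1"), k(names(r$reactants)[1])),
    mass_action_order2 = times(k("k1"), k(names(r$reactants)[1]),
                               k(names(r$reactants)[2])),
    zero_order_synthesis = k("k1"),
    michaelis_menten = paste0(
      "<apply><divide/>",
      times(k("k1"), k(r$enzyme),
            k(setdiff(names(r$reactants), r$enzyme)[1] %||%
                names(r$reactants)[1])),
      "<apply><plus/>", k("k2"),
      k(setdiff(names(r$reactants), r$enzyme)[1] %||% names(r$reactants)[1]),
      "</apply></apply>"),
    mass_action_reversible = paste0(
      "<apply><minus/>",
      times(k("k1"), k(names(r$reactants)[1]), k(names(r$reactants)[2])),
      times(k("k2"), k(names(r$products)[1])),
      "</apply>"))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Export a network as an SBML Level 3 document
#'
#' Species, reactions and rate laws (with reaction-local parameters `k1`,
#' `k2`) in SBML Level 3 Version 2 core.  The writer covers exactly the
#' rate-law kinds the network uses; an unsupported kind is an error.
#'
#' @param net An `ap_network`.
#' @param path Output file path (`.xml`).
#' @return The path, invisibly.
#' @export
export_sbml <- function(net, path) {
  validate_network(net)
  pv <- net$params$values
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2">')
  w('<model id="alternative_pathway" substanceUnits="mole" ',
    'timeUnits="second" volumeUnits="litre" extentUnits="mole">')
  w('<listOfCompartments><compartment id="plasma" spatialDimensions="3" ',
    sprintf('size="%.17g" constant="true"/></listOfCompartments>', net$volume))
  w("<listOfSpecies>")
  for (i in seq_len(nrow(net$species))) {
    s <- net$species[i, ]
    w(sprintf(
      '<species id="%s" compartment="plasma" initialConcentration="%.17g" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(s$id), s$init_conc))
  }
  w("</listOfSpecies>")
  w("<listOfReactions>")
  for (r in net$reactions) {
    if (!r$kind %in% c("mass_action_order1", "mass_action_order2",
                       "michaelis_menten", "zero_order_synthesis",
                       "mass_action_reversible"))
      stop("cannot export rate-law kind '", r$kind, "'")
    rev <- if (r$kind == "mass_action_reversible") "true" else "false"
    w(sprintf('<reaction id="r%d" reversible="%s" name="%s">',
              r$id, rev, r$tag))
    if (length(r$reactants)) {
      w("<listOfReactants>")
      for (nm in names(r$reactants))
        w(sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                  esc(nm), r$reactants[[nm]]))
      w("</listOfReactants>")
    }
    if (length(r$products)) {
      w("<listOfProducts>")
      for (nm in names(r$products))
        w(sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                  esc(nm), r$products[[nm]]))
      w("</listOfProducts>")
    }
    if (!is.na(r$enzyme) && r$kind == "michaelis_menten" &&
        !(r$enzyme %in% names(r$reactants))) {
      w("<listOfModifiers>")
      w(sprintf('<modifierSpeciesReference species="%s"/>', esc(r$enzyme)))
      w("</listOfModifiers>")
    }
    ks <- unname(pv[r$params])
    w("<kineticLaw>")
    w('<math xmlns="http://www.w3.org/1998/Math/MathML">')
    w(.mathml_rate(r))
    w("</math>")
    w("<listOfLocalParameters>")
    w(sprintf('<localParameter id="k1" name="%s" value="%.17g"/>',
              r$params[1], ks[1]))
    if (length(ks) > 1)
      w(sprintf('<localParameter id="k2" name="%s" value="%.17g"/>',
                r$params[2], ks[2]))
    w("</listOfLocalParameters>")
    w("</kineticLaw>")
    w("</reaction>")
  }
  w("</listOfReactions>")
  w("</model>")
  w("</sbml>")
  invisible(path)
}

#' Import an SBML document written by [export_sbml()]
#'
#' @param path SBML file path.
#' @return List with `species` (data frame: id, initial concentration),
#'   `reactions` (data frame: id, reversible, n_reactants, n_products) and
#'   `parameters` (data frame: reaction, id, name, value).
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    initial_concentration = as.numeric(xml2::xml_attr(sp, "initialConcentration")),
    stringsAsFactors = FALSE)
  rx <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  reactions <- data.frame(
    id = xml2::xml_attr(rx, "id"),
    reversible = xml2::xml_attr(rx, "reversible") == "true",
    n_reactants = vapply(rx, function(r)
      length(xml2::xml_find_all(r, ".//s:listOfReactants/s:speciesReference", ns)), 0L),
    n_products = vapply(rx, function(r)
      length(xml2::xml_find_all(r, ".//s:listOfProducts/s:speciesReference", ns)), 0L),
    stringsAsFactors = FALSE)
  par_rows <- lapply(rx, function(r) {
    lp <- xml2::xml_find_all(r, ".//s:localParameter", ns)
    if (!length(lp)) return(NULL)
    data.frame(reaction = xml2::xml_attr(r, "id"),
               id = xml2::xml_attr(lp, "id"),
               name = xml2::xml_attr(lp, "name"),
               value = as.numeric(xml2::xml_attr(lp, "value")),
               stringsAsFactors = FALSE)
  })
  parameters <- do.call(rbind, par_rows)
  list(species = species, reactions = reactions, parameters = parameters)
}
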