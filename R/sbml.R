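#' Import a kinetic scheme from SBML
#'
#' Reads a Systems Biology Markup Language (Level 2/3) document restricted
#' to irreversible first-order mass-action kinetics with a single reactant
#' per reaction. Reversible reactions are expanded into two irreversible
#' ones (forward/reverse rate constants taken as the first/second local or
#' global parameters referenced by the kinetic law). Compartments and
#' volumes are ignored; species initial amounts (or concentrations) become
#' the scheme's initial concentrations.
#'
#' @param document path to an SBML `.xml` file, or a single string of XML.
#' @return a [kinetic_scheme()].
#' @examples
#' sbml <- paste0(
#'   '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
#'   '<model id="m"><listOfSpecies>',
#'   '<species id="A" initialAmount="1"/><species id="B" initialAmount="0"/>',
#'   '</listOfSpecies><listOfParameters>',
#'   '<parameter id="k1" value="0.5"/></listOfParameters>',
#'   '<listOfReactions><reaction id="r1" reversible="false">',
#'   '<listOfReactants><speciesReference species="A"/></listOfReactants>',
#'   '<listOfProducts><speciesReference species="B"/></listOfProducts>',
#'   '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
#'   '<apply><times/><ci>k1</ci><ci>A</ci></apply></math></kineticLaw>',
#'   '</reaction></listOfReactions></model></sbml>')
#' import_sbml(sbml)
#' @export
import_sbml <- function(document) {
  doc <- tryCatch({
    if (length(document) == 1L && !grepl("<", document, fixed = TRUE))
      xml2::read_xml(document)        # a path
    else xml2::read_xml(paste(document, collapse = "\n"))
  }, error = function(e)
    stop("SBML parse error: ", conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L)
    stop("SBML document declares no species", call. = FALSE)
  species <- xml2::xml_attr(sp_nodes, "id")
  amt <- xml2::xml_attr(sp_nodes, "initialAmount")
  conc <- xml2::xml_attr(sp_nodes, "initialConcentration")
  c0 <- ifelse(is.na(amt), conc, amt)
  c0 <- stats::setNames(ifelse(is.na(c0), 0, as.numeric(c0)), species)

  # global parameters (model-level)
  par_nodes <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
  gpar <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))

  from <- character(); to <- character(); kk <- numeric()
  for (rx in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rx, "id")
    if (is.na(rid)) rid <- "<unnamed>"
    reactants <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./listOfReactants/speciesReference"), "species")
    products <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./listOfProducts/speciesReference"), "species")
    stoich <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./listOfReactants/speciesReference"),
      "stoichiometry")
    if (length(reactants) != 1L || any(!is.na(stoich) & as.numeric(stoich) != 1))
      stop("unsupported model: reaction '", rid,
           "' is not first order in a single reactant", call. = FALSE)
    if (length(products) > 1L)
      stop("unsupported model: reaction '", rid,
           "' has more than one product", call. = FALSE)
    reversible <- identical(xml2::xml_attr(rx, "reversible"), "true")
    if (reversible && length(products) != 1L)
      stop("unsupported model: reversible reaction '", rid,
           "' needs exactly one product", call. = FALSE)

    lpar_nodes <- xml2::xml_find_all(
      rx, "./kineticLaw/listOfParameters/parameter|./kineticLaw/listOfLocalParameters/localParameter")
    lpar <- stats::setNames(as.numeric(xml2::xml_attr(lpar_nodes, "value")),
                            xml2::xml_attr(lpar_nodes, "id"))
    params <- c(lpar, gpar[setdiff(names(gpar), names(lpar))])

    # identifiers referenced in the kinetic-law math, in document order
    ci <- xml2::xml_text(xml2::xml_find_all(rx, "./kineticLaw//ci"))
    ci <- trimws(ci)
    krefs <- ci[ci %in% names(params)]
    # mass action requires the reactant itself to appear in the law
    if (!reactants %in% ci)
      stop("unsupported model: kinetic law of reaction '", rid,
           "' is not mass action in its reactant", call. = FALSE)
    needed <- if (reversible) 2L else 1L
    if (length(krefs) < needed)
      stop("unsupported model: kinetic law of reaction '", rid,
           "' references no rate parameter", call. = FALSE)

    from <- c(from, reactants)
    to <- c(to, if (length(products)) products else "loss")
    kk <- c(kk, params[[krefs[1]]])
    if (reversible) {
      from <- c(from, products)
      to <- c(to, reactants)
      kk <- c(kk, params[[krefs[2]]])
    }
  }
  kinetic_scheme(species,
                 data.frame(from = from, to = to, k = kk,
                            stringsAsFactors = FALSE),
                 c0)
}
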