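#' Read or write constraint-based models
#'
#' Two interchangeable on-disk forms are supported: a compact JSON dialect
#' (`metabolites`, `reactions` with stoichiometries and bounds, `biomass`,
#' `exchanges`) and SBML Level 3 with the flux-balance-constraints (fbc)
#' package. `load_model()` dispatches on the file extension; a round trip
#' through either format preserves the flux-balance optimum.
#'
#' @param path file path; `.json` for the JSON dialect, `.xml`/`.sbml` for
#'   SBML.
#'
#' @return A [metabolic_model()].
#' @export
load_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = read_model_json(path),
         xml = ,
         sbml = read_model_sbml(path),
         stop("unrecognised model file extension: .", ext))
}

#' @rdname load_model
#' @param model a [metabolic_model()].
#' @export
write_model_json <- function(model, path) {
  rx <- lapply(model$reactions, function(r) {
    s <- model$S[, r]
    s <- s[s != 0]
    list(id = r,
         metabolites = as.list(s),
         lower_bound = unname(model$lb[r]),
         upper_bound = unname(model$ub[r]))
  })
  obj <- list(id = model$id,
              metabolites = model$metabolites,
              reactions = rx,
              biomass = model$biomass,
              exchanges = as.list(model$exchanges))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname load_model
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- unlist(obj$metabolites)
  rids <- vapply(obj$reactions, `[[`, "", "id")
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  lb <- ub <- numeric(length(rids))
  for (i in seq_along(obj$reactions)) {
    r <- obj$reactions[[i]]
    for (m in names(r$metabolites)) S[m, i] <- as.numeric(r$metabolites[[m]])
    lb[i] <- as.numeric(r$lower_bound)
    ub[i] <- as.numeric(r$upper_bound)
  }
  if (is.null(obj$biomass)) stop("model file lacks a biomass reaction id")
  metabolic_model(obj$id, S, lb, ub, biomass = obj$biomass,
                  exchanges = unlist(obj$exchanges))
}

SBML_NS <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

#' @rdname load_model
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS["s"], SBML_NS["fbc"]),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" compartment="c" constant="false" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false"/>'),
            esc(model$metabolites)),
    '    </listOfSpecies>',
    '    <listOfParameters>')
  bnd_ids <- character(0)
  bnd_vals <- numeric(0)
  bnd_id <- function(v) {
    hit <- which(bnd_vals == v)
    if (length(hit)) return(bnd_ids[hit[1]])
    id <- sprintf("bnd_%d", length(bnd_ids) + 1L)
    bnd_ids <<- c(bnd_ids, id); bnd_vals <<- c(bnd_vals, v)
    id
  }
  rxn_lines <- character(0)
  for (r in model$reactions) {
    lo <- bnd_id(model$lb[[r]]); hi <- bnd_id(model$ub[[r]])
    s <- model$S[, r]; s <- s[s != 0]
    reac <- s[s < 0]; prod <- s[s > 0]
    rxn_lines <- c(rxn_lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(r), tolower(model$lb[[r]] < 0), lo, hi))
    if (length(reac)) rxn_lines <- c(rxn_lines,
      '        <listOfReactants>',
      sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              esc(names(reac)), format(-unname(reac), digits = 17)),
      '        </listOfReactants>')
    if (length(prod)) rxn_lines <- c(rxn_lines,
      '        <listOfProducts>',
      sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              esc(names(prod)), format(unname(prod), digits = 17)),
      '        </listOfProducts>')
    rxn_lines <- c(rxn_lines, '      </reaction>')
  }
  param_lines <- sprintf(
    '      <parameter id="%s" value="%s" constant="true"/>',
    bnd_ids, format(bnd_vals, digits = 17))
  lines <- c(lines, param_lines, '    </listOfParameters>',
    '    <listOfReactions>', rxn_lines, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(model$biomass)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>', '</sbml>')
  # exchange compound mapping travels in annotation-free form: id convention
  writeLines(lines, path)
  invisible(path)
}

#' @rdname load_model
#' @param biomass_pattern regular expression used to locate the biomass
#'   reaction when the SBML file carries no fbc objective.
#' @export
read_model_sbml <- function(path, biomass_pattern = "(?i)biomass") {
  doc <- xml2::read_xml(path)
  ns <- SBML_NS
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  mets <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), "id")
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))
  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rids <- xml2::xml_attr(rxns, "id")
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  lb <- ub <- numeric(length(rids))
  for (i in seq_along(rxns)) {
    rx <- rxns[[i]]
    for (sr in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns))
      S[xml2::xml_attr(sr, "species"), i] <-
        S[xml2::xml_attr(sr, "species"), i] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns))
      S[xml2::xml_attr(sr, "species"), i] <-
        S[xml2::xml_attr(sr, "species"), i] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    lbid <- xml2::xml_attr(rx, "lowerFluxBound")
    ubid <- xml2::xml_attr(rx, "upperFluxBound")
    lb[i] <- if (!is.na(lbid) && lbid %in% names(pvals)) pvals[[lbid]] else -1000
    ub[i] <- if (!is.na(ubid) && ubid %in% names(pvals)) pvals[[ubid]] else 1000
  }
  fo <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  biomass <- if (!inherits(fo, "xml_missing")) xml2::xml_attr(fo, "reaction") else NA
  if (is.na(biomass) || !biomass %in% rids) {
    hit <- grep(biomass_pattern, rids, perl = TRUE, value = TRUE)
    if (length(hit) == 0)
      stop("no biomass reaction: no fbc objective and no reaction id matches '",
           biomass_pattern, "'")
    biomass <- hit[1]
  }
  # exchange convention: EX_<compound> reactions with a single participant
  ex_idx <- grep("^EX_", rids)
  ex_idx <- ex_idx[colSums(S[, ex_idx, drop = FALSE] != 0) == 1]
  exchanges <- stats::setNames(sub("^EX_", "", rids[ex_idx]), rids[ex_idx])
  metabolic_model(xml2::xml_attr(mdl, "id"), S, lb, ub,
                  biomass = biomass, exchanges = exchanges)
}
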