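#' Construct a constraint-based metabolic model
#'
#' A minimal stoichiometric container: a metabolite-by-reaction matrix with
#' flux bounds, a biomass reaction, and exchange reactions that map one-to-one
#' onto environment compounds. Exchange reactions follow the usual convention
#' that negative flux is uptake and positive flux secretion.
#'
#' @param id model identifier.
#' @param S numeric stoichiometric matrix (metabolites x reactions) with
#'   dimnames.
#' @param lb,ub numeric flux bounds, one per reaction (columns of `S`).
#' @param biomass id of the biomass reaction (must be a column of `S`).
#' @param exchanges named character vector mapping exchange reaction ids to
#'   the environment compound each one transports.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, S, lb, ub, biomass, exchanges) {
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("S must carry metabolite row names and reaction column names")
  if (length(lb) != ncol(S) || length(ub) != ncol(S))
    stop("flux bounds and stoichiometric matrix dimensions are inconsistent")
  if (!biomass %in% colnames(S))
    stop("biomass reaction '", biomass, "' not present in the model")
  if (!all(names(exchanges) %in% colnames(S)))
    stop("exchange reactions not present in the model")
  if (anyDuplicated(names(exchanges)))
    stop("each exchange reaction must map to exactly one compound")
  m <- structure(list(
    id = id,
    metabolites = rownames(S),
    reactions = colnames(S),
    S = S,
    lb = stats::setNames(as.numeric(lb), colnames(S)),
    ub = stats::setNames(as.numeric(ub), colnames(S)),
    biomass = biomass,
    exchanges = exchanges
  ), class = "metabolic_model")
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      "  reactions: ", length(x$reactions),
      "  exchanges: ", length(x$exchanges), "\n", sep = "")
  cat("  biomass: ", x$biomass, "\n", sep = "")
  invisible(x)
}

#' Compounds a model can exchange with its environment
#' @param model a `metabolic_model`.
#' @return character vector of compound names.
#' @export
model_compounds <- function(model) unname(model$exchanges)

# exchange reaction id for a compound, or NA
exchange_for <- function(model, compound) {
  idx <- match(compound, model$exchanges)
  if (is.na(idx)) NA_character_ else names(model$exchanges)[idx]
}

#' Define a growth medium
#'
#' @param name medium label (e.g. `"M5C"`).
#' @param carbon_sources character vector of carbon-compound names.
#' @param inorganics character vector of inorganic nutrient names; must be
#'   disjoint from `carbon_sources`.
#' @param uptake_bound positive uptake-flux cap applied to every medium
#'   compound (mmol/gDW/h by convention).
#'
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(name, carbon_sources, inorganics,
                        uptake_bound = 10) {
  if (length(intersect(carbon_sources, inorganics)) > 0)
    stop("carbon sources and inorganics must be disjoint")
  if (uptake_bound <= 0) stop("uptake_bound must be positive")
  structure(list(name = name,
                 carbon_sources = unique(carbon_sources),
                 inorganics = unique(inorganics),
                 uptake_bound = uptake_bound),
            class = "medium_spec")
}

#' @export
print.medium_spec <- function(x, ...) {
  cat("<medium_spec> ", x$name, ": ", length(x$carbon_sources),
      " carbon sources + ", length(x$inorganics), " inorganics (uptake cap ",
      x$uptake_bound, ")\n", sep = "")
  invisible(x)
}

#' All compounds of a medium
#' @param medium a `medium_spec`.
#' @return character vector (carbon sources then inorganics).
#' @export
medium_compounds <- function(medium) c(medium$carbon_sources, medium$inorganics)

# Inorganic nutrients of the defined minimal medium (MM): nitrogen, phosphate,
# sulfate, magnesium and the trace-element cations/anions of the recipe.
MM_INORGANICS <- c("nh4", "pi", "so4", "mg2", "k", "na", "cl", "ca2",
                   "fe2", "mn2", "zn2", "cobalt2", "cu2", "mobd", "bo3")

#' Named in-silico media presets
#'
#' Returns the defined media used throughout the pipeline. `M5C` holds the five
#' carbon sources assayed in vitro (glucose, fructose, malate, sorbitol,
#' methanol). `L10C` holds the ten most abundant leaf-detected metabolites
#' (fumarate, sucrose, aspartate, malate, citrate, glutamate, alanine,
#' fructose, threonine, methanol). `L8C` is L10C without citrate, alanine and
#' threonine, plus glucose. Other leaf media (L13C/L18C/L26C) are not built in
#' and must be supplied as a user [medium_spec()].
#'
#' @param name one of `"M5C"`, `"L8C"`, `"L10C"`.
#' @param inorganics inorganic nutrient set added to every preset; defaults to
#'   the minimal-medium recipe ions.
#' @param uptake_bound uptake cap per compound.
#'
#' @return A [medium_spec()].
#' @export
media_presets <- function(name, inorganics = MM_INORGANICS, uptake_bound = 10) {
  l10 <- c("fumarate", "sucrose", "aspartate", "malate", "citrate",
           "glutamate", "alanine", "fructose", "threonine", "methanol")
  carbons <- switch(name,
    M5C = c("glucose", "fructose", "malate", "sorbitol", "methanol"),
    L10C = l10,
    L8C = c(setdiff(l10, c("citrate", "alanine", "threonine")), "glucose"),
    stop("unknown medium preset '", name,
         "'; L13C/L18C/L26C and other compositions must be given as a ",
         "user medium_spec()"))
  medium_spec(name, carbons, inorganics, uptake_bound)
}

#' Build toy single-species metabolic models with known carbon usability
#'
#' Each toy model lumps catabolism into one route per usable carbon source
#' (uptake, conversion to a biomass precursor) plus a single biomass reaction
#' that consumes the precursor together with every inorganic nutrient. Growth
#' is therefore possible exactly when at least one usable carbon source and
#' all inorganics can be taken up. Exchange reactions exist for every compound
#' in `inorganic_set` and for the union of all species' carbon sources (plus
#' `extra_carbons`), so unusable carbons are exchangeable but metabolically
#' inert.
#'
#' @param species_specs named list; each element is the character vector of
#'   carbon sources that species can use (at least one each).
#' @param inorganic_set character vector of inorganic nutrients every species
#'   requires.
#' @param extra_carbons carbon compounds to expose as exchanges even if no
#'   species uses them.
#' @param carbon_yield biomass-precursor yield per unit carbon uptake.
#'
#' @return A named list of [metabolic_model()] objects.
#' @export
toy_models <- function(species_specs, inorganic_set = c("nh4", "pi", "so4"),
                       extra_carbons = character(), carbon_yield = 1) {
  if (length(species_specs) == 0) stop("no species specified")
  if (is.null(names(species_specs)))
    names(species_specs) <- paste0("sp", seq_along(species_specs))
  all_carbons <- unique(c(unlist(species_specs), extra_carbons))
  lapply(stats::setNames(nm = names(species_specs)), function(sp) {
    usable <- unique(species_specs[[sp]])
    if (length(usable) == 0) stop("species '", sp, "' has an empty carbon set")
    compounds <- c(all_carbons, inorganic_set)
    mets <- c(paste0(compounds, "_c"), "precursor_c", "biomass_c")
    rxns <- c(paste0("EX_", compounds),
              paste0("CAT_", usable),
              "BIOMASS")
    S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
    for (cp in compounds) S[paste0(cp, "_c"), paste0("EX_", cp)] <- -1
    for (cs in usable) {
      S[paste0(cs, "_c"), paste0("CAT_", cs)] <- -1
      S["precursor_c", paste0("CAT_", cs)] <- carbon_yield
    }
    # biomass consumes the precursor and a trace of every inorganic nutrient
    S["precursor_c", "BIOMASS"] <- -1
    for (io in inorganic_set) S[paste0(io, "_c"), "BIOMASS"] <- -0.01
    S["biomass_c", "BIOMASS"] <- 1
    # biomass_c drained through a sink so the LP is balanced
    S <- cbind(S, SINK_biomass = 0)
    S["biomass_c", "SINK_biomass"] <- -1
    lb <- rep(0, ncol(S)); ub <- rep(1000, ncol(S))
    names(lb) <- names(ub) <- colnames(S)
    exchanges <- stats::setNames(compounds, paste0("EX_", compounds))
    metabolic_model(sp, S, lb, ub, biomass = "BIOMASS", exchanges = exchanges)
  })
}
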