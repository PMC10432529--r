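#' Flux balance analysis under a defined medium
#'
#' Maximises biomass flux subject to steady-state mass balance and flux
#' bounds. Uptake (negative exchange flux) is opened only for compounds
#' present in the medium, capped at the medium's `uptake_bound`; all other
#' exchanges are closed for uptake. Secretion stays open for every exchange.
#'
#' @param model a [metabolic_model()].
#' @param medium a [medium_spec()], or a character vector of compound names
#'   (then `uptake_bound` applies).
#' @param uptake_bound uptake cap used when `medium` is a plain compound
#'   vector.
#' @param full if `TRUE` return the whole flux vector as attribute `"fluxes"`.
#'
#' @return Optimal biomass flux (0 when growth is infeasible).
#' @export
fba <- function(model, medium, uptake_bound = 10, full = FALSE) {
  prob <- fba_problem(model, medium, uptake_bound)
  obj <- numeric(length(model$reactions))
  obj[match(model$biomass, model$reactions)] <- 1
  sol <- solve_lp(obj, prob$S, rep("=", nrow(prob$S)), rep(0, nrow(prob$S)),
                  prob$lb, prob$ub, maximize = TRUE)
  if (sol$status != "optimal") return(0)
  if (sol$objval >= 0.999 * max(prob$ub))
    stop("unbounded biomass flux: model defect (check internal cycles/bounds)")
  val <- max(0, sol$objval)
  if (full) attr(val, "fluxes") <- stats::setNames(sol$x, model$reactions)
  val
}

# bounds for a model constrained to a medium (optionally a compound subset)
fba_problem <- function(model, medium, uptake_bound = 10,
                        open_compounds = NULL) {
  if (inherits(medium, "medium_spec")) {
    comps <- medium_compounds(medium)
    bound <- medium$uptake_bound
  } else {
    comps <- as.character(medium)
    bound <- uptake_bound
  }
  if (!is.null(open_compounds)) comps <- intersect(comps, open_compounds)
  lb <- model$lb; ub <- model$ub
  # close all exchange uptake, then open medium compounds
  lb[names(model$exchanges)] <- pmax(lb[names(model$exchanges)], 0)
  for (cp in comps) {
    ex <- exchange_for(model, cp)
    if (!is.na(ex)) lb[ex] <- -bound
  }
  list(S = model$S, lb = lb, ub = ub)
}

# growth optimum with only `open` medium compounds available
fba_subset <- function(model, medium, open) {
  prob <- fba_problem(model, medium, open_compounds = open)
  obj <- numeric(length(model$reactions))
  obj[match(model$biomass, model$reactions)] <- 1
  sol <- solve_lp(obj, prob$S, rep("=", nrow(prob$S)), rep(0, nrow(prob$S)),
                  prob$lb, prob$ub, maximize = TRUE)
  if (sol$status != "optimal") 0 else max(0, sol$objval)
}

#' Enumerate minimum nutritional requirements of a model
#'
#' Finds the smallest sets of medium compounds whose uptake sustains biomass
#' production at or above a threshold, together with all alternative minima of
#' the same cardinality. The integer program (minimise the number of open
#' uptake indicators subject to biomass >= threshold) is solved exactly:
#' compounds whose removal alone abolishes growth are fixed as essential, and
#' the remainder is searched in ascending cardinality with flux-balance
#' feasibility as the oracle, so every set returned is a global minimum and
#' alternatives are collected until `max_alternatives`.
#'
#' @param model a [metabolic_model()].
#' @param medium a [medium_spec()]; the model must grow on the full medium.
#' @param threshold_fraction growth threshold as a fraction of the
#'   medium-constrained maximum (default 0.1).
#' @param max_alternatives cap on enumerated alternative minima (default 50).
#'
#' @return An object of class `minimal_media_result` with elements
#'   `species`, `medium_name`, `minimal_sets` (list of character vectors),
#'   `union_requirements`, `essential`, `growth_threshold`, `max_growth`.
#' @export
minimal_media <- function(model, medium, threshold_fraction = 0.1,
                          max_alternatives = 50) {
  stopifnot(inherits(medium, "medium_spec"))
  comps <- medium_compounds(medium)
  # restrict to compounds the model can actually exchange
  comps <- comps[!is.na(vapply(comps, exchange_for, "", model = model))]
  vmax <- fba(model, medium)
  if (vmax <= 1e-6)
    stop("model '", model$id, "' cannot grow on medium '", medium$name, "'")
  if (threshold_fraction > 1)
    stop("growth threshold exceeds the medium-constrained maximum")
  thr <- threshold_fraction * vmax
  grows <- function(open) fba_subset(model, medium, open) >= thr - 1e-9

  essential <- comps[!vapply(comps, function(m) grows(setdiff(comps, m)),
                             logical(1))]
  free <- setdiff(comps, essential)

  minimal_sets <- list()
  if (grows(essential)) {
    minimal_sets <- list(essential)
  } else {
    for (k in seq_len(length(free))) {
      subsets <- utils::combn(free, k, simplify = FALSE)
      hits <- Filter(function(a) grows(c(essential, a)), subsets)
      if (length(hits) > 0) {
        minimal_sets <- lapply(hits, function(a) c(essential, a))
        break
      }
    }
  }
  if (length(minimal_sets) == 0)
    stop("no minimal medium found below the enumeration limit")
  if (length(minimal_sets) > max_alternatives)
    minimal_sets <- minimal_sets[seq_len(max_alternatives)]
  minimal_sets <- lapply(minimal_sets, function(s) sort(s))

  structure(list(
    species = model$id,
    medium_name = medium$name,
    minimal_sets = minimal_sets,
    union_requirements = sort(unique(unlist(minimal_sets))),
    essential = sort(essential),
    growth_threshold = thr,
    max_growth = vmax
  ), class = "minimal_media_result")
}

#' @export
print.minimal_media_result <- function(x, ...) {
  cat("<minimal_media_result> ", x$species, " on ", x$medium_name, "\n",
      "  ", length(x$minimal_sets), " minimal set(s) of size ",
      length(x$minimal_sets[[1]]), "; union of ",
      length(x$union_requirements), " compounds\n", sep = "")
  invisible(x)
}

#' Metabolic resource overlap between two species
#'
#' MRO compares the minimal nutritional requirements of two models evaluated
#' on the same medium: with `M_A`, `M_B` the unions of each species'
#' alternative minimal requirement sets, the mean-normalised index is
#' `|M_A \U2229 M_B| / ((|M_A| + |M_B|) / 2)`; the min-normalised variant
#' divides by `min(|M_A|, |M_B|)`. `carbon_only` drops inorganic nutrients
#' (shared salts compress the dynamic range) before computing the overlap.
#'
#' @param resA,resB [minimal_media()] results computed on the same medium.
#' @param medium the shared [medium_spec()]; needed for `carbon_only`.
#' @param carbon_only restrict requirement sets to the medium's carbon
#'   sources.
#' @param normalisation `"mean"` (default) or `"min"`.
#'
#' @return An object of class `mro_result` with the index and set sizes.
#' @export
mro <- function(resA, resB, medium = NULL, carbon_only = FALSE,
                normalisation = c("mean", "min")) {
  normalisation <- match.arg(normalisation)
  if (!identical(resA$medium_name, resB$medium_name))
    stop("minimal-media results were computed on different media")
  MA <- resA$union_requirements
  MB <- resB$union_requirements
  if (carbon_only) {
    if (is.null(medium))
      stop("carbon_only requires the medium_spec to identify carbon sources")
    MA <- intersect(MA, medium$carbon_sources)
    MB <- intersect(MB, medium$carbon_sources)
  }
  inter <- length(intersect(MA, MB))
  denom <- switch(normalisation,
                  mean = (length(MA) + length(MB)) / 2,
                  min = min(length(MA), length(MB)))
  val <- if (denom == 0) 0 else inter / denom
  structure(list(
    pair = c(resA$species, resB$species),
    medium_name = resA$medium_name,
    mro = val,
    set_sizes = c(A = length(MA), B = length(MB), intersection = inter),
    carbon_only = carbon_only,
    normalisation = normalisation
  ), class = "mro_result")
}

#' @export
print.mro_result <- function(x, ...) {
  cat(sprintf("<mro_result> %s vs %s on %s: MRO = %.4f (|A|=%d, |B|=%d, |A&B|=%d, %s-normalised%s)\n",
              x$pair[1], x$pair[2], x$medium_name, x$mro,
              x$set_sizes["A"], x$set_sizes["B"], x$set_sizes["intersection"],
              x$normalisation, if (x$carbon_only) ", carbon only" else ""))
  invisible(x)
}
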