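# Independent oracles used across the suite. Each one recomputes a quantity
# by the most direct route available (enumeration, closed form, hand
# formula), staying off the code paths it checks.

# exhaustive minimal-media search: test every subset of medium compounds
# with an FBA feasibility check, keep the minimum-cardinality ones
oracle_minimal_media <- function(model, medium, threshold_fraction = 0.1) {
  comps <- medium_compounds(medium)
  comps <- comps[comps %in% model_compounds(model)]
  thr <- threshold_fraction * fba(model, medium)
  grows <- function(open)
    phyllocomp:::fba_subset(model, medium, open) >= thr - 1e-9
  hits <- list()
  for (k in seq_along(comps)) {
    for (s in utils::combn(comps, k, simplify = FALSE))
      if (grows(s)) hits <- c(hits, list(sort(s)))
    if (length(hits) > 0) break
  }
  hits
}

# sets-of-sets comparison ignoring order
same_set_collection <- function(a, b) {
  norm <- function(x) sort(vapply(x, function(s) paste(sort(s), collapse = "|"), ""))
  identical(norm(a), norm(b))
}

# Bray-Curtis by the printed formula
oracle_bray_curtis <- function(u, v) sum(abs(u - v)) / sum(u + v)

# sorting-based empirical quantile with linear interpolation
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# founder reconstruction by explicit founder bookkeeping: build the founder
# list, expand to descendants, and read the fractions straight off
oracle_founder_reconstruction <- function(founder_divisions, rs_gt4 = 5) {
  k <- pmin(founder_divisions, rs_gt4)
  desc <- rep(k, times = 2^k)
  f_obs <- table(factor(desc, levels = sort(unique(k)))) / length(desc)
  g <- table(factor(k, levels = sort(unique(k)))) / length(k)
  list(cell_fractions = as.numeric(f_obs),
       founder_fractions = as.numeric(g),
       fold_increase = length(desc) / length(k))
}

# quick random toy-model configuration for metabolic tests
random_toy_config <- function(seed, n_species = 2, n_carbons = 4) {
  set.seed(seed)
  carbons <- paste0("c", seq_len(n_carbons))
  specs <- lapply(seq_len(n_species), function(i)
    sample(carbons, sample(seq_len(min(3, n_carbons)), 1)))
  names(specs) <- paste0("sp", seq_len(n_species))
  list(specs = specs,
       medium = medium_spec("rand", carbons, c("nh4", "pi"), uptake_bound = 10),
       models = toy_models(specs, inorganic_set = c("nh4", "pi"),
                           extra_carbons = carbons))
}
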