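#' Background-correct per-cell green fluorescence
#'
#' Subtracts the mean background fluorescence of each field of view from the
#' green intensity of every cell in that field. Corrected values at or below
#' zero come from cells dimmer than their background (at least LOD-many
#' divisions); they are floored at `floor_value` and flagged.
#'
#' @param cells data frame with columns `cell_id`, `fov`, `green`,
#'   `bg_green` (per-FOV background readings; repeated values per FOV are
#'   averaged) and any others, which pass through.
#' @param floor_value positive floor for non-positive corrected intensities
#'   (default 1 a.u.).
#'
#' @return `cells` with added columns `green_corrected` and `bg_flagged`.
#' @export
background_correct <- function(cells, floor_value = 1) {
  need <- c("cell_id", "fov", "green", "bg_green")
  if (!all(need %in% names(cells)))
    stop("cells must have columns: ", paste(need, collapse = ", "))
  if (anyNA(cells$bg_green))
    stop("missing background for at least one field of view")
  bg <- tapply(cells$bg_green, cells$fov, mean)
  corrected <- cells$green - as.numeric(bg[as.character(cells$fov)])
  flagged <- corrected <= 0
  corrected[flagged] <- floor_value
  cells$green_corrected <- corrected
  cells$bg_flagged <- flagged
  cells
}

#' Reproductive success of a single cell
#'
#' The fluorescence-dilution reporter halves its green signal at every
#' division, so the division count since arrival is
#' `RS = log2(x0_mean / x)`, with `x0_mean` the mean corrected intensity of
#' the population at time zero and `x` the cell's corrected intensity.
#'
#' @param x0_mean mean initial-population intensity (a.u., > 0).
#' @param x per-cell corrected intensity (a.u., > 0); vectorised.
#' @return Real-valued division counts.
#' @export
reproductive_success <- function(x0_mean, x) {
  if (!is.finite(x0_mean) || x0_mean <= 0)
    stop("x0_mean must be a positive intensity")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("intensities must be positive")
  log2(x0_mean / x)
}

#' Limit of detection from background-derived RS values
#'
#' Image background is dim, so RS values computed from background readings
#' are high; a cell's RS is trustworthy only below the level where it could
#' plausibly be background. The LOD is the RS value with probability `alpha`
#' of being background noise: the empirical `alpha`-quantile (linear ECDF
#' interpolation) of the background RS distribution. The working LOD used
#' for binning is this quantile snapped down to the nearest division-bin
#' edge (`k + 0.5`), see [bin_rs()].
#'
#' @param bg_rs RS values computed from background intensities (>= 20).
#' @param alpha background-probability level (default 0.05).
#'
#' @return List with `lod` (raw quantile) and `working_lod` (snapped to a
#'   bin edge).
#' @export
lod_from_background <- function(bg_rs, alpha = 0.05) {
  if (length(bg_rs) < 20)
    stop("at least 20 background values are required")
  q <- unname(stats::quantile(bg_rs, probs = alpha, type = 7))
  working <- floor(q + 0.5) - 0.5
  list(lod = q, working_lod = working)
}

RS_BINS <- c("RS_0", "RS_1", "RS_2", "RS_3", "RS_4", "RS_>4")

#' Bin reproductive-success values into division classes
#'
#' Half-open bins centred on integer division counts: `RS_0: RS < 0.5`,
#' `RS_k: k - 0.5 <= RS < k + 0.5` for k = 1..4, and `RS_>4: RS >= 4.5`.
#' Values at or above the working LOD are pooled into the top class and
#' flagged censored (their division count cannot be resolved further).
#' Negative RS values (cells brighter than the t0 mean) fall in `RS_0` and
#' are counted in the `n_negative` attribute.
#'
#' @param rs_values numeric RS values.
#' @param lod working limit of detection; must sit on a bin edge
#'   (`k + 0.5`; default 4.5).
#'
#' @return Data frame of class `rs_records` with columns `rs`,
#'   `bin` (factor over all classes), `censored`; attribute `n_negative`.
#' @export
bin_rs <- function(rs_values, lod = 4.5) {
  if (!isTRUE(all.equal(lod %% 1, 0.5)))
    stop("lod must sit on a bin edge (k + 0.5)")
  k <- floor(rs_values + 0.5)
  k[k < 0] <- 0
  censored <- rs_values >= lod
  lab <- ifelse(censored, "RS_>4", paste0("RS_", pmin(k, 4)))
  out <- data.frame(rs = rs_values,
                    bin = factor(lab, levels = RS_BINS),
                    censored = censored)
  attr(out, "n_negative") <- sum(rs_values < 0)
  class(out) <- c("rs_records", "data.frame")
  out
}

#' Population structure: per-bin fractions
#'
#' Tabulates binned RS values into relative fractions per experimental unit
#' (e.g. treatment x timepoint x replicate). Units with fewer than
#' `min_cells` cells are kept but flagged with a warning.
#'
#' @param records an [bin_rs()] result (or data frame with a `bin` column).
#' @param groups optional data frame of grouping columns aligned with
#'   `records` rows; `NULL` treats all records as one unit.
#' @param min_cells warning threshold for cells per unit (default 100).
#'
#' @return Data frame of class `rs_distribution`: grouping columns, one
#'   column per RS class holding fractions that sum to 1, and `n_cells`.
#' @export
rs_distribution <- function(records, groups = NULL, min_cells = 100) {
  bins <- records$bin
  if (is.null(groups)) {
    groups <- data.frame(unit = rep("all", length(bins)))
  }
  key <- interaction(groups, drop = TRUE, lex.order = TRUE)
  tab <- table(key, bins)
  n <- rowSums(tab)
  frac <- sweep(unclass(tab), 1, n, "/")
  if (any(n < min_cells))
    warning(sum(n < min_cells), " unit(s) have fewer than ", min_cells,
            " cells")
  meta <- unique(cbind(groups, .key = as.character(key)))
  meta <- meta[match(rownames(tab), meta$.key), , drop = FALSE]
  meta$.key <- NULL
  out <- cbind(meta, as.data.frame(frac), n_cells = as.integer(n))
  rownames(out) <- NULL
  class(out) <- c("rs_distribution", "data.frame")
  out
}

#' Reconstruct the founder population from an observed RS distribution
#'
#' A founder that divided `k` times is represented by `2^k` descendants, so
#' observed cell fractions over-represent prolific founders. Inverting the
#' weighting gives founder fractions `g_k = f_k 2^-k / sum_j f_j 2^-j` and a
#' population fold increase since inoculation `1 / sum_j f_j 2^-j`. The
#' censored `RS_>4` class needs a representative division count; the default
#' 5 (its lower bound) makes the fold increase conservative.
#'
#' @param fractions named numeric vector of observed cell fractions over the
#'   RS classes (names from `RS_0` to `RS_>4`), summing to 1.
#' @param rs_gt4_divisions representative division count for `RS_>4`
#'   (default 5).
#'
#' @return List with `founder_fractions` (named by division count, summing
#'   to 1) and `fold_increase`.
#' @export
founder_reconstruction <- function(fractions, rs_gt4_divisions = 5) {
  if (length(fractions) == 0 || sum(fractions) == 0)
    stop("empty RS distribution")
  if (is.null(names(fractions)))
    names(fractions) <- RS_BINS[seq_along(fractions)]
  if (!isTRUE(all.equal(sum(fractions), 1)))
    stop("fractions must sum to 1")
  k <- suppressWarnings(as.numeric(sub("^RS_", "", names(fractions))))
  k[names(fractions) == "RS_>4"] <- rs_gt4_divisions
  if (anyNA(k)) stop("unrecognised RS class names")
  w <- fractions * 2^(-k)
  g <- w / sum(w)
  names(g) <- k
  list(founder_fractions = g, fold_increase = 1 / sum(w))
}

#' Bray-Curtis dissimilarity between population structures
#'
#' Compositional distance `BC(u, v) = sum|u_i - v_i| / sum(u_i + v_i)`
#' between rows of relative fractions (delegated to [vegan::vegdist()]).
#'
#' @param fractions numeric matrix or data frame, rows = units, columns =
#'   RS classes; rows must be non-negative and sum to 1.
#' @return A symmetric `dist`-convertible distance matrix in `[0, 1]`.
#' @export
bray_curtis <- function(fractions) {
  m <- as.matrix(fractions)
  if (any(m < 0)) stop("fractions must be non-negative")
  if (!isTRUE(all.equal(unname(rowSums(m)), rep(1, nrow(m)))))
    stop("rows must sum to 1")
  as.matrix(vegan::vegdist(m, method = "bray"))
}
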