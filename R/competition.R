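#' Competition coefficient from a carrying capacity
#'
#' Competition coefficients are the reciprocal of the carrying capacity
#' estimated for the focal strain in the relevant pairing: `a = 1/K`.
#'
#' @param K carrying capacity, strictly positive.
#' @return `1/K`.
#' @export
competition_coefficient <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("carrying capacity must be positive and finite")
  1 / K
}

#' Competitive-ability score
#'
#' `score = (mu_i - 1) / sqrt(a_ii * a_ij)` where `mu_i` is the focal
#' strain's monoculture growth rate, `a_ii = 1/K_intra` the intraspecific
#' competition coefficient (focal vs a near-isogenic competitor) and
#' `a_ij = 1/K_inter` the interspecific coefficient (focal vs a heterologous
#' competitor). The numerator subtracts the dimensionless constant 1 from a
#' per-hour rate; the score is used exactly in this printed form, with `mu`
#' in the per-hour units produced by [fit_logistic()], so scores are
#' comparable only within one experimental context (and are usually
#' z-scaled, see [zscore_scores()]). The geometric mean in the denominator
#' makes the score symmetric in the two coefficients and its sign follows
#' `mu_i - 1`.
#'
#' @param mu_mono focal monoculture growth rate (per hour).
#' @param K_intra,K_inter carrying capacities under intra- and interspecific
#'   competition, strictly positive.
#'
#' @return The raw competitive score.
#' @export
competitive_score <- function(mu_mono, K_intra, K_inter) {
  a_ii <- competition_coefficient(K_intra)
  a_ij <- competition_coefficient(K_inter)
  (mu_mono - 1) / sqrt(a_ii * a_ij)
}

#' z-scale a cohort of raw scores
#'
#' Centres to zero and rescales to unit sample SD. The cohort is whatever
#' the caller passes: typically all replicate-level scores within one
#' context (in vitro or in planta).
#'
#' @param raw numeric vector of raw scores (length >= 2, nonzero SD).
#' @return Vector of z-scores with mean 0 and sample SD 1.
#' @export
zscore_scores <- function(raw) {
  if (length(raw) < 2) stop("at least 2 scores are required for z-scaling")
  s <- stats::sd(raw)
  if (s == 0) stop("scores have zero variance; z-scaling undefined")
  (raw - mean(raw)) / s
}

#' Relative change in area under the curve
#'
#' Ratio of the focal strain's AUC in co-culture to its monoculture AUC:
#' 1 means no effect of the competitor, values below 1 mean suppression.
#'
#' @param auc_co,auc_mono areas under the (fluorescence) growth curve.
#' @return `auc_co / auc_mono`.
#' @export
relative_auc_change <- function(auc_co, auc_mono) {
  if (any(auc_mono <= 0)) stop("monoculture AUC must be positive")
  auc_co / auc_mono
}
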