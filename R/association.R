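#' Patristic distances from a focal tip
#'
#' Sums branch lengths along the tip-to-tip path from the focal strain to
#' every other tip (via [ape::cophenetic.phylo()]).
#'
#' @param tree an [ape::read.tree()] `phylo` object, a newick string, or a
#'   path to a newick file.
#' @param focal focal tip label.
#'
#' @return List of class `phylo_distances`: `focal`, `entries` (named
#'   distances to all other tips), `matrix` (full patristic matrix).
#' @export
patristic_distances <- function(tree, focal) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or newick")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!focal %in% tree$tip.label) stop("focal tip '", focal, "' not in tree")
  dm <- ape::cophenetic.phylo(tree)
  structure(list(focal = focal,
                 entries = dm[focal, setdiff(colnames(dm), focal)],
                 matrix = dm),
            class = "phylo_distances")
}

#' Pearson correlation with test
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero variance.
#' @return An `assoc_result` list: `method`, `estimate` (r), `ci` (95%),
#'   `df`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(method = "pearson",
                 estimate = unname(ct$estimate),
                 ci = as.numeric(ct$conf.int),
                 df = unname(ct$parameter),
                 p_value = ct$p.value,
                 n = length(x)),
            class = "assoc_result")
}

#' Linear regression with effect sizes
#'
#' Ordinary least squares with overall F, (adjusted) R-squared, 95%
#' confidence intervals, and per-predictor eta-squared from the sequential
#' (Type-I) ANOVA decomposition (`SS_term / SS_total`).
#'
#' @param formula model formula.
#' @param data data frame.
#'
#' @return An `assoc_result` list with `fit` (the `lm` object),
#'   `coefficients`, `ci`, `r_squared`, `adj_r_squared`, `F`, `df`,
#'   `p_value`, `eta_squared`.
#' @export
fit_linear <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  sm <- summary(fit)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  eta <- stats::setNames(ss / sum(ss), rownames(an))
  eta <- eta[names(eta) != "Residuals"]
  fstat <- sm$fstatistic
  structure(list(method = "ols",
                 fit = fit,
                 coefficients = stats::coef(fit),
                 ci = stats::confint(fit),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 F = unname(fstat[1]),
                 df = unname(fstat[2:3]),
                 p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                            lower.tail = FALSE)),
                 eta_squared = eta),
            class = "assoc_result")
}

#' Gamma generalised linear model with a log link
#'
#' For strictly positive responses. Reports the IRLS fit, null and residual
#' deviance, and the deviance pseudo-R-squared
#' `1 - residual deviance / null deviance`.
#'
#' @param formula model formula.
#' @param data data frame; the response must be strictly positive.
#'
#' @return An `assoc_result` list with `fit`, `coefficients`, `ci`,
#'   `null_deviance`, `residual_deviance`, `pseudo_r_squared`.
#' @export
fit_gamma_glm <- function(formula, data) {
  resp <- stats::model.response(stats::model.frame(formula, data))
  if (any(resp <= 0))
    stop("Gamma-log GLM requires a strictly positive response")
  fit <- stats::glm(formula, data = data, family = stats::Gamma(link = "log"))
  structure(list(method = "gamma-log glm",
                 fit = fit,
                 coefficients = stats::coef(fit),
                 ci = suppressMessages(suppressWarnings(stats::confint.default(fit))),
                 null_deviance = fit$null.deviance,
                 residual_deviance = fit$deviance,
                 pseudo_r_squared = 1 - fit$deviance / fit$null.deviance),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("<assoc_result> ", x$method, "\n", sep = "")
  if (x$method == "pearson") {
    cat(sprintf("  r = %.4f (95%% CI %.4f..%.4f), df = %d, p = %.4g\n",
                x$estimate, x$ci[1], x$ci[2], x$df, x$p_value))
  } else if (x$method == "ols") {
    cat(sprintf("  R2 = %.4f (adj %.4f), F(%g, %g) = %.4g, p = %.4g\n",
                x$r_squared, x$adj_r_squared, x$df[1], x$df[2], x$F,
                x$p_value))
    cat("  eta^2:", paste(sprintf("%s %.3f", names(x$eta_squared),
                                  x$eta_squared), collapse = ", "), "\n")
  } else {
    cat(sprintf("  pseudo-R2 = %.4f (null dev %.4g, residual dev %.4g)\n",
                x$pseudo_r_squared, x$null_deviance, x$residual_deviance))
  }
  invisible(x)
}

#' Reference metrics for the Pe299R strain panel
#'
#' Published reference measurements for six phyllosphere epiphytes relative
#' to the focal strain *Pantoea eucalypti* 299R: patristic phylogenetic
#' distance (`pd`), empirical carbon-profile dissimilarity, metabolic
#' resource overlap under several in-silico media (`mro_m5c` .. `mro_l26c`),
#' and z-scored competitive-ability scores in vitro and in planta. Shipped
#' as a plain-text fixture so the panel-level correlations can be computed
#' without downloads.
#'
#' @return Data frame with one row per competitor strain.
#' @export
strain_metrics <- function() {
  utils::read.csv(system.file("extdata", "pe299r_strain_metrics.csv",
                              package = "phyllocomp"),
                  stringsAsFactors = FALSE)
}
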