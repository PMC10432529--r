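#' Build a z-scored carbon-utilisation profile matrix
#'
#' Arranges per-strain, per-carbon growth parameters (`mu` and `K`) into a
#' strains x (carbon x parameter) matrix and z-scales each column (sample SD,
#' n-1 denominator). Conditions whose fit did not converge are coded as
#' no-growth (`mu = 0`, `K = 0`) before scaling. Columns without variance
#' carry no contrast between strains and are dropped with a warning.
#'
#' @param fits data frame with columns `strain`, `carbon`, `mu`, `K` and
#'   optionally `converged`; one row per strain x carbon condition.
#'
#' @return Numeric matrix (strains x scaled parameters) of class
#'   `carbon_profile`, with attributes `dropped` (zero-variance columns) and
#'   `scaling = "z-score, sample SD"`.
#' @export
build_carbon_profile <- function(fits) {
  need <- c("strain", "carbon", "mu", "K")
  if (!all(need %in% names(fits)))
    stop("fits must have columns: ", paste(need, collapse = ", "))
  strains <- unique(fits$strain)
  if (length(strains) < 2) stop("at least 2 strains are required")
  carbons <- unique(fits$carbon)
  if (!is.null(fits$converged)) {
    fits$mu[!fits$converged] <- 0
    fits$K[!fits$converged] <- 0
  }
  grid <- table(fits$strain, fits$carbon)
  if (any(grid != 1))
    stop("fits must cover each strain x carbon combination exactly once")
  M <- matrix(0, length(strains), 2 * length(carbons),
              dimnames = list(strains,
                              c(paste0(carbons, "_mu"), paste0(carbons, "_K"))))
  for (i in seq_len(nrow(fits))) {
    M[fits$strain[i], paste0(fits$carbon[i], "_mu")] <- fits$mu[i]
    M[fits$strain[i], paste0(fits$carbon[i], "_K")] <- fits$K[i]
  }
  sds <- apply(M, 2, stats::sd)
  dropped <- colnames(M)[sds == 0]
  if (length(dropped) > 0)
    warning("dropping zero-variance columns: ", paste(dropped, collapse = ", "))
  M <- M[, sds > 0, drop = FALSE]
  M <- scale(M)                      # center + sample-SD z-score
  attr(M, "scaled:center") <- NULL
  attr(M, "scaled:scale") <- NULL
  structure(M, dropped = dropped, scaling = "z-score, sample SD",
            class = c("carbon_profile", "matrix", "array"))
}

#' Carbon-profile dissimilarity from a focal strain
#'
#' Euclidean distances between z-scored profile rows; the distance from the
#' focal strain to each other strain is the carbon-utilisation dissimilarity
#' used as an empirical proxy for resource-use difference. Also exposes the
#' full distance matrix and the complete-linkage merge tree.
#'
#' @param profile a [build_carbon_profile()] matrix.
#' @param focal focal strain (row name).
#'
#' @return List of class `profile_dissimilarity` with `focal`, `entries`
#'   (named distances to the other strains), `dist_matrix`, and `hclust`
#'   (complete linkage).
#' @export
profile_dissimilarity <- function(profile, focal) {
  if (!focal %in% rownames(profile))
    stop("focal strain '", focal, "' absent from the profile")
  d <- stats::dist(unclass(profile), method = "euclidean")
  dm <- as.matrix(d)
  entries <- dm[focal, setdiff(rownames(dm), focal)]
  structure(list(focal = focal, entries = entries, dist_matrix = dm,
                 hclust = stats::hclust(d, method = "complete")),
            class = "profile_dissimilarity")
}

#' @export
print.profile_dissimilarity <- function(x, ...) {
  cat("<profile_dissimilarity> from ", x$focal, ":\n", sep = "")
  print(round(sort(x$entries), 3))
  invisible(x)
}

#' Write a complete-linkage dendrogram as newick
#' @param diss a [profile_dissimilarity()] result.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(diss, path) {
  ape::write.tree(ape::as.phylo(diss$hclust), file = path)
  invisible(path)
}
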