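#' Permutational multivariate analysis of variance on a distance matrix
#'
#' Partitions the total sum of squared distances with sequential (Type-I)
#' sums of squares following the Gower-matrix formulation: with
#' `A = -D^2 / 2` and `G` its double-centred form, the SS explained by a
#' nested sequence of designs is `tr(H_j G) - tr(H_{j-1} G)` where `H_j` is
#' the hat matrix of the design including factors `1..j`. The pseudo-F per
#' factor is its mean square over the residual mean square, and p-values
#' come from unrestricted permutation of the sample labels:
#' `p = (1 + #\{F* >= F_obs\}) / (n_perm + 1)`.
#'
#' Degenerate inputs (all distances equal, hence no multivariate variance)
#' return `F = 0`, `p = 1`.
#'
#' @param d distance matrix (square symmetric matrix or `dist`).
#' @param factors data frame of factors, one column per term, in the order
#'   the sequential decomposition should use; every factor needs at least 2
#'   groups with at least 2 members overall.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#'
#' @return Data frame of class `permanova_result`, one row per factor plus a
#'   residual row: `df`, `ss`, `r_squared`, `pseudo_F`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(d, factors, n_perm = 999, seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  factors <- as.data.frame(factors)
  if (nrow(factors) != n) stop("factor table does not match the distances")
  for (f in names(factors)) {
    tb <- table(factors[[f]])
    if (length(tb) < 2) stop("factor '", f, "' has fewer than 2 groups")
    if (all(tb < 2)) stop("factor '", f, "' has only singleton groups")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ss_total <- sum(diag(G))

  # hat matrices of the cumulative designs (intercept implicit via centring)
  hats <- list()
  X <- matrix(1, n, 1)
  for (j in seq_along(factors)) {
    X <- cbind(X, stats::model.matrix(~ 0 + factor(factors[[j]])))
    qr_x <- qr(X)
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
  }
  dfs <- vapply(factors, function(f) length(unique(f)) - 1L, integer(1))
  df_res <- n - 1L - sum(dfs)
  if (df_res < 1) stop("no residual degrees of freedom")

  stat_fun <- function(Gp) {
    tr_h <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    tr0 <- sum(Gp) / n                     # tr((11'/n) Gp)
    ss <- diff(c(tr0, tr_h))
    ss_res <- sum(diag(Gp)) - tr_h[length(tr_h)]
    Fs <- (ss / dfs) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, Fs = Fs)
  }

  obs <- stat_fun(G)
  if (ss_total <= 1e-12) {
    out <- data.frame(term = c(names(factors), "Residual"),
                      df = c(dfs, df_res),
                      ss = 0, r_squared = 0,
                      pseudo_F = c(rep(0, length(dfs)), NA),
                      p_value = c(rep(1, length(dfs)), NA),
                      n_permutations = n_perm)
    class(out) <- c("permanova_result", "data.frame")
    return(out)
  }

  exceed <- numeric(length(dfs))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    Gp <- G[idx, idx]
    Fs <- stat_fun(Gp)$Fs
    exceed <- exceed + (Fs >= obs$Fs - 1e-12)
  }
  pvals <- (1 + exceed) / (n_perm + 1)

  out <- data.frame(term = c(names(factors), "Residual"),
                    df = c(dfs, df_res),
                    ss = c(obs$ss, obs$ss_res),
                    r_squared = c(obs$ss, obs$ss_res) / ss_total,
                    pseudo_F = c(obs$Fs, NA),
                    p_value = c(pvals, NA),
                    n_permutations = n_perm)
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("Permutational multivariate ANOVA (sequential SS, ",
      x$n_permutations[1], " permutations)\n", sep = "")
  df <- as.data.frame(x)
  df$n_permutations <- NULL
  print(format(df, digits = 4), row.names = FALSE)
  invisible(x)
}
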