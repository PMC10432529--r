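# Internal linear programming for flux-balance problems.
#
# Primary route: boot::simplex (max/min a'x s.t. A1 x <= b1, A2 x >= b2,
# A3 x = b3, x >= 0, b >= 0). FBA problems carry free (possibly negative)
# flux bounds, so variables are shifted by their lower bound and rows are
# sign-flipped as needed. boot::simplex can return solved = 1 with NaN on
# equality rows whose coefficients are all negative, so every solution is
# validated against the constraints and a two-phase dense simplex
# (Bland's rule) takes over whenever the primary route misbehaves.

#' @keywords internal
#' @noRd
solve_lp <- function(obj, mat, dir, rhs, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(ncol(mat) == n, length(dir) == nrow(mat), length(rhs) == nrow(mat),
            length(lb) == n, length(ub) == n)
  if (any(ub < lb)) return(list(status = "infeasible", objval = NA_real_, x = NULL))

  # shift x = v - lb >= 0; fold finite upper bounds in as rows
  rhs2 <- rhs - as.vector(mat %*% lb)
  dir2 <- ifelse(dir %in% c("=", "=="), "=", dir)
  fin <- which(is.finite(ub))
  ub_rows <- matrix(0, length(fin), n)
  ub_rows[cbind(seq_along(fin), fin)] <- 1
  M <- rbind(mat, ub_rows)
  D <- c(dir2, rep("<=", length(fin)))
  B <- c(rhs2, ub[fin] - lb[fin])

  valid <- function(x) {
    if (is.null(x) || any(!is.finite(x))) return(FALSE)
    lhs <- as.vector(M %*% x)
    tol <- 1e-6 * max(1, max(abs(B)))
    all(x >= -tol) &&
      all(abs(lhs - B)[D == "="] <= tol) &&
      all((lhs - B)[D == "<="] <= tol) &&
      all((B - lhs)[D == ">="] <= tol)
  }

  x <- solve_lp_boot(obj, M, D, B, maximize)
  if (!valid(x)) x <- solve_lp_twophase(obj, M, D, B, maximize)
  if (is.character(x)) return(list(status = x, objval = NA_real_, x = NULL))
  if (!valid(x)) return(list(status = "failed", objval = NA_real_, x = NULL))
  v <- x + lb
  list(status = "optimal", objval = sum(obj * v), x = v)
}

# boot::simplex route; returns solution vector or NULL
solve_lp_boot <- function(obj, M, D, B, maximize) {
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL; A3 <- NULL; b3 <- NULL
  for (i in seq_len(nrow(M))) {
    row <- M[i, ]; val <- B[i]; type <- D[i]
    # keep rhs non-negative; also flip all-negative zero-rhs equalities,
    # which trip boot::simplex's phase 1
    if (val < 0 || (type == "=" && val == 0 && sum(row) < 0)) {
      row <- -row; val <- -val
      type <- switch(type, "<=" = ">=", ">=" = "<=", "=" = "=")
    }
    switch(type,
      "<=" = { A1 <- rbind(A1, row); b1 <- c(b1, val) },
      ">=" = { A2 <- rbind(A2, row); b2 <- c(b2, val) },
      "="  = { A3 <- rbind(A3, row); b3 <- c(b3, val) })
  }
  res <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = maximize,
                  n.iter = max(500L, 20L * (length(obj) + nrow(M)))),
    error = function(e) NULL)
  if (is.null(res) || res$solved != 1) return(NULL)
  as.numeric(res$soln)
}

# two-phase dense simplex with Bland's rule; returns solution vector,
# "infeasible", or "unbounded"
solve_lp_twophase <- function(obj, M, D, B, maximize) {
  n <- ncol(M)
  # normalise rhs sign, then append slack/surplus columns
  flip <- B < 0
  M[flip, ] <- -M[flip, , drop = FALSE]
  B[flip] <- -B[flip]
  D[flip] <- ifelse(D[flip] == "<=", ">=", ifelse(D[flip] == ">=", "<=", "="))
  m <- nrow(M)
  slack_cols <- which(D != "=")
  A <- cbind(M, matrix(0, m, length(slack_cols)))
  for (k in seq_along(slack_cols)) {
    i <- slack_cols[k]
    A[i, n + k] <- if (D[i] == "<=") 1 else -1
  }
  ntot <- ncol(A)
  cost <- c(if (maximize) -obj else obj, rep(0, ntot - n))

  # initial basis: slacks where they enter with +1, artificials elsewhere
  basis <- integer(m)
  art <- integer(0)
  for (i in seq_len(m)) {
    j <- if (D[i] == "<=") n + match(i, slack_cols) else NA
    if (!is.na(j)) basis[i] <- j
    else {
      A <- cbind(A, as.numeric(seq_len(m) == i))
      basis[i] <- ncol(A)
      art <- c(art, ncol(A))
    }
  }
  run <- function(A, b, cost, basis, phase1_cols = integer(0)) {
    m <- nrow(A); ntot <- ncol(A)
    Tb <- cbind(A, b)
    # price out the basis
    for (i in seq_len(m)) Tb[i, ] <- Tb[i, ] / Tb[i, basis[i]]
    z <- cost
    zval <- 0
    for (i in seq_len(m)) {
      cb <- cost[basis[i]]
      if (cb != 0) { z <- z - cb * Tb[i, seq_len(ntot)]; zval <- zval - cb * Tb[i, ntot + 1] }
    }
    for (it in seq_len(5000L)) {
      enter <- which(z < -1e-9)
      if (length(enter) == 0) break
      e <- min(enter)                      # Bland
      col <- Tb[, e]
      pos <- which(col > 1e-9)
      if (length(pos) == 0) return("unbounded")
      ratio <- Tb[pos, ntot + 1] / col[pos]
      cand <- pos[ratio <= min(ratio) + 1e-12]
      l <- cand[which.min(basis[cand])]    # Bland on leaving
      piv <- Tb[l, e]
      Tb[l, ] <- Tb[l, ] / piv
      for (i in seq_len(m)) if (i != l && abs(Tb[i, e]) > 1e-12)
        Tb[i, ] <- Tb[i, ] - Tb[i, e] * Tb[l, ]
      zval <- zval - z[e] * Tb[l, ntot + 1]
      z <- z - z[e] * Tb[l, seq_len(ntot)]
      basis[l] <- e
    }
    list(Tb = Tb, basis = basis, zval = zval)
  }

  if (length(art) > 0) {
    c1 <- rep(0, ncol(A)); c1[art] <- 1
    r1 <- run(A, B, c1, basis)
    if (is.character(r1)) return("infeasible")
    x1 <- numeric(ncol(A))
    x1[r1$basis] <- r1$Tb[, ncol(A) + 1]
    if (sum(x1[art]) > 1e-7) return("infeasible")
    # drive artificials out of the basis where possible, then drop them
    Tb <- r1$Tb; basis <- r1$basis
    for (i in which(basis %in% art)) {
      j <- which(abs(Tb[i, seq_len(ntot)]) > 1e-9)
      if (length(j) > 0) {
        e <- j[1]; piv <- Tb[i, e]
        Tb[i, ] <- Tb[i, ] / piv
        for (k in seq_len(m)) if (k != i && abs(Tb[k, e]) > 1e-12)
          Tb[k, ] <- Tb[k, ] - Tb[k, e] * Tb[i, ]
        basis[i] <- e
      }
    }
    keep_rows <- !(basis %in% art)
    A2 <- Tb[keep_rows, seq_len(ntot), drop = FALSE]
    B2 <- Tb[keep_rows, ncol(Tb)]
    basis2 <- basis[keep_rows]
    r2 <- run(A2, B2, cost[seq_len(ntot)], basis2)
  } else {
    r2 <- run(A, B, cost, basis)
  }
  if (is.character(r2)) return(r2)
  x <- numeric(ntot)
  x[r2$basis] <- r2$Tb[, ncol(r2$Tb)]
  x[seq_len(n)]
}
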