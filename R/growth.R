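#' Construct a growth curve
#'
#' @param times observation times in hours, strictly increasing.
#' @param values OD600 or fluorescence readings, finite and non-negative
#'   after blank correction.
#' @param label strain x condition label.
#' @param blank_corrected has the blank already been subtracted?
#'
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(times, values, label = "", blank_corrected = FALSE) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(values))) stop("values must be finite")
  structure(list(times = times, values = values, label = label,
                 blank_corrected = isTRUE(blank_corrected)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("<growth_curve> ", x$label, ": ", length(x$times), " points over [",
      min(x$times), ", ", max(x$times), "] h",
      if (x$blank_corrected) " (blank corrected)", "\n", sep = "")
  invisible(x)
}

#' Subtract a blank (no-carbon) curve from a growth curve
#'
#' Pointwise subtraction of the blank signal; when time grids differ the
#' blank is linearly interpolated onto the curve's grid (its time range must
#' cover the curve). Negative corrected values are clipped to zero.
#'
#' @param curve,blank [growth_curve()] objects.
#' @return A blank-corrected [growth_curve()].
#' @export
blank_correct <- function(curve, blank) {
  if (identical(curve$times, blank$times)) {
    bl <- blank$values
  } else {
    if (min(blank$times) > min(curve$times) ||
        max(blank$times) < max(curve$times))
      stop("blank time range does not cover the curve")
    bl <- stats::approx(blank$times, blank$values, xout = curve$times)$y
  }
  growth_curve(curve$times, pmax(curve$values - bl, 0),
               label = curve$label, blank_corrected = TRUE)
}

# logistic model and its exact integral
logistic_n <- function(t, mu, K, N0) K / (1 + ((K - N0) / N0) * exp(-mu * t))

# \int K/(1+A e^{-mu t}) dt = (K/mu) * [mu t + log1p(A e^{-mu t})] + C
logistic_auc <- function(mu, K, N0, t0, t1) {
  A <- (K - N0) / N0
  prim <- function(t) (K / mu) * (mu * t + log1p(A * exp(-mu * t)))
  prim(t1) - prim(t0)
}

#' Fit a logistic growth model to a curve
#'
#' Least-squares fit of `N(t) = K / (1 + ((K - N0)/N0) exp(-mu t))` via
#' Levenberg-Marquardt. Starting values: `K` from the curve maximum, `N0`
#' from the first positive reading, `mu` from the log-linear slope of the
#' rising segment; `K` is bounded in `(0, 2 max(values)]`. The reported AUC
#' is the analytic integral of the fitted curve over the observed interval
#' (robust to sparse sampling). Flat or all-zero curves return a no-growth
#' fit (`converged = FALSE`, `mu = 0`, `K = 0`) rather than an error.
#'
#' @param curve a blank-corrected [growth_curve()] with at least 4 points.
#'
#' @return An object of class `logistic_fit` with components `mu`, `K`,
#'   `N0`, `auc`, `converged`, `residual_sse`, plus the data for methods.
#' @export
fit_logistic <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  t <- curve$times; v <- curve$values
  if (length(t) < 4) stop("at least 4 points are required for fitting")

  no_growth <- function() {
    structure(list(mu = 0, K = 0, N0 = 0,
                   auc = 0, converged = FALSE,
                   residual_sse = sum(v^2),
                   times = t, values = v, label = curve$label),
              class = "logistic_fit")
  }
  vmax <- max(v)
  if (vmax <= 0 || stats::sd(v) == 0) return(no_growth())

  K0 <- vmax
  N0_0 <- v[v > 0][1]
  # slope of log-values over the rising segment: positive readings up to the
  # first half-maximum crossing (plateau noise must not flatten the slope)
  half <- which(v >= 0.5 * vmax)[1]
  rise <- which(v > 0 & seq_along(v) <= half)
  mu0 <- if (length(rise) >= 2) {
    sl <- stats::coef(stats::lm(log(v[rise]) ~ t[rise]))[2]
    max(as.numeric(sl), 1e-3)
  } else 0.5

  # measurement error in plate readers and fluorescence scales with signal,
  # so residuals are minimised on the log scale whenever the curve is
  # strictly positive; zeros (clipped blanks) force the linear scale
  logspace <- all(v > 0)
  fit_one <- function(m0) {
    frm <- if (logspace)
      log(v) ~ log(K / (1 + ((K - N0) / N0) * exp(-mu * t)))
    else
      v ~ K / (1 + ((K - N0) / N0) * exp(-mu * t))
    tryCatch(
      minpack.lm::nlsLM(
        frm,
        start = list(mu = m0, K = K0, N0 = max(N0_0, 1e-8)),
        lower = c(mu = 1e-8, K = 1e-8, N0 = 1e-10),
        upper = c(mu = Inf, K = 2 * vmax, N0 = vmax),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
  }
  # small multi-start over mu to step around local minima
  best <- NULL
  for (m0 in unique(c(mu0, 0.1, 0.5, 1))) {
    fit <- fit_one(m0)
    if (is.null(fit)) next
    sse_i <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse_i < best$sse - 1e-14) best <- list(fit = fit, sse = sse_i)
  }
  if (is.null(best)) return(no_growth())
  cf <- stats::coef(best$fit)
  sse <- sum((v - logistic_n(t, cf[["mu"]], cf[["K"]], cf[["N0"]]))^2)
  # a "fit" that explains nothing over a flat line is no growth
  if (!is.finite(cf[["K"]]) || cf[["K"]] <= 0) return(no_growth())
  structure(list(mu = unname(cf[["mu"]]), K = unname(cf[["K"]]),
                 N0 = unname(cf[["N0"]]),
                 auc = logistic_auc(cf[["mu"]], cf[["K"]], cf[["N0"]],
                                    min(t), max(t)),
                 converged = TRUE,
                 residual_sse = sse,
                 times = t, values = v, label = curve$label),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<logistic_fit> ", x$label, ": no growth (not converged)\n", sep = "")
  } else {
    cat(sprintf("<logistic_fit> %s: mu = %.4g /h, K = %.4g, N0 = %.3g, AUC = %.4g (SSE %.3g)\n",
                x$label, x$mu, x$K, x$N0, x$auc, x$residual_sse))
  }
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(mu = object$mu, K = object$K, N0 = object$N0)
}

#' @export
predict.logistic_fit <- function(object, times = object$times, ...) {
  if (!object$converged) return(rep(0, length(times)))
  logistic_n(times, object$mu, object$K, object$N0)
}

#' @export
fitted.logistic_fit <- function(object, ...) predict(object)

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$values - fitted(object)
}

#' @export
plot.logistic_fit <- function(x, ...) {
  graphics::plot(x$times, x$values, xlab = "time (h)", ylab = "value",
                 main = x$label, ...)
  if (x$converged) {
    tt <- seq(min(x$times), max(x$times), length.out = 200)
    graphics::lines(tt, predict(x, tt))
  }
  invisible(x)
}

#' Read a long-format plate-reader table
#'
#' Expects columns `time_h`, `well`, `strain`, `condition`, `value` and
#' returns one [growth_curve()] per well.
#'
#' @param path CSV file path.
#' @return Named list of [growth_curve()] objects keyed by well.
#' @export
read_growth_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "well", "strain", "condition", "value")
  if (!all(need %in% names(df)))
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_h), ]
    growth_curve(d$time_h, d$value,
                 label = paste(d$strain[1], d$condition[1], sep = " x "))
  })
}

#' Write logistic fits to CSV
#' @param fits list of `logistic_fit` objects.
#' @param path output CSV path.
#' @export
write_fits_csv <- function(fits, path) {
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(label = f$label, mu = f$mu, K = f$K, N0 = f$N0, auc = f$auc,
               converged = f$converged, residual_sse = f$residual_sse)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
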