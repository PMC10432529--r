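# Multiplicative lognormal noise with unit mean and a given CV keeps
# intensities and optical densities positive, and matches how measurement
# error scales with signal in plate readers and fluorescence imaging.
lognormal_factor <- function(n, cv) {
  if (cv < 0) stop("noise CV must be non-negative")
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a logistic growth curve
#'
#' Noise-free values follow `N(t) = K / (1 + ((K - N0)/N0) exp(-mu t))`;
#' `noise_cv > 0` multiplies each reading by a unit-mean lognormal factor
#' with that coefficient of variation.
#'
#' @param mu per-hour growth rate (> 0).
#' @param K carrying capacity (> N0).
#' @param N0 initial value (0 < N0 < K).
#' @param times strictly increasing sampling times in hours.
#' @param noise_cv multiplicative noise CV (default 0).
#' @param seed integer seed (only consumed when `noise_cv > 0`).
#' @param label curve label.
#'
#' @return A [growth_curve()] with attribute `truth` holding the generating
#'   parameters.
#' @export
sim_logistic_curve <- function(mu, K, N0, times, noise_cv = 0, seed = 1,
                               label = "sim") {
  if (mu <= 0) stop("mu must be positive")
  if (N0 <= 0 || N0 >= K) stop("need 0 < N0 < K")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  v <- logistic_n(times, mu, K, N0)
  if (noise_cv > 0) {
    set.seed(seed)
    v <- v * lognormal_factor(length(v), noise_cv)
  } else if (noise_cv < 0) stop("noise_cv must be non-negative")
  out <- growth_curve(times, v, label = label, blank_corrected = TRUE)
  attr(out, "truth") <- list(mu = mu, K = K, N0 = N0)
  out
}

#' Simulate a fluorescence-dilution (CUSPER) cell population
#'
#' Each founder draws a division count `k` from `division_pmf` (supported on
#' 0..8; the reporter cannot resolve more) and yields `2^k` descendant
#' records whose green intensity is `gfp_mean / 2^k` perturbed by unit-mean
#' lognormal noise of CV `gfp_cv`. Background readings are drawn from a
#' lognormal with mean `bg_mean` and CV `bg_cv`.
#'
#' @param n_founders number of founder cells.
#' @param division_pmf numeric vector of probabilities for 0, 1, ...
#'   divisions (at most 9 entries, summing to 1).
#' @param gfp_mean founder green intensity (a.u., > 0).
#' @param gfp_cv per-cell intensity noise CV.
#' @param bg_mean,bg_cv background intensity distribution.
#' @param n_background number of background readings to draw.
#' @param seed integer seed.
#'
#' @return List with `cells` (data frame `cell_id`, `founder`, `divisions`,
#'   `green`) , `background` (numeric vector) and `truth` (the arguments and
#'   per-founder division counts).
#' @export
sim_cusper_population <- function(n_founders, division_pmf, gfp_mean = 5000,
                                  gfp_cv = 0.05, bg_mean = 100, bg_cv = 0.2,
                                  n_background = 100, seed = 1) {
  if (any(division_pmf < 0) || !isTRUE(all.equal(sum(division_pmf), 1)))
    stop("division_pmf must be non-negative and sum to 1")
  if (length(division_pmf) > 9)
    stop("division counts beyond 8 are not resolvable; pmf too long")
  if (gfp_mean <= 0 || bg_mean <= 0) stop("intensities must be positive")
  set.seed(seed)
  ks <- sample(seq_along(division_pmf) - 1L, n_founders, replace = TRUE,
               prob = division_pmf)
  divisions <- rep(ks, times = 2L^ks)
  founder <- rep(seq_len(n_founders), times = 2L^ks)
  green <- gfp_mean / 2^divisions *
    lognormal_factor(length(divisions), gfp_cv)
  bg <- bg_mean * lognormal_factor(n_background, bg_cv)
  list(cells = data.frame(cell_id = seq_along(divisions),
                          founder = founder,
                          divisions = divisions,
                          green = green),
       background = bg,
       truth = list(n_founders = n_founders, division_pmf = division_pmf,
                    gfp_mean = gfp_mean, gfp_cv = gfp_cv,
                    founder_divisions = ks))
}

#' Simulate a two-channel fluorescence microscopy scene
#'
#' Plants axis-aligned ellipses of given areas on a Gaussian background:
#' the red channel carries the constitutive cell marker used for
#' segmentation, the green channel the per-cell reporter intensities on its
#' own background. Cells overlapping the image border are flagged in the
#' ground truth so edge-exclusion behaviour can be checked.
#'
#' @param cells data frame with columns `row`, `col` (centre, pixels),
#'   `area_um2`, `green` and optionally `red` (default `red_level`) and
#'   `aspect` (major/minor axis ratio, default 1.6); `NULL` places
#'   `n_cells` non-overlapping cells at random.
#' @param n_cells number of random cells when `cells` is `NULL`.
#' @param shape image dimensions `c(rows, cols)` in pixels.
#' @param pixel_size um per pixel (default 0.1).
#' @param area_range sampled cell area range in um^2 for random scenes.
#' @param red_level red intensity painted on cell pixels.
#' @param green_range sampled green intensity range for random scenes.
#' @param bg_level,bg_sd background mean and SD (both channels).
#' @param noise_sd Gaussian noise SD added to cell pixels.
#' @param seed integer seed.
#'
#' @return List with integer matrices `red`, `green` and `truth`, a data
#'   frame of planted cells (`row`, `col`, `area_um2`, `area_px`, `red`,
#'   `green`, `touches_edge`).
#' @export
sim_cell_image <- function(cells = NULL, n_cells = 10, shape = c(128, 128),
                           pixel_size = 0.1, area_range = c(0.8, 2.2),
                           red_level = 10000, green_range = c(500, 5000),
                           bg_level = 200, bg_sd = 30, noise_sd = 50,
                           seed = 1) {
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  if (is.null(cells)) {
    cells <- place_random_cells(n_cells, nr, nc, pixel_size, area_range,
                                red_level, green_range)
  }
  if (is.null(cells$red)) cells$red <- rep(red_level, nrow(cells))
  if (is.null(cells$aspect)) cells$aspect <- rep(1.6, nrow(cells))
  red <- matrix(stats::rnorm(nr * nc, bg_level, bg_sd), nr, nc)
  green <- matrix(stats::rnorm(nr * nc, bg_level, bg_sd), nr, nc)
  truth <- cells
  truth$area_px <- integer(nrow(cells))
  truth$touches_edge <- logical(nrow(cells))
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (i in seq_len(nrow(cells))) {
    area_px <- cells$area_um2[i] / pixel_size^2
    rx <- sqrt(area_px * cells$aspect[i] / pi)  # semi-axis along rows
    ry <- area_px / (pi * rx)
    m <- ((rows - cells$row[i]) / rx)^2 + ((cols - cells$col[i]) / ry)^2 <= 1
    truth$area_px[i] <- sum(m)
    truth$touches_edge[i] <- any(m[1, ]) || any(m[nr, ]) ||
      any(m[, 1]) || any(m[, nc])
    red[m] <- cells$red[i] + stats::rnorm(sum(m), 0, noise_sd)
    green[m] <- cells$green[i] + stats::rnorm(sum(m), 0, noise_sd)
  }
  truth$area_um2_px <- truth$area_px * pixel_size^2
  clip16 <- function(m) matrix(pmin(pmax(round(m), 0), 65535), nrow(m))
  list(red = clip16(red), green = clip16(green), truth = truth,
       pixel_size = pixel_size, bg_level = bg_level)
}

# rejection placement of non-overlapping ellipse centres away from other cells
place_random_cells <- function(n_cells, nr, nc, pixel_size, area_range,
                               red_level, green_range) {
  max_r <- sqrt(max(area_range) / pixel_size^2 * 1.6 / pi) + 2
  out <- NULL
  tries <- 0
  while (is.null(out) || nrow(out) < n_cells) {
    tries <- tries + 1
    if (tries > 10000) stop("could not place non-overlapping cells")
    row <- stats::runif(1, max_r + 1, nr - max_r)
    col <- stats::runif(1, max_r + 1, nc - max_r)
    if (!is.null(out) &&
        any((out$row - row)^2 + (out$col - col)^2 < (2.2 * max_r)^2)) next
    out <- rbind(out, data.frame(
      row = row, col = col,
      area_um2 = stats::runif(1, area_range[1], area_range[2]),
      green = stats::runif(1, green_range[1], green_range[2]),
      red = red_level))
  }
  out
}

#' Write simulated growth curves or cell records as CSV
#'
#' @param curves named list of [growth_curve()] objects (names become well
#'   ids).
#' @param path output CSV.
#' @param strain,condition metadata columns for the long-format table.
#' @export
write_growth_table <- function(curves, path, strain = names(curves),
                               condition = "sim") {
  if (is.null(names(curves))) names(curves) <- paste0("W", seq_along(curves))
  condition <- rep_len(condition, length(curves))
  strain <- rep_len(strain, length(curves))
  df <- do.call(rbind, Map(function(cu, w, s, cond)
    data.frame(time_h = cu$times, well = w, strain = s, condition = cond,
               value = cu$values),
    curves, names(curves), strain, condition))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
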