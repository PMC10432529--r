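#' Intermodes histogram threshold
#'
#' Iteratively smooths a 256-bin histogram with a 3-bin mean filter
#' (replicated ends) until exactly two local maxima remain, then returns the
#' floor of the midpoint between the two modes (bins are indexed 0..255).
#' Histograms that never become bimodal (flat or unimodal) raise an error
#' after `max_iter` smoothing passes; the caller may fall back to a fixed
#' threshold.
#'
#' @param histogram numeric vector of 256 non-negative counts.
#' @param max_iter maximum smoothing iterations (default 10000).
#'
#' @return Integer threshold bin in 0..255.
#' @export
intermodes_threshold <- function(histogram, max_iter = 10000) {
  if (length(histogram) != 256) stop("histogram must have 256 bins")
  if (sum(histogram) == 0) stop("histogram is empty")
  h <- as.numeric(histogram)
  n_modes <- function(h) {
    left <- c(h[1], h[-256]); right <- c(h[-1], h[256])
    sum(h > left & h >= right)
  }
  it <- 0
  while (n_modes(h) != 2) {
    h <- (c(h[1], h[-256]) + h + c(h[-1], h[256])) / 3
    it <- it + 1
    if (it > max_iter)
      stop("histogram never became bimodal after ", max_iter, " iterations")
  }
  left <- c(h[1], h[-256]); right <- c(h[-1], h[256])
  modes <- which(h > left & h >= right) - 1L   # 0-based bins
  as.integer(floor((modes[1] + modes[2]) / 2))
}

# 8-connected component labelling by label propagation; mask is logical
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    r_src <- max(1, 1 - dr):min(nr, nr - dr)
    c_src <- max(1, 1 - dc):min(nc, nc - dc)
    out[r_src + dr, c_src + dc] <- m[r_src, c_src]
    out
  }
  repeat {
    nb <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      s <- shift(lab, dr, dc)
      nb <- pmax(nb, s)
    }
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  # relabel to 1..k
  ids <- sort(unique(lab[lab > 0]))
  lab[] <- match(lab, c(0L, ids)) - 1L
  lab
}

#' Segment cells in the red channel
#'
#' Thresholds the red channel with the intermodes method on a 256-bin
#' histogram scaled over the image's intensity range, labels 8-connected
#' components, and keeps only components whose area (in um^2, via
#' `pixel_size^2`) lies in `[min_area, max_area]` and that do not touch the
#' image border.
#'
#' @param red numeric matrix of red-channel intensities.
#' @param pixel_size physical pixel edge in um/px (default 0.045; set to the
#'   calibration of your optics).
#' @param min_area,max_area retained area range in um^2 (defaults 0.5 and
#'   2.5).
#' @param fallback_threshold intensity cutoff used if the histogram never
#'   becomes bimodal (`NULL` propagates the error).
#'
#' @return List of class `segmented_cells`: `labels` (matrix, 0 =
#'   background), `cells` (data frame `label`, `area_um2`, `centroid_row`,
#'   `centroid_col`, `touches_edge`, `mean_red`), `threshold` (intensity
#'   units), `pixel_size`.
#' @export
segment_cells <- function(red, pixel_size = 0.045, min_area = 0.5,
                          max_area = 2.5, fallback_threshold = NULL) {
  rng <- range(red)
  if (diff(rng) == 0) stop("red channel is constant; nothing to segment")
  bins <- pmin(floor((red - rng[1]) / diff(rng) * 256), 255)
  h <- tabulate(as.integer(bins) + 1L, nbins = 256)
  tbin <- tryCatch(intermodes_threshold(h), error = function(e) {
    if (is.null(fallback_threshold)) stop(e)
    NA_integer_
  })
  thr <- if (is.na(tbin)) fallback_threshold else
    rng[1] + (tbin + 0.5) / 256 * diff(rng)
  mask <- red > thr
  lab <- label_components(mask)
  k <- max(lab)
  keep <- integer(0)
  cells <- NULL
  if (k > 0) {
    px_area <- pixel_size^2
    idx <- which(lab > 0, arr.ind = TRUE)
    labs <- lab[lab > 0]
    area_px <- tabulate(labs, nbins = k)
    cr <- tapply(idx[, 1], labs, mean)
    cc <- tapply(idx[, 2], labs, mean)
    edge <- vapply(seq_len(k), function(l) {
      p <- idx[labs == l, , drop = FALSE]
      any(p[, 1] %in% c(1, nrow(red))) || any(p[, 2] %in% c(1, ncol(red)))
    }, logical(1))
    mean_red <- vapply(seq_len(k), function(l) mean(red[lab == l]), numeric(1))
    area_um2 <- area_px * px_area
    keep <- which(area_um2 >= min_area & area_um2 <= max_area & !edge)
    cells <- data.frame(label = keep,
                        area_um2 = area_um2[keep],
                        centroid_row = as.numeric(cr[keep]),
                        centroid_col = as.numeric(cc[keep]),
                        touches_edge = rep(FALSE, length(keep)),
                        mean_red = mean_red[keep])
    lab[!(lab %in% keep)] <- 0L
  } else {
    cells <- data.frame(label = integer(0), area_um2 = numeric(0),
                        centroid_row = numeric(0), centroid_col = numeric(0),
                        touches_edge = logical(0), mean_red = numeric(0))
  }
  structure(list(labels = lab, cells = cells, threshold = thr,
                 pixel_size = pixel_size),
            class = "segmented_cells")
}

#' @export
print.segmented_cells <- function(x, ...) {
  cat("<segmented_cells> ", nrow(x$cells), " retained cell(s), threshold ",
      signif(x$threshold, 5), ", pixel ", x$pixel_size, " um\n", sep = "")
  invisible(x)
}

#' Measure per-cell green fluorescence through a segmentation mask
#'
#' @param seg a [segment_cells()] result.
#' @param green green-channel matrix, same dimensions as the mask.
#' @param fov field-of-view label attached to the records.
#'
#' @return Data frame of cell records: `cell_id`, `fov`, `red`, `green`
#'   (mean intensities over the mask), `area_um2`.
#' @export
measure_green <- function(seg, green, fov = 1) {
  if (!all(dim(green) == dim(seg$labels)))
    stop("green channel and mask dimensions differ")
  cells <- seg$cells
  if (nrow(cells) == 0)
    return(data.frame(cell_id = character(0), fov = character(0),
                      red = numeric(0), green = numeric(0),
                      area_um2 = numeric(0)))
  g <- vapply(cells$label, function(l) mean(green[seg$labels == l]),
              numeric(1))
  data.frame(cell_id = paste0(fov, "_", cells$label), fov = as.character(fov),
             red = cells$mean_red, green = g, area_um2 = cells$area_um2)
}

#' Sample background intensity from a cell-free patch
#'
#' Picks one randomly placed square patch containing no mask pixels and
#' returns its mean intensity. Deterministic for a fixed seed.
#'
#' @param green green-channel matrix.
#' @param seg a [segment_cells()] result (its mask defines occupied pixels);
#'   `NULL` treats the whole image as background.
#' @param patch patch edge length in pixels (default 16).
#' @param seed integer seed.
#' @param max_tries placement attempts before giving up.
#'
#' @return Mean background intensity of the sampled patch.
#' @export
sample_background <- function(green, seg = NULL, patch = 16, seed = 1,
                              max_tries = 1000) {
  nr <- nrow(green); nc <- ncol(green)
  if (patch > nr || patch > nc) stop("patch larger than the image")
  occupied <- if (is.null(seg)) matrix(FALSE, nr, nc) else seg$labels > 0
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    r0 <- sample.int(nr - patch + 1, 1)
    c0 <- sample.int(nc - patch + 1, 1)
    rows <- r0:(r0 + patch - 1); cols <- c0:(c0 + patch - 1)
    if (!any(occupied[rows, cols])) return(mean(green[rows, cols]))
  }
  stop("no mask-free patch of size ", patch, " found")
}

#' Read and write two-channel 16-bit TIFF images
#'
#' The on-disk form is a multi-directory TIFF with the red channel first and
#' the green channel second, 16 bits per sample.
#'
#' @param img list with integer matrices `red` and `green` (0..65535).
#' @param path file path.
#' @return `read_cell_image()` returns a list with `red` and `green`
#'   matrices.
#' @export
write_cell_image <- function(img, path) {
  stopifnot(is.list(img), all(c("red", "green") %in% names(img)))
  scaled <- lapply(img[c("red", "green")], function(m) {
    if (any(m < 0 | m > 65535)) stop("intensities outside the 16-bit range")
    m / 65535
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_cell_image
#' @export
read_cell_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a two-channel TIFF")
  list(red = round(pages[[1]] * 65535),
       green = round(pages[[2]] * 65535))
}
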