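#' Fluorescence line profile along a cell perimeter
#'
#' Intensity samples along a polyline drawn around the periphery of a
#' PNN-bearing cell. For a closed profile the first and last samples are
#' treated as adjacent and `perimeter` is the total path length (wrapping
#' past the last sample back to the first).
#'
#' @param pos_um positions along the path (um), strictly increasing.
#' @param intensity fluorescence intensities (au), non-negative.
#' @param closed logical; does the path wrap around the perimeter?
#' @param perimeter total path length for closed profiles (um); defaults to
#'   the last position plus the median sample spacing.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(pos_um, intensity, closed = TRUE, perimeter = NULL) {
  stopifnot(length(pos_um) == length(intensity), length(pos_um) > 0,
            !is.unsorted(pos_um, strictly = TRUE), all(intensity >= 0))
  if (is.null(perimeter)) {
    dx <- if (length(pos_um) > 1) median(diff(pos_um)) else 1
    perimeter <- pos_um[length(pos_um)] - pos_um[1] + dx
  }
  structure(list(pos_um = as.numeric(pos_um),
                 intensity = as.numeric(intensity),
                 closed = isTRUE(closed), perimeter = perimeter),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("Line profile: %d samples over %.1f um (%s), intensity [%.0f, %.0f] au\n",
              length(x$pos_um), x$perimeter,
              if (x$closed) "closed" else "open",
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Peak-counting threshold for a line profile
#'
#' The threshold separating PNN-covered stretches from holes: a fraction
#' (default 50%) of the highest fluorescence intensity of the profile.
#'
#' @param profile a [line_profile()].
#' @param frac fraction of the maximum (default 0.5).
#' @return Threshold (au), with attribute `degenerate` set when the profile
#'   is all zero.
#' @export
profile_threshold <- function(profile, frac = 0.5) {
  stopifnot(inherits(profile, "line_profile"), frac > 0, frac <= 1)
  m <- max(profile$intensity)
  out <- frac * m
  attr(out, "degenerate") <- m == 0
  out
}

#' Count supra-threshold WFA peaks and measure PNN holes
#'
#' Counts strict local intensity maxima above the threshold along the
#' profile, enforcing a minimum peak separation (the taller peak wins), and
#' measures the hole sizes as arc distances between consecutive qualifying
#' peaks. On a closed path peaks wrap around, so there are as many holes as
#' peaks; on an open path one fewer. A profile with many peaks and small
#' holes indicates an intact PNN lattice; few peaks with large holes
#' indicate a degraded net.
#'
#' Before peak detection the profile is lightly smoothed with a centered
#' moving average of width `smooth_um` (circular on closed paths), a
#' deterministic surrogate for the visual averaging a manual counter
#' applies. When `threshold` is not supplied it is taken as half the
#' maximum of the smoothed trace, and a degeneracy guard rejects profiles
#' whose threshold does not clear the trace minimum by at least
#' `min_contrast` noise standard deviations (noise estimated robustly from
#' successive sample differences): such a profile is statistically flat
#' and is reported as having no peaks.
#'
#' @param profile a [line_profile()].
#' @param threshold intensity threshold (au); half the smoothed maximum
#'   when `NULL`. An explicit threshold disables the degeneracy guard.
#' @param min_sep_um minimum peak separation (um); default one bump
#'   full-width-at-half-maximum of the typical PNN-lattice node.
#' @param smooth_um moving-average window (um); 0 disables smoothing.
#' @param min_contrast degeneracy guard, in noise SDs (see above).
#' @return An object of class `pnn_integrity`: list with `threshold`,
#'   `peak_count`, `peak_positions` (um), `hole_sizes` (um) and logical
#'   `degenerate`.
#' @export
count_wfa_peaks <- function(profile, threshold = NULL, min_sep_um = 0.8,
                            smooth_um = 0.5, min_contrast = 3) {
  stopifnot(inherits(profile, "line_profile"))
  raw <- profile$intensity
  v <- raw
  n <- length(v)
  k <- 1L
  if (smooth_um > 0 && n > 3) {
    dx <- median(diff(profile$pos_um))
    k <- max(1L, round(smooth_um / dx))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1) {
      kern <- rep(1 / k, k)
      v <- if (profile$closed) {
        pad <- (k - 1) / 2
        vv <- c(v[(n - pad + 1):n], v, v[1:pad])
        as.numeric(stats::filter(vv, kern, sides = 2))[(pad + 1):(pad + n)]
      } else {
        sm <- as.numeric(stats::filter(v, kern, sides = 2))
        ifelse(is.na(sm), v, sm)
      }
    }
  }
  degenerate <- FALSE
  if (is.null(threshold)) {
    threshold <- 0.5 * max(v)
    # robust noise scale of the raw samples, scaled to the smoothed trace
    sigma_raw <- 1.4826 * median(abs(diff(raw))) / sqrt(2)
    sigma_sm <- sigma_raw / sqrt(k)
    if (threshold <= min(v) + min_contrast * sigma_sm) {
      degenerate <- TRUE
      return(structure(list(threshold = as.numeric(threshold),
                            peak_count = 0L, peak_positions = numeric(0),
                            hole_sizes = numeric(0), degenerate = TRUE),
                       class = "pnn_integrity"))
    }
  }
  stopifnot(threshold >= 0)
  if (profile$closed && n >= 3) {
    vprev <- v[c(n, 1:(n - 1))]
    vnext <- v[c(2:n, 1)]
    idx <- which(v > vprev & v > vnext)
  } else {
    idx <- .local_maxima(v)
  }
  idx <- idx[v[idx] > threshold]
  if (length(idx) > 1) {
    gap_fun <- if (profile$closed) {
      L <- profile$perimeter
      function(a, b) pmin(abs(a - b), L - abs(a - b))
    } else function(a, b) abs(a - b)
    pos <- profile$pos_um[idx]
    ord <- order(v[idx], decreasing = TRUE)
    acc <- logical(length(idx))
    for (k in ord) {
      if (!any(acc & gap_fun(pos, pos[k]) < min_sep_um)) acc[k] <- TRUE
    }
    idx <- sort(idx[acc])
  }
  peaks <- profile$pos_um[idx]
  holes <- if (length(peaks) >= 2) {
    h <- diff(peaks)
    if (profile$closed)
      c(h, profile$perimeter - (peaks[length(peaks)] - peaks[1]))
    else h
  } else if (length(peaks) == 1 && profile$closed) {
    profile$perimeter
  } else numeric(0)
  structure(list(threshold = as.numeric(threshold),
                 peak_count = length(peaks), peak_positions = peaks,
                 hole_sizes = holes, degenerate = degenerate),
            class = "pnn_integrity")
}

#' @export
print.pnn_integrity <- function(x, ...) {
  cat(sprintf("PNN integrity: %d peaks above %.1f au", x$peak_count, x$threshold))
  if (length(x$hole_sizes))
    cat(sprintf(", holes %.2f-%.2f um (median %.2f)", min(x$hole_sizes),
                max(x$hole_sizes), median(x$hole_sizes)))
  cat("\n")
  invisible(x)
}

# fractional overlap of pixel intervals [i-1, i) * px with [lo, hi), per index
.pixel_overlap <- function(n, px, lo, hi) {
  starts <- (seq_len(n) - 1) * px
  pmax(0, pmin(starts + px, hi) - pmax(starts, lo)) / px
}

#' Mean fluorescence intensity inside square ROIs
#'
#' Area-weighted mean pixel intensity of each square region of interest and
#' their pooled (ROI-averaged) mean; pixels partially covered by an ROI
#' contribute in proportion to the covered area. This mirrors averaging
#' 4-6 randomly placed 15 um x 15 um (IHC) or 20 um x 20 um (zymography)
#' ROIs per slice.
#'
#' @param image numeric matrix (rows = y, cols = x), single channel.
#' @param centers data.frame with `x_um`, `y_um` ROI centers.
#' @param side_um ROI side length (um).
#' @param px_um pixel size (um/px).
#' @return List with `roi_means` (au, one per ROI) and `pooled_mean`.
#' @export
roi_mean_intensity <- function(image, centers, side_um, px_um) {
  stopifnot(is.matrix(image), side_um > 0, px_um > 0,
            all(c("x_um", "y_um") %in% names(centers)))
  W <- ncol(image) * px_um
  H <- nrow(image) * px_um
  roi_means <- vapply(seq_len(nrow(centers)), function(k) {
    x0 <- centers$x_um[k] - side_um / 2; x1 <- centers$x_um[k] + side_um / 2
    y0 <- centers$y_um[k] - side_um / 2; y1 <- centers$y_um[k] + side_um / 2
    if (x0 < 0 || y0 < 0 || x1 > W || y1 > H)
      stop(sprintf("ROI %d extends outside the image", k))
    wx <- .pixel_overlap(ncol(image), px_um, x0, x1)
    wy <- .pixel_overlap(nrow(image), px_um, y0, y1)
    w <- outer(wy, wx)
    sum(w * image) / sum(w)
  }, numeric(1))
  list(roi_means = roi_means, pooled_mean = mean(roi_means))
}

# min distance from points (px, py) to a polyline, plus the sign of the side
# (positive = left of the directed polyline at the nearest segment)
.dist_to_polyline <- function(px, py, poly) {
  nseg <- nrow(poly) - 1
  stopifnot(nseg >= 1)
  best <- rep(Inf, length(px))
  side <- rep(0, length(px))
  for (s in seq_len(nseg)) {
    ax <- poly$x_um[s]; ay <- poly$y_um[s]
    bx <- poly$x_um[s + 1]; by <- poly$y_um[s + 1]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    qx <- ax + t * dx; qy <- ay + t * dy
    d <- sqrt((px - qx)^2 + (py - qy)^2)
    cross <- dx * (py - ay) - dy * (px - ax)
    upd <- d < best
    best[upd] <- d[upd]
    side[upd] <- sign(cross[upd])
  }
  list(dist = best, side = side)
}

#' Distance-binned mean intensity from a tumor border
#'
#' Assigns every pixel its distance to the tumor-border polyline, keeps the
#' parenchymal side, partitions it into annular distance bins (200 um by
#' default), and averages `n_rois` randomly placed square ROIs per bin
#' (seeded, so placements are reproducible). Mirrors drawing concentric
#' rings at every 200 um from the glioma border and averaging 3-5 ROIs of
#' 20 um x 20 um per ring.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param border data.frame polyline with `x_um`, `y_um`.
#' @param px_um pixel size (um/px).
#' @param bin_um bin width (um).
#' @param n_bins number of distance bins.
#' @param roi_side_um ROI side (um).
#' @param n_rois ROIs per bin.
#' @param seed RNG seed for ROI placement.
#' @param parenchyma_side +1 if the parenchyma lies left of the directed
#'   border polyline, -1 for right.
#' @return data.frame with `bin_lo_um`, `bin_hi_um`, `mean_au`, `n_rois`
#'   and logical `empty` for bins where no ROI could be placed.
#' @export
radial_bin_intensity <- function(image, border, px_um, bin_um = 200,
                                 n_bins = 3, roi_side_um = 20, n_rois = 4,
                                 seed = 1, parenchyma_side = -1) {
  stopifnot(is.matrix(image), px_um > 0, bin_um > 0, n_bins >= 1,
            parenchyma_side %in% c(-1, 1))
  if (max(border$x_um) > ncol(image) * px_um || max(border$y_um) > nrow(image) * px_um ||
      min(border$x_um) < 0 || min(border$y_um) < 0)
    stop("border polyline outside image bounds")
  old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)

  # distance of pixel centers on the parenchymal side
  xs <- (seq_len(ncol(image)) - 0.5) * px_um
  ys <- (seq_len(nrow(image)) - 0.5) * px_um
  g <- expand.grid(y = ys, x = xs)
  dd <- .dist_to_polyline(g$x, g$y, border)
  dist_px <- ifelse(dd$side == parenchyma_side, dd$dist, NA_real_)

  half <- roi_side_um / 2
  W <- ncol(image) * px_um; H <- nrow(image) * px_um
  out <- lapply(seq_len(n_bins), function(b) {
    lo <- (b - 1) * bin_um; hi <- b * bin_um
    # keep the whole ROI inside its ring: centers at least half a side
    # from both ring edges (falling back to the bare ring if too narrow)
    ok <- which(!is.na(dist_px) & dist_px >= lo + half & dist_px < hi - half &
                  g$x >= half & g$x <= W - half &
                  g$y >= half & g$y <= H - half)
    if (!length(ok))
      ok <- which(!is.na(dist_px) & dist_px >= lo & dist_px < hi &
                    g$x >= half & g$x <= W - half &
                    g$y >= half & g$y <= H - half)
    if (!length(ok))
      return(data.frame(bin_lo_um = lo, bin_hi_um = hi, mean_au = NA_real_,
                        n_rois = 0L, empty = TRUE))
    pick <- ok[sample.int(length(ok), min(n_rois, length(ok)),
                          replace = length(ok) < n_rois)]
    centers <- data.frame(x_um = g$x[pick], y_um = g$y[pick])
    m <- roi_mean_intensity(image, centers, roi_side_um, px_um)
    data.frame(bin_lo_um = lo, bin_hi_um = hi, mean_au = m$pooled_mean,
               n_rois = length(pick), empty = FALSE)
  })
  do.call(rbind, out)
}
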