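#' Marker-labelled cell coordinate map
#'
#' Cell coordinates with NeuN/PV/WFA marker flags, the bounds of the imaged
#' field, and an optional tumor-border polyline (absent for sham tissue).
#'
#' @param cells data.frame with `x_um`, `y_um` and 0/1 (or logical) marker
#'   columns `neun`, `pv`, `wfa`; an optional `layer` column may carry
#'   cortical layer labels.
#' @param bounds numeric `c(xmin, xmax, ymin, ymax)` (um).
#' @param border data.frame polyline (`x_um`, `y_um`) or `NULL` for sham.
#' @param tumor_side +1 if the tumor lies left of the directed border
#'   polyline, -1 for right. Ignored when `border` is `NULL`.
#' @return An object of class `cell_map`.
#' @export
cell_map <- function(cells, bounds, border = NULL, tumor_side = 1) {
  stopifnot(all(c("x_um", "y_um", "neun", "pv", "wfa") %in% names(cells)),
            length(bounds) == 4, bounds[2] > bounds[1], bounds[4] > bounds[3],
            tumor_side %in% c(-1, 1))
  if (nrow(cells)) {
    stopifnot(all(cells$x_um >= bounds[1] & cells$x_um <= bounds[2]),
              all(cells$y_um >= bounds[3] & cells$y_um <= bounds[4]))
    if (any(!(cells$neun | cells$pv | cells$wfa)))
      stop("every cell must carry at least one marker flag")
  }
  structure(list(cells = cells, bounds = bounds, border = border,
                 tumor_side = tumor_side),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("Cell map: %d cells (NeuN %d, PV %d, WFA %d) in %g x %g um field%s\n",
              nrow(x$cells), sum(x$cells$neun), sum(x$cells$pv),
              sum(x$cells$wfa), x$bounds[2] - x$bounds[1],
              x$bounds[4] - x$bounds[3],
              if (is.null(x$border)) " (sham, no border)" else ""))
  invisible(x)
}

# does segment a-b intersect the axis-aligned rectangle [x0,x1]x[y0,y1]?
.seg_hits_rect <- function(ax, ay, bx, by, x0, x1, y0, y1) {
  # quick accept: an endpoint inside
  if ((ax >= x0 && ax <= x1 && ay >= y0 && ay <= y1) ||
      (bx >= x0 && bx <= x1 && by >= y0 && by <= y1)) return(TRUE)
  # parametric clipping (Liang-Barsky)
  dx <- bx - ax; dy <- by - ay
  t0 <- 0; t1 <- 1
  for (pq in list(c(-dx, ax - x0), c(dx, x1 - ax), c(-dy, ay - y0), c(dy, y1 - ay))) {
    p <- pq[1]; q <- pq[2]
    if (p == 0) { if (q < 0) return(FALSE) } else {
      r <- q / p
      if (p < 0) { if (r > t1) return(FALSE); if (r > t0) t0 <- r }
      else       { if (r < t0) return(FALSE); if (r < t1) t1 <- r }
    }
  }
  TRUE
}

#' Partition a field into 100 um boxes and label them by tumor distance
#'
#' Draws a grid of square boxes over the field, labels each box `tumor`,
#' `border` or `parenchyma`, and assigns each parenchymal box its distance
#' from the tumor: the Chebyshev number of box steps to the nearest border
#' box times the box size (so the first box column off the border is at
#' 0.1 mm). Border boxes are those the border polyline passes through -
#' the boxes containing both glioma mass and brain parenchyma. For a sham
#' map (no border) every box is parenchyma with distance `NA`.
#'
#' @param map a [cell_map()].
#' @param box_um box side (um).
#' @return An object of class `box_grid`: data.frame with box corner
#'   coordinates `x0`, `y0` (um), `label`, `steps` (box steps from the
#'   border) and `dist_mm`.
#' @export
grid_boxes <- function(map, box_um = 100) {
  stopifnot(inherits(map, "cell_map"), box_um > 0)
  b <- map$bounds
  nx <- floor((b[2] - b[1]) / box_um)
  ny <- floor((b[4] - b[3]) / box_um)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  g$x0 <- b[1] + (g$ix - 1) * box_um
  g$y0 <- b[3] + (g$iy - 1) * box_um

  if (is.null(map$border)) {
    g$label <- "parenchyma"
    g$steps <- NA_integer_
    g$dist_mm <- NA_real_
  } else {
    poly <- map$border
    if (max(poly$x_um) > b[2] || min(poly$x_um) < b[1] ||
        max(poly$y_um) > b[4] || min(poly$y_um) < b[3])
      stop("border polyline outside field bounds")
    nseg <- nrow(poly) - 1
    is_border <- vapply(seq_len(nrow(g)), function(k) {
      any(vapply(seq_len(nseg), function(s)
        .seg_hits_rect(poly$x_um[s], poly$y_um[s],
                       poly$x_um[s + 1], poly$y_um[s + 1],
                       g$x0[k], g$x0[k] + box_um, g$y0[k], g$y0[k] + box_um),
        logical(1)))
    }, logical(1))
    cx <- g$x0 + box_um / 2; cy <- g$y0 + box_um / 2
    dd <- .dist_to_polyline(cx, cy, poly)
    g$label <- ifelse(is_border, "border",
                      ifelse(dd$side == map$tumor_side, "tumor", "parenchyma"))
    bi <- which(g$label == "border")
    if (!length(bi)) stop("border polyline produced no border boxes")
    g$steps <- NA_integer_
    pj <- which(g$label == "parenchyma")
    if (length(pj)) {
      g$steps[pj] <- vapply(pj, function(k)
        min(pmax(abs(g$ix[k] - g$ix[bi]), abs(g$iy[k] - g$iy[bi]))), numeric(1))
    }
    g$dist_mm <- g$steps * box_um / 1000
  }
  structure(g, class = c("box_grid", "data.frame"),
            box_um = box_um, bounds = b)
}

#' Cell density per distance bin
#'
#' Counts marker-positive cells per box (half-open box membership, so each
#' cell lands in exactly one box) and averages the per-box counts within
#' each distance bin, giving the mean density per 0.01 mm^2 when boxes are
#' 100 um. For sham maps (no border) all parenchymal boxes pool into a
#' single `overall` bin. Optionally subsamples a fixed number of boxes per
#' bin (seeded) to mimic the 3-5 boxes scored per slice.
#'
#' @param map a [cell_map()].
#' @param grid a [grid_boxes()] result for `map`.
#' @param marker one of `"neun"`, `"pv"`, `"wfa"`.
#' @param bins matrix-like data.frame with `lo_mm`, `hi_mm` distance bins;
#'   default the three printed bins 0-0.2, 0.2-0.4, 0.4-0.6 mm.
#' @param subsample optional number of boxes to draw per bin (e.g. 3-5).
#' @param seed RNG seed for subsampling.
#' @return An object of class `density_profile`: data.frame with `marker`,
#'   `bin`, `lo_mm`, `hi_mm`, `mean_density` (cells per box area) and
#'   `n_boxes`; empty bins are flagged with `n_boxes = 0` and `NA` density.
#' @export
density_per_bin <- function(map, grid, marker = c("neun", "pv", "wfa"),
                            bins = NULL, subsample = NULL, seed = 1) {
  marker <- match.arg(marker)
  stopifnot(inherits(map, "cell_map"), inherits(grid, "box_grid"))
  grid <- box_counts(map, grid, marker)

  par_boxes <- grid[grid$label == "parenchyma", , drop = FALSE]
  if (is.null(map$border)) {
    rows <- list(data.frame(bin = "overall", lo_mm = NA_real_, hi_mm = NA_real_,
                            boxes = I(list(par_boxes))))
  } else {
    if (is.null(bins))
      bins <- data.frame(lo_mm = c(0, 0.2, 0.4), hi_mm = c(0.2, 0.4, 0.6))
    rows <- lapply(seq_len(nrow(bins)), function(k) {
      sel <- par_boxes[!is.na(par_boxes$dist_mm) &
                         par_boxes$dist_mm > bins$lo_mm[k] &
                         par_boxes$dist_mm <= bins$hi_mm[k], , drop = FALSE]
      data.frame(bin = sprintf("%.1f-%.1f", bins$lo_mm[k], bins$hi_mm[k]),
                 lo_mm = bins$lo_mm[k], hi_mm = bins$hi_mm[k],
                 boxes = I(list(sel)))
    })
  }
  if (!is.null(subsample)) {
    old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
  }
  out <- lapply(rows, function(r) {
    bx <- r$boxes[[1]]
    if (!is.null(subsample) && nrow(bx) > subsample)
      bx <- bx[sample.int(nrow(bx), subsample), , drop = FALSE]
    data.frame(marker = marker, bin = r$bin, lo_mm = r$lo_mm, hi_mm = r$hi_mm,
               mean_density = if (nrow(bx)) mean(bx$count) else NA_real_,
               n_boxes = nrow(bx))
  })
  structure(do.call(rbind, out), class = c("density_profile", "data.frame"))
}

#' Per-box marker-positive cell counts
#'
#' Assigns every marker-positive cell to exactly one grid box by the
#' half-open convention (x in `[x0, x0 + box)`, likewise y), so the counts
#' over all boxes sum to the number of marker-positive cells with no
#' double counting.
#'
#' @inheritParams density_per_bin
#' @return The grid with an added integer `count` column.
#' @export
box_counts <- function(map, grid, marker = c("neun", "pv", "wfa")) {
  marker <- match.arg(marker)
  stopifnot(inherits(map, "cell_map"), inherits(grid, "box_grid"))
  box_um <- attr(grid, "box_um")
  b <- attr(grid, "bounds")
  cells <- map$cells[as.logical(map$cells[[marker]]), , drop = FALSE]
  ix <- floor((cells$x_um - b[1]) / box_um) + 1
  iy <- floor((cells$y_um - b[3]) / box_um) + 1
  counts <- table(paste(ix, iy))
  grid$count <- as.integer(counts[paste(grid$ix, grid$iy)])
  grid$count[is.na(grid$count)] <- 0L
  grid
}

#' Normalize a density profile to sham
#'
#' Expresses each bin's density as a percentage of the matching sham
#' density. A sham profile with a single `overall` bin is recycled across
#' the bins of `profile`.
#'
#' @param profile a [density_per_bin()] result.
#' @param sham a [density_per_bin()] result from sham tissue, same marker.
#' @return The profile with an added `pct_of_sham` column.
#' @export
normalize_to_sham <- function(profile, sham) {
  stopifnot(inherits(profile, "density_profile"),
            inherits(sham, "density_profile"))
  if (!all(profile$marker == sham$marker[1]))
    stop("marker mismatch between profile and sham")
  ref <- if (nrow(sham) == 1) rep(sham$mean_density, nrow(profile)) else {
    if (!identical(profile$bin, sham$bin)) stop("bin mismatch with sham profile")
    sham$mean_density
  }
  if (any(!is.na(ref) & ref == 0)) stop("sham density is zero: normalization undefined")
  profile$pct_of_sham <- 100 * profile$mean_density / ref
  profile
}
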