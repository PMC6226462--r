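#' Read and write the package's plain-text data formats
#'
#' Voltage traces are two-column CSV (`time_ms`, `v_mv`); line profiles are
#' two-column CSV (`pos_um`, `intensity_au`); border polylines and cell
#' maps are CSV with the column layouts documented in [cell_map()].
#'
#' @param x object to write.
#' @param path file path.
#' @name pnncap_io
NULL

#' @rdname pnncap_io
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "hh_trace"))
  write.csv(data.frame(time_ms = x$t * 1e3, v_mv = x$v * 1e3), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname pnncap_io
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time_ms", "v_mv") %in% names(d)))
  d
}

#' @rdname pnncap_io
#' @export
write_profile_csv <- function(x, path) {
  stopifnot(inherits(x, "line_profile"))
  write.csv(data.frame(pos_um = x$pos_um, intensity_au = x$intensity), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname pnncap_io
#' @param closed,perimeter passed to [line_profile()].
#' @export
read_profile_csv <- function(path, closed = TRUE, perimeter = NULL) {
  d <- read.csv(path)
  stopifnot(all(c("pos_um", "intensity_au") %in% names(d)))
  line_profile(d$pos_um, d$intensity_au, closed = closed, perimeter = perimeter)
}

#' @rdname pnncap_io
#' @export
write_cell_map_csv <- function(x, path) {
  stopifnot(inherits(x, "cell_map"))
  write.csv(x$cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pnncap_io
#' @param bounds,border,tumor_side passed to [cell_map()].
#' @export
read_cell_map_csv <- function(path, bounds, border = NULL, tumor_side = 1) {
  cell_map(read.csv(path), bounds, border = border, tumor_side = tumor_side)
}

#' @rdname pnncap_io
#' @param max_au full-scale intensity used to normalize to TIFF's unit
#'   range on write and restore on read.
#' @export
write_image_tiff <- function(x, path, max_au = max(x)) {
  stopifnot(is.matrix(x))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
  tiff::writeTIFF(pmax(pmin(x / max_au, 1), 0), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname pnncap_io
#' @export
read_image_tiff <- function(path, max_au = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * max_au
}

#' @rdname pnncap_io
#' @export
write_border_csv <- function(x, path) {
  stopifnot(all(c("x_um", "y_um") %in% names(x)))
  write.csv(x[, c("x_um", "y_um")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname pnncap_io
#' @export
read_border_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("x_um", "y_um") %in% names(d)))
  d
}
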