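# File IO: single-plane TIFF for masks (16-bit labels) and intensity images
# (32-bit), CSV for tracks, traces and nuclei tables.

#' Write / read a 16-bit label TIFF
#'
#' Integer labels up to 65535 round-trip exactly.
#'
#' @param mask Integer (or logical) matrix, 0 = background.
#' @param path Output path.
#' @return `read_label_tiff` returns an integer matrix.
#' @export
write_label_tiff <- function(mask, path) {
  m <- mask * 1
  if (max(m) > 65535) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

# Intensity images are stored scaled into [0, 1) (fixed scale 65536) in a
# 32-bit TIFF; the scale is undone on read. Relative round-trip precision is
# single-float (~1e-6), ample for fluorescence intensities.
#' Write / read a 32-bit intensity TIFF
#'
#' @param image Non-negative numeric matrix (a.u.), values below 65536.
#' @param path Path.
#' @return `read_intensity_tiff` returns a numeric matrix.
#' @export
write_intensity_tiff <- function(image, path) {
  if (min(image) < 0 || max(image) >= 65536) {
    stop("intensities must lie in [0, 65536)", call. = FALSE)
  }
  tiff::writeTIFF(image / 65536, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_intensity_tiff
#' @export
read_intensity_tiff <- function(path) {
  tiff::readTIFF(path) * 65536
}

#' CSV IO for tracks, traces and nuclei tables
#'
#' Plain CSV with a header; columns follow the package conventions
#' (`t_s`, `x_um` for bead tracks; `t_s`, `stage_um` for stage tracks;
#' `t_s`, `value` for traces; `x_px`, `y_px` for nuclei).
#'
#' @param x Data frame to write.
#' @param path File path.
#' @param required Column names that must be present on read.
#' @return `read_table_csv` returns a data frame.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path)
  if (!is.null(required)) {
    miss <- setdiff(required, names(x))
    if (length(miss) > 0L) {
      stop(sprintf("%s is missing column(s): %s", path,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  x
}

#' Read a bead, stage or generic trace CSV
#'
#' @param path File path.
#' @return Data frame with the track's class attached.
#' @export
read_bead_track <- function(path) {
  x <- read_table_csv(path, required = c("t_s", "x_um"))
  class(x) <- c("bead_track", "data.frame")
  x
}

#' @rdname read_bead_track
#' @export
read_stage_track <- function(path) {
  x <- read_table_csv(path, required = c("t_s", "stage_um"))
  class(x) <- c("stage_track", "data.frame")
  x
}

#' @rdname read_bead_track
#' @export
read_trace <- function(path) {
  x <- read_table_csv(path, required = c("t_s", "value"))
  class(x) <- c("trace", "data.frame")
  x
}
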