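# Minimal ImageJ .roi codec for polygon outlines.
#
# The ImageJ ROI file is big-endian: a 64-byte header ("Iout" magic, version,
# ROI type, bounding box, vertex count) followed by x then y vertex offsets
# (16-bit, relative to the bounding-box left/top corner). Only polygon-like
# outlines (polygon, freehand, traced) are meaningful as gland annotations;
# composite and non-area ROI types are rejected.

IJ_ROI_TYPES <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
                  polyline = 5L, noroi = 6L, freehand = 7L, traced = 8L,
                  angle = 9L, point = 10L)

#' Read an ImageJ .roi polygon file
#'
#' @param path Path to a `.roi` file written by ImageJ's ROI tools.
#' @return Two-column (x, y) matrix of vertices in the annotated image's
#'   pixel coordinates.
#' @export
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop(sprintf("%s is not an ImageJ ROI file (missing 'Iout' magic)", path))
  rd2 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, endian = "big", signed = TRUE)
  type <- as.integer(raw[7])
  accepted <- IJ_ROI_TYPES[c("polygon", "freehand", "traced")]
  if (!type %in% accepted)
    stop(sprintf(
      "ImageJ ROI type %d in %s is not a polygon outline (accepted: polygon, freehand, traced)",
      type, path))
  top <- rd2(8); left <- rd2(10)
  n <- rd2(16)
  if (n < 3)
    stop(sprintf("ImageJ ROI %s has %d vertices; at least 3 required", path, n))
  if (length(raw) < 64 + 4 * n)
    stop(sprintf("truncated ImageJ ROI file: %s", path))
  xs <- readBin(raw[65:(64 + 2 * n)], "integer", n = n, size = 2,
                endian = "big", signed = TRUE)
  ys <- readBin(raw[(65 + 2 * n):(64 + 4 * n)], "integer", n = n, size = 2,
                endian = "big", signed = TRUE)
  cbind(x = xs + left, y = ys + top)
}

#' Write a polygon as an ImageJ .roi file
#'
#' @param vertices Two-column (x, y) matrix of integer pixel vertices.
#' @param path Output path.
#' @param type ROI type to record, `"polygon"` or `"freehand"`.
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(vertices, path, type = c("polygon", "freehand")) {
  type <- match.arg(type)
  v <- round(as.matrix(vertices))
  stopifnot(ncol(v) == 2, nrow(v) >= 3)
  left <- min(v[, 1]); top <- min(v[, 2])
  right <- max(v[, 1]); bottom <- max(v[, 2])
  n <- nrow(v)
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  writeBin(charToRaw("Iout"), con)
  wr2(227L)                                    # format version
  writeBin(as.raw(c(IJ_ROI_TYPES[type], 0L)), con)
  wr2(c(top, left, bottom, right, n))
  writeBin(raw(64 - 18), con)                  # rest of the fixed header
  wr2(v[, 1] - left)
  wr2(v[, 2] - top)
  invisible(path)
}
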