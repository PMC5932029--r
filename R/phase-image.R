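#' Quantitative phase image of one tissue core
#'
#' A `PhaseImage` couples a raster of optical path-length phase values
#' (radians) with its physical calibration: the pixel size in micrometres per
#' pixel and the nominal tissue section thickness `L` in micrometres. The
#' section thickness enters the scattering mean free path `ls = L / var[phi]`;
#' the pixel size mediates between the full acquisition resolution
#' (6.2 pixels/um in the reference configuration) and the analysis resolution
#' (1.59 pixels/um) used for curvature and texture.
#'
#' @param pixels Numeric matrix of phase values in radians; rows are image
#'   rows (y), columns are image columns (x). All values must be finite.
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param thickness_um Section thickness `L` in micrometres (> 0); the
#'   standard histology section is 5 um.
#' @param core_id Identifier of the tissue core the image belongs to.
#' @return An object of class `PhaseImage`.
#' @export
phase_image <- function(pixels, pixel_size, thickness_um = 5, core_id = "core") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  nbad <- sum(!is.finite(pixels))
  if (nbad > 0)
    stop(sprintf("phase image contains %d non-finite pixel(s)", nbad))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/pixel)")
  if (!is.numeric(thickness_um) || length(thickness_um) != 1 || thickness_um <= 0)
    stop("`thickness_um` must be a single positive number (um)")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         thickness_um = thickness_um, core_id = as.character(core_id)),
    class = "PhaseImage")
}

#' @export
print.PhaseImage <- function(x, ...) {
  cat(sprintf(
    "<PhaseImage '%s'> %d x %d px, %.4f um/px (%.2f px/um), L = %g um\n",
    x$core_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
    1 / x$pixel_size, x$thickness_um))
  cat(sprintf("  phase range [%.3f, %.3f] rad, mean %.4f rad\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' Read a phase image from a single-channel TIFF
#'
#' Reads a floating-point (or integer) single-channel TIFF raster and attaches
#' physical calibration. Integer rasters are mapped to radians as
#' `value * scale + offset`; float rasters are assumed to already hold radians.
#'
#' @param path Path to a single-channel TIFF file.
#' @inheritParams phase_image
#' @param scale,offset Linear map applied to integer-encoded rasters
#'   (ignored for floating-point TIFFs).
#' @return A [phase_image()].
#' @export
read_phase_image <- function(path, pixel_size, thickness_um = 5,
                             core_id = NULL, scale = 1, offset = 0) {
  if (!file.exists(path)) stop(sprintf("phase image file not found: %s", path))
  px <- tiff::readTIFF(path, all = FALSE, info = TRUE)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] != 1)
      stop(sprintf("expected a single-channel raster, got %d channels in %s",
                   dim(px)[3], path))
    px <- px[, , 1]
  }
  # tiff::readTIFF rescales integer samples to [0,1]; undo via the stated map
  smp <- attr(px, "sample.format")
  m <- matrix(as.vector(px), nrow(px), ncol(px))
  if (!is.null(smp) && !identical(smp, "float")) m <- m * scale + offset
  nbad <- sum(!is.finite(m))
  if (nbad > 0)
    stop(sprintf("phase image %s contains %d non-finite pixel(s)", path, nbad))
  if (is.null(core_id))
    core_id <- tools::file_path_sans_ext(basename(path))
  phase_image(m, pixel_size, thickness_um, core_id)
}

#' Write a phase image as a float32 TIFF
#'
#' Writes the raster as a single-strip, little-endian, 32-bit floating point
#' grayscale TIFF. Values are stored verbatim (radians), including values
#' outside \[0, 1\] and negative phases.
#'
#' @param img A [phase_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phase_image <- function(img, path) {
  stopifnot(inherits(img, "PhaseImage"))
  write_float_tiff(img$pixels, path)
  invisible(path)
}

# Minimal single-strip float32 grayscale TIFF writer (little-endian).
write_float_tiff <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == 3 && count == 1) { wr2(value); wr2(0) } else wr4(value)
  }
  writeBin(charToRaw("II"), con); wr2(42L); wr4(8L)  # header, IFD at byte 8
  n_entries <- 11L
  data_off <- 8L + 2L + n_entries * 12L + 4L
  wr2(n_entries)
  entry(256, 3, 1, w)              # ImageWidth
  entry(257, 3, 1, h)              # ImageLength
  entry(258, 3, 1, 32L)            # BitsPerSample
  entry(259, 3, 1, 1L)             # Compression: none
  entry(262, 3, 1, 1L)             # Photometric: BlackIsZero
  entry(273, 4, 1, data_off)       # StripOffsets
  entry(277, 3, 1, 1L)             # SamplesPerPixel
  entry(278, 3, 1, h)              # RowsPerStrip
  entry(279, 4, 1, 4L * w * h)     # StripByteCounts
  entry(284, 3, 1, 1L)             # PlanarConfiguration
  entry(339, 3, 1, 3L)             # SampleFormat: IEEE float
  wr4(0L)                          # next IFD: none
  # row-major pixel order
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

#' Downsample a phase image by bicubic interpolation
#'
#' Resamples the raster to `target_edge` pixels on its longer side using
#' separable Catmull-Rom bicubic interpolation, the conventional bicubic
#' kernel, which reproduces constant and linear intensity ramps exactly.
#' The pixel size is rescaled so the physical extent of the image is
#' preserved; downsampling an 8000-pixel, 6.2 pixels/um acquisition to
#' 2048 pixels yields the 1.59 pixels/um analysis resolution.
#'
#' @param img A [phase_image()].
#' @param target_edge Target size in pixels of the larger image dimension;
#'   must not exceed the current size (no upsampling).
#' @return A [phase_image()] at the new resolution.
#' @export
downsample_image <- function(img, target_edge) {
  stopifnot(inherits(img, "PhaseImage"))
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  edge <- max(h, w)
  if (target_edge > edge)
    stop(sprintf("upsampling requested (%d -> %d pixels); only downsampling is supported",
                 edge, target_edge))
  s <- edge / target_edge
  nh <- max(1L, round(h / s)); nw <- max(1L, round(w / s))
  out <- bicubic_resample(img$pixels, nh, nw)
  phase_image(out, pixel_size = img$pixel_size * s,
              thickness_um = img$thickness_um, core_id = img$core_id)
}

# Catmull-Rom kernel (Keys cubic, a = -1/2)
cubic_kernel <- function(x) {
  x <- abs(x)
  ifelse(x < 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

# Separable cubic resampling with pixel-center alignment
# (destination center j maps to source (j + 0.5) * scale - 0.5, 0-based).
bicubic_resample <- function(m, nh, nw) {
  resamp_1d <- function(n_src, n_dst) {
    sc <- n_src / n_dst
    centers <- (seq_len(n_dst) - 0.5) * sc - 0.5        # 0-based source coords
    base <- floor(centers)
    w <- matrix(0, n_dst, n_src)
    put <- function(rows, src, wt) {
      # linear extrapolation beyond the borders keeps degree-1 reproduction
      below <- src < 0; above <- src > n_src - 1
      mid <- !(below | above)
      idx <- cbind(rows[mid], src[mid] + 1)
      w[idx] <<- w[idx] + wt[mid]
      if (any(below)) {
        k <- -src[below]
        i <- rows[below]
        w[cbind(i, 1)] <<- w[cbind(i, 1)] + wt[below] * (1 + k)
        w[cbind(i, 2)] <<- w[cbind(i, 2)] - wt[below] * k
      }
      if (any(above)) {
        k <- src[above] - (n_src - 1)
        i <- rows[above]
        w[cbind(i, n_src)] <<- w[cbind(i, n_src)] + wt[above] * (1 + k)
        w[cbind(i, n_src - 1)] <<- w[cbind(i, n_src - 1)] - wt[above] * k
      }
    }
    for (k in -1:2) {
      src <- base + k
      put(seq_len(n_dst), src, cubic_kernel(centers - src))
    }
    w
  }
  wr <- resamp_1d(nrow(m), nh)
  wc <- resamp_1d(ncol(m), nw)
  wr %*% m %*% t(wc)
}
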