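#' Scattering mean free path map from a phase image
#'
#' Under the scattering-phase theorem, assuming the section captures the
#' refractive-index fluctuation statistics of the bulk tissue, the scattering
#' mean free path is \deqn{l_s(x, y) = L / \mathrm{var}[\varphi(x, y)],}
#' where `L` is the section thickness and the variance is taken spatially
#' over a local window. The reference configuration uses a 149 x 149 pixel
#' window at the full 6.2 pixels/um acquisition resolution — roughly the
#' diameter of three epithelial cells (about 24 um). At other resolutions the
#' default kernel is rescaled to preserve that physical extent (see
#' [ls_kernel_edge()]).
#'
#' The local variance is the population (divisor `N`) variance over the
#' window, computed with symmetric reflective padding at the raster border.
#' Pixels with zero local variance are marked invalid (`NA`), as are pixels
#' whose window extends beyond the raster, so that border reflections never
#' enter gland medians.
#'
#' @param img A [phase_image()].
#' @param kernel_edge Odd window edge in pixels; `NULL` (default) derives it
#'   from the image's pixel size via [ls_kernel_edge()].
#' @return A `ScatteringMap`: list with `ls_pixels` (um; `NA` where invalid),
#'   `kernel_edge`, `thickness_um`, and `n_zero_var` (count of zero-variance
#'   pixels flagged invalid).
#' @export
scattering_length_map <- function(img, kernel_edge = NULL) {
  stopifnot(inherits(img, "PhaseImage"))
  phi <- img$pixels
  k <- kernel_edge %||% ls_kernel_edge(img$pixel_size)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("`kernel_edge` must be odd")
  if (k > min(dim(phi)))
    stop(sprintf("variance kernel (%d px) exceeds the %d x %d raster",
                 k, nrow(phi), ncol(phi)))
  # center the phase first so the sum-of-squares update is well conditioned;
  # the local variance is invariant to this shift
  phi0 <- phi - mean(phi)
  n <- as.numeric(k)^2
  mu <- box_sum_reflect(phi0, k) / n
  m2 <- box_sum_reflect(phi0 * phi0, k) / n
  v <- pmax(m2 - mu * mu, 0)
  ls <- img$thickness_um / v
  zero <- v == 0
  ls[zero] <- NA_real_
  # invalidate border pixels whose window leaves the raster
  r <- (k - 1L) %/% 2L
  nr <- nrow(phi); nc <- ncol(phi)
  if (r > 0) {
    ls[c(seq_len(r), nr + 1L - seq_len(r)), ] <- NA_real_
    ls[, c(seq_len(r), nc + 1L - seq_len(r))] <- NA_real_
  }
  structure(
    list(ls_pixels = ls, kernel_edge = k, thickness_um = img$thickness_um,
         n_zero_var = sum(zero)),
    class = "ScatteringMap")
}

#' Variance-kernel edge for a given pixel size
#'
#' The reference kernel is 149 pixels at 6.2 pixels/um, a physical extent of
#' about 24 um (three epithelial cell diameters). For another pixel size the
#' edge preserving that extent is returned, rounded to the nearest odd
#' integer: at the 1.59 pixels/um analysis resolution this gives 39 pixels.
#'
#' @param pixel_size Pixel size in um/pixel.
#' @return Odd integer kernel edge in pixels.
#' @export
ls_kernel_edge <- function(pixel_size) {
  extent_um <- 149 / 6.2
  k <- extent_um / pixel_size
  k_odd <- 2L * as.integer(round((k - 1) / 2)) + 1L
  max(3L, k_odd)
}

#' Median scattering mean free path over a gland
#'
#' @param map A `ScatteringMap` from [scattering_length_map()].
#' @param mask Logical gland mask of the same dimensions (from
#'   [rasterize_gland_mask()]).
#' @return Median of the valid `ls` values (um) inside the mask. Errors when
#'   the mask covers no valid pixel.
#' @export
median_ls <- function(map, mask) {
  stopifnot(inherits(map, "ScatteringMap"),
            identical(dim(mask), dim(map$ls_pixels)))
  vals <- map$ls_pixels[mask]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("gland mask overlaps no valid scattering-length pixel")
  stats::median(vals)
}
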