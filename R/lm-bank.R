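#' Leung-Malik filter bank
#'
#' Builds the oriented multi-scale filter bank used for texton texture
#' analysis: odd (first-derivative, "edge") and even (second-derivative,
#' "bar") elongated Gaussian-derivative filters at several orientations and
#' scales, plus rotationally symmetric Gaussian and Laplacian-of-Gaussian
#' (LoG) blob filters. The default configuration has 6 orientations and
#' 3 derivative scales (36 oriented filters) with the blob families extended —
#' 14 LoG scales on a quarter-octave ladder and 8 Gaussian scales on a
#' half-octave ladder — for a total of 58 filters.
#'
#' All kernels are L1-normalized; derivative and LoG kernels are exactly
#' zero-mean (enforced after truncation to the finite support).
#'
#' @param orientations Number of derivative-filter orientations.
#' @param deriv_scales Gaussian sigmas of the oriented derivative filters
#'   (the cross-section sigma; the elongation factor is 3).
#' @param log_scales Sigmas of the LoG filters.
#' @param gauss_scales Sigmas of the Gaussian filters.
#' @param support Kernel edge in pixels (odd).
#' @return A `FilterBank`: list with `kernels` (list of matrices), `info`
#'   (data frame: family, orientation, scale) and `id` (configuration hash
#'   used to cache kernel spectra).
#' @export
build_lm_bank <- function(orientations = 6,
                          deriv_scales = c(1, sqrt(2), 2),
                          log_scales = 2^(seq(0, 13) / 4),
                          gauss_scales = 2^(seq(0, 7) / 2),
                          support = 49) {
  support <- as.integer(support)
  if (support %% 2L == 0L) stop("`support` must be odd")
  r <- (support - 1L) / 2L
  gx <- matrix(rep(-r:r, each = support), support, support)   # x = column offset
  gy <- matrix(rep(-r:r, times = support), support, support)  # y = row offset
  kernels <- list()
  info <- list()
  add <- function(k, family, orientation, scale) {
    if (family %in% c("edge", "bar", "log")) k <- k - mean(k)
    k <- k / sum(abs(k))
    kernels[[length(kernels) + 1L]] <<- k
    info[[length(info) + 1L]] <<- data.frame(
      family = family, orientation = orientation, scale = scale)
  }
  thetas <- pi * (seq_len(orientations) - 1L) / orientations
  for (sc in deriv_scales) for (th in thetas) {
    add(oriented_gaussian_deriv(gx, gy, sc, th, order = 1), "edge", th, sc)
  }
  for (sc in deriv_scales) for (th in thetas) {
    add(oriented_gaussian_deriv(gx, gy, sc, th, order = 2), "bar", th, sc)
  }
  for (sc in log_scales) {
    r2 <- gx^2 + gy^2
    k <- (r2 - 2 * sc^2) / sc^4 * exp(-r2 / (2 * sc^2))
    add(k, "log", NA_real_, sc)
  }
  for (sc in gauss_scales) {
    k <- exp(-(gx^2 + gy^2) / (2 * sc^2))
    add(k, "gaussian", NA_real_, sc)
  }
  info <- do.call(rbind, info)
  dup <- duplicated(info)
  if (any(dup))
    stop("filter bank configuration yields duplicate kernels")
  structure(
    list(kernels = kernels, info = info,
         id = substr(rlang_free_hash(info), 1, 12)),
    class = "FilterBank")
}

# Rotated, elongated Gaussian derivative: derivative of order 1 or 2 along
# the rotated y axis with sigma `sc`, Gaussian with sigma 3*sc across it.
oriented_gaussian_deriv <- function(gx, gy, sc, theta, order) {
  u <- cos(theta) * gx + sin(theta) * gy    # along-filter axis (3*sc)
  v <- -sin(theta) * gx + cos(theta) * gy   # derivative axis (sc)
  g <- exp(-u^2 / (2 * (3 * sc)^2)) * exp(-v^2 / (2 * sc^2))
  if (order == 1) (-v / sc^2) * g
  else ((v^2 - sc^2) / sc^4) * g
}

# Small stable hash of a configuration data frame (dependency-free).
rlang_free_hash <- function(x) {
  s <- paste(utils::capture.output(print(x)), collapse = "\n")
  b <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (i in seq_along(b)) {
    h1 <- (h1 * 31 + b[i]) %% 2147483647
    h2 <- (h2 * 131 + b[i]) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

#' @export
print.FilterBank <- function(x, ...) {
  cat(sprintf("<FilterBank> %d kernels (%s), support %dx%d\n",
              length(x$kernels),
              paste(sprintf("%s: %d", names(table(x$info$family)),
                            as.integer(table(x$info$family))), collapse = ", "),
              nrow(x$kernels[[1]]), ncol(x$kernels[[1]])))
  invisible(x)
}
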