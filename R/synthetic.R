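#' Class-conditional generator parameters
#'
#' Default morphology and texture parameters for synthetic benign and
#' malignant glands. The defaults encode the qualitative contrasts seen in
#' breast histology: benign glands are well differentiated — rounded acini
#' whose boundaries undulate rapidly (high perimeter curvature at the ~13 um
#' analysis scale) and whose interiors mix high-phase epithelium with
#' low-phase lumina (large local phase variance, hence short scattering mean
#' free path) — while malignant glands are monoclonal sheets: smoother,
#' slowly varying outlines and near-homogeneous interiors (small variance,
#' long mean free path).
#'
#' @param class `"benign"` or `"malignant"`.
#' @param effect `"strong"` (default class contrasts) or `"null"` (both
#'   classes share identical parameters; used for null-effect calibration
#'   checks).
#' @return Named list of generator parameters.
#' @export
synthetic_class_params <- function(class = c("benign", "malignant"),
                                   effect = c("strong", "null")) {
  class <- match.arg(class)
  effect <- match.arg(effect)
  if (effect == "null") {
    # one intermediate phenotype for both classes
    return(list(
      boundary_wobble_amplitude = 0.12, boundary_wobble_harmonics = 3:6,
      phase_mean = 0.8, phase_variance = 0.02, speckle_corr = 2,
      lumen_frac = 0.1, lumen_phase = 0.2, texture_class = "pooled",
      radius_range = c(38, 52)))
  }
  if (class == "benign") {
    list(boundary_wobble_amplitude = 0.18, boundary_wobble_harmonics = 5:9,
         phase_mean = 0.9, phase_variance = 0.05, speckle_corr = 1.2,
         lumen_frac = 0.25, lumen_phase = 0.15, texture_class = "acinar",
         radius_range = c(38, 52))
  } else {
    list(boundary_wobble_amplitude = 0.07, boundary_wobble_harmonics = 2:4,
         phase_mean = 0.7, phase_variance = 0.01, speckle_corr = 3,
         lumen_frac = 0, lumen_phase = 0.2, texture_class = "sheet",
         radius_range = c(38, 52))
  }
}

#' Synthetic cohort configuration
#'
#' Bundles everything the generator needs for a cohort of tissue-microarray
#' cores. The defaults emulate the reference study design — 34 benign plus
#' 34 malignant cores — at a desk-scale raster: a 512-pixel crop at the
#' 1.59 pixels/um analysis resolution and the standard 5 um section.
#'
#' @param n_benign,n_malignant Core counts per class.
#' @param glands_per_core Integer range (min, max) of glands per core.
#' @param image_edge Square raster edge in pixels.
#' @param pixel_size Pixel size in um/pixel (default: analysis resolution,
#'   1/1.59).
#' @param thickness_um Section thickness in um.
#' @param noise_sd Standard deviation of the additive Gaussian phase noise
#'   (radians).
#' @param effect `"strong"` or `"null"` class contrasts
#'   (see [synthetic_class_params()]).
#' @param seed Master seed of the cohort.
#' @return A `SyntheticCohortConfig` list.
#' @export
synthetic_cohort_config <- function(n_benign = 34, n_malignant = 34,
                                    glands_per_core = c(2, 3),
                                    image_edge = 512, pixel_size = 1 / 1.59,
                                    thickness_um = 5, noise_sd = 0.05,
                                    effect = c("strong", "null"), seed = 1L) {
  effect <- match.arg(effect)
  bp <- synthetic_class_params("benign", effect)
  mp <- synthetic_class_params("malignant", effect)
  if (effect == "strong") {
    stopifnot(bp$phase_variance > mp$phase_variance,
              bp$boundary_wobble_amplitude > mp$boundary_wobble_amplitude)
  }
  structure(
    list(n_benign = n_benign, n_malignant = n_malignant,
         glands_per_core = glands_per_core, image_edge = image_edge,
         pixel_size = pixel_size, thickness_um = thickness_um,
         noise_sd = noise_sd, effect = effect,
         benign_params = bp, malignant_params = mp, seed = as.integer(seed)),
    class = "SyntheticCohortConfig")
}

#' Generate one synthetic tissue core
#'
#' Deterministically (given `seed`) builds a phase image and its gland
#' annotations. Glands are non-overlapping star-convex polygons whose radius
#' is modulated by a band-limited random Fourier wobble; the interior phase
#' is the class texture field (benign: lumen blobs in high-phase epithelium;
#' malignant: near-homogeneous sheet) plus class speckle, the background is
#' a distinct fibrous stroma texture, and i.i.d. Gaussian noise of standard
#' deviation `noise_sd` is added everywhere. Annotations trace the generated
#' boundaries exactly.
#'
#' @param class_label `"benign"` or `"malignant"`.
#' @param params Class parameters from [synthetic_class_params()].
#' @param seed Core seed.
#' @param image_edge,pixel_size,thickness_um,noise_sd See
#'   [synthetic_cohort_config()].
#' @param n_glands Number of glands; `NULL` draws from `glands_range`.
#' @param glands_range Integer range when `n_glands` is `NULL`.
#' @param core_id Core identifier.
#' @return List with `image` (a [phase_image()]), `annotations` (list of
#'   [gland_annotation()]) and `stats` (per-gland ground-truth statistics:
#'   area, interior mean and variance before noise).
#' @export
generate_core <- function(class_label, params, seed, image_edge = 512,
                          pixel_size = 1 / 1.59, thickness_um = 5,
                          noise_sd = 0.05, n_glands = NULL,
                          glands_range = c(2, 3), core_id = "core") {
  with_seed(seed, {
    ne <- as.integer(image_edge)
    if (is.null(n_glands))
      n_glands <- sample(glands_range[1]:glands_range[2], 1)
    # background stroma: anisotropic fibrous streaks
    img <- 0.35 + aniso_field(ne, ne, sd = 0.15, sigma_along = 5,
                              sigma_across = 0.8,
                              transposed = (seed %% 2 == 0))
    polys <- place_gland_polygons(n_glands, params, ne)
    # class speckle field with calibrated pointwise variance
    epi <- params$phase_mean +
      speckle_field(ne, ne, variance = params$phase_variance,
                    corr_sigma = params$speckle_corr)
    annotations <- list()
    stats_list <- list()
    for (i in seq_along(polys)) {
      g <- gland_annotation(polys[[i]], core_id, class_label,
                            sprintf("g%d", i), check_simple = FALSE)
      mask <- rasterize_gland_mask(g, c(ne, ne))
      img[mask] <- epi[mask]
      if (params$lumen_frac > 0)
        img <- add_lumen_blobs(img, mask, params$lumen_frac,
                               params$lumen_phase)
      stats_list[[i]] <- data.frame(
        gland_id = g$gland_id, area_px = sum(mask),
        interior_mean = mean(img[mask]), interior_var = stats::var(img[mask]))
      annotations[[i]] <- g
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(ne * ne, 0, noise_sd), ne, ne)
    stats_df <- do.call(rbind, stats_list)
    list(image = phase_image(img, pixel_size, thickness_um, core_id),
         annotations = annotations,
         stats = data.frame(core_id = core_id, label = class_label, stats_df,
                            image_mean = mean(img)))
  })
}

# Band-limited radial wobble polygon: r(theta) = R (1 + sum a_k cos(k theta
# + phi_k)) with 3 harmonics from the class band; `amplitude` is the RMS
# radial modulation as a fraction of R.
wobble_polygon <- function(center, radius, amplitude, harmonics) {
  ks <- sample(harmonics, min(3, length(harmonics)))
  wts <- stats::runif(length(ks), 0.5, 1)
  a <- amplitude * sqrt(2) * wts / sqrt(sum(wts^2))
  phi <- stats::runif(length(ks), 0, 2 * pi)
  nv <- max(96L, round(2 * pi * radius))
  th <- 2 * pi * (seq_len(nv) - 1L) / nv
  r <- radius * (1 + colSums(a * cos(outer(ks, th) + phi)))
  v <- cbind(x = round(center[1] + r * cos(th)),
             y = round(center[2] + r * sin(th)))
  collapse_duplicate_vertices(v)   # canonical: no repeated pixel vertices
}

place_gland_polygons <- function(n_glands, params, edge,
                                 margin = 48, max_retry = 200) {
  polys <- list(); centers <- NULL; bound_r <- numeric(0)
  for (i in seq_len(n_glands)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      R <- stats::runif(1, params$radius_range[1], params$radius_range[2])
      rb <- R * (1 + 2 * params$boundary_wobble_amplitude)
      lo <- margin + rb; hi <- edge - 1 - margin - rb
      if (hi <= lo) stop("image too small for the requested gland size")
      c_i <- stats::runif(2, lo, hi)
      ok <- is.null(centers) ||
        all(sqrt(rowSums(sweep(centers, 2, c_i)^2)) > bound_r + rb + 8)
      if (ok) {
        polys[[i]] <- wobble_polygon(c_i, R, params$boundary_wobble_amplitude,
                                     params$boundary_wobble_harmonics)
        centers <- rbind(centers, c_i)
        bound_r <- c(bound_r, rb)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place gland %d without overlap after %d retries",
                   i, max_retry))
  }
  polys
}

# Smoothed white noise rescaled to an exact pointwise variance target.
speckle_field <- function(nr, nc, variance, corr_sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_sigma > 0) {
    z <- gauss_blur(z, corr_sigma)
    r <- max(1L, ceiling(3 * corr_sigma))
    g <- exp(-(seq(-r, r))^2 / (2 * corr_sigma^2)); g <- g / sum(g)
    z <- z / sum(g^2)           # blur shrinks the sd by sum(g^2) per axis
  }
  z * sqrt(variance)
}

# Oriented stroma texture: noise smoothed strongly along one axis.
aniso_field <- function(nr, nc, sd, sigma_along, sigma_across, transposed) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  r1 <- max(1L, ceiling(3 * sigma_along))
  g1 <- exp(-(seq(-r1, r1))^2 / (2 * sigma_along^2)); g1 <- g1 / sum(g1)
  r2 <- max(1L, ceiling(3 * sigma_across))
  g2 <- exp(-(seq(-r2, r2))^2 / (2 * sigma_across^2)); g2 <- g2 / sum(g2)
  z <- blur_axis(blur_axis(z, g1, rows = TRUE), g2, rows = FALSE)
  if (transposed) z <- t(z)
  z * sd / sqrt(sum(g1^2) * sum(g2^2))
}

blur_axis <- function(m, g, rows) {
  r <- (length(g) - 1L) %/% 2L
  if (rows) {
    p <- pad_reflect(m, r, r, 0, 0)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(g)) out <- out + g[j] * p[j:(j + nrow(m) - 1L), , drop = FALSE]
  } else {
    p <- pad_reflect(m, 0, 0, r, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(g)) out <- out + g[j] * p[, j:(j + ncol(m) - 1L), drop = FALSE]
  }
  out
}

# Punch low-phase lumen disks into a gland until roughly `frac` of its area
# is lumen.
add_lumen_blobs <- function(img, mask, frac, lumen_phase, max_blobs = 60) {
  idx <- which(mask, arr.ind = TRUE)
  target <- frac * nrow(idx)
  lumen <- matrix(FALSE, nrow(img), ncol(img))
  for (b in seq_len(max_blobs)) {
    if (sum(lumen & mask) >= target) break
    ctr <- idx[sample.int(nrow(idx), 1), ]
    rb <- stats::runif(1, 4, 9)
    rows <- max(1, floor(ctr[1] - rb)):min(nrow(img), ceiling(ctr[1] + rb))
    cols <- max(1, floor(ctr[2] - rb)):min(ncol(img), ceiling(ctr[2] + rb))
    dd <- outer((rows - ctr[1])^2, (cols - ctr[2])^2, `+`)
    sel <- dd <= rb^2
    lumen[rows, cols][sel] <- TRUE
  }
  lumen <- lumen & mask
  img[lumen] <- lumen_phase
  img
}

#' Generate a synthetic cohort
#'
#' Builds `n_benign + n_malignant` cores from a cohort configuration.
#' With `dir = NULL` the cohort is returned in memory; otherwise each core's
#' phase image (float32 TIFF) and annotations (polygon JSON) are written to
#' `dir` along with `labels.csv` and a `manifest.json` of per-core
#' ground-truth generator statistics.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @param dir Output directory, or `NULL` for an in-memory cohort.
#' @return Invisibly (on disk) or directly (in memory): list with `cores`
#'   (list of `generate_core()` outputs), `labels` (data frame), and
#'   `manifest` (per-gland ground-truth statistics).
#' @export
generate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "SyntheticCohortConfig"))
  specs <- rbind(
    if (cfg$n_benign > 0)
      data.frame(core_id = sprintf("b%02d", seq_len(cfg$n_benign)),
                 label = "benign"),
    if (cfg$n_malignant > 0)
      data.frame(core_id = sprintf("m%02d", seq_len(cfg$n_malignant)),
                 label = "malignant"))
  cores <- vector("list", nrow(specs))
  stats_all <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    p <- if (specs$label[i] == "benign") cfg$benign_params else cfg$malignant_params
    core <- generate_core(
      specs$label[i], p, seed = derive_seed(cfg$seed, specs$core_id[i]),
      image_edge = cfg$image_edge, pixel_size = cfg$pixel_size,
      thickness_um = cfg$thickness_um, noise_sd = cfg$noise_sd,
      glands_range = cfg$glands_per_core, core_id = specs$core_id[i])
    cores[[i]] <- core
    stats_all[[i]] <- core$stats
  }
  manifest <- do.call(rbind, stats_all)
  out <- list(cores = stats::setNames(cores, specs$core_id), labels = specs,
              manifest = manifest, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(specs))) {
      id <- specs$core_id[i]
      write_phase_image(cores[[i]]$image, file.path(dir, paste0(id, ".tif")))
      write_annotations_json(cores[[i]]$annotations,
                             file.path(dir, paste0(id, ".json")))
    }
    utils::write.csv(specs, file.path(dir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(cfg), cores = manifest),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Load a cohort written by [generate_cohort()]
#'
#' @param dir Dataset directory containing `<core>.tif`, `<core>.json` and
#'   `labels.csv`.
#' @param pixel_size,thickness_um Calibration to attach to the images.
#' @return List with `cores` (each `list(image, annotations)`) and `labels`.
#' @export
read_cohort <- function(dir, pixel_size = 1 / 1.59, thickness_um = 5) {
  labels <- read_core_labels(file.path(dir, "labels.csv"))
  cores <- lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$core_id[i]
    list(image = read_phase_image(file.path(dir, paste0(id, ".tif")),
                                  pixel_size, thickness_um, core_id = id),
         annotations = read_annotations(file.path(dir, paste0(id, ".json"))))
  })
  list(cores = stats::setNames(cores, labels$core_id), labels = labels)
}
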