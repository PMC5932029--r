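#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline. The defaults reproduce
#' the reference configuration: analysis resolution 1.59 pixels/um, variance
#' kernel of 149 pixels at full resolution (rescaled by pixel size
#' otherwise), 60-pixel texture window, perimeter subsampling step 20,
#' K = 50 textons, 10000 response samples per core, mean gland-to-core
#' aggregation, and three cross-validation folds.
#'
#' @param pixel_size Analysis pixel size in um/pixel.
#' @param thickness_um Section thickness in um.
#' @param ls_kernel Variance kernel edge; `NULL` derives it from
#'   `pixel_size` via [ls_kernel_edge()].
#' @param texture_window Texton histogram window edge (pixels).
#' @param curvature_step Perimeter subsampling step (vertices).
#' @param K Number of textons.
#' @param n_samples Response samples per core for codebook fitting.
#' @param aggregation `"mean"` or `"median"` gland-to-core aggregation.
#' @param shrinkage LDA covariance shrinkage (`"auto"` or a number).
#' @param n_folds Cross-validation folds.
#' @param seed Master seed; sampling, k-means and fold assignment use
#'   streams derived from it.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(pixel_size = 1 / 1.59, thickness_um = 5,
                            ls_kernel = NULL, texture_window = 60,
                            curvature_step = 20, K = 50, n_samples = 10000,
                            aggregation = c("mean", "median"),
                            shrinkage = "auto", n_folds = 3, seed = 1L) {
  aggregation <- match.arg(aggregation)
  stopifnot(pixel_size > 0, thickness_um > 0, texture_window >= 1,
            curvature_step >= 1, K >= 2, n_samples >= K, n_folds >= 2)
  structure(
    list(pixel_size = pixel_size, thickness_um = thickness_um,
         ls_kernel = ls_kernel, texture_window = texture_window,
         curvature_step = curvature_step, K = K, n_samples = n_samples,
         aggregation = aggregation, shrinkage = shrinkage,
         n_folds = n_folds, seed = as.integer(seed)),
    class = "PipelineConfig")
}

# Crop window around a gland: the histogram support (bbox + half window,
# rounded up) plus the convolution support margin so every histogram pixel's
# response is computed from true image content.
gland_crop <- function(g, shape, window, support) {
  v <- g$vertices
  mh <- ceiling(window / 2)
  mc <- (support - 1L) %/% 2L
  hist_r <- c(max(0, floor(min(v[, 2])) - mh), min(shape[1] - 1, ceiling(max(v[, 2])) + mh))
  hist_c <- c(max(0, floor(min(v[, 1])) - mh), min(shape[2] - 1, ceiling(max(v[, 1])) + mh))
  conv_r <- c(max(0, hist_r[1] - mc), min(shape[1] - 1, hist_r[2] + mc))
  conv_c <- c(max(0, hist_c[1] - mc), min(shape[2] - 1, hist_c[2] + mc))
  list(hist_r = hist_r, hist_c = hist_c, conv_r = conv_r, conv_c = conv_c)
}

#' Extract geometric and scattering features plus response samples for one core
#'
#' Computes, for every annotated gland of a core: the median perimeter
#' curvature, the median scattering mean free path, and a random sample of
#' filter-bank response vectors drawn uniformly without replacement from the
#' union of gland interiors, for texton-codebook fitting.
#'
#' @param core List with `image` (a [phase_image()]) and `annotations`.
#' @param cfg A [pipeline_config()].
#' @param bank A [build_lm_bank()] filter bank.
#' @param sample_seed Seed of the response-sampling stream.
#' @return List with `core_id`, `geom` (data frame `gland_id, median_c,
#'   median_ls, area_px`), and `samples` (matrix of response vectors).
#' @export
extract_core_features <- function(core, cfg, bank, sample_seed = NULL) {
  img <- core$image
  stopifnot(inherits(img, "PhaseImage"))
  shape <- dim(img$pixels)
  sample_seed <- sample_seed %||% derive_seed(cfg$seed, paste0("smp_", img$core_id))
  ls_map <- scattering_length_map(
    img, cfg$ls_kernel %||% ls_kernel_edge(img$pixel_size))
  geom <- list(); mask_idx <- list()
  for (g in core$annotations) {
    check_annotation_bounds(g, shape)
    mask <- rasterize_gland_mask(g, shape)
    prof <- perimeter_curvature(g, cfg$curvature_step)
    geom[[g$gland_id]] <- data.frame(
      core_id = g$core_id, gland_id = g$gland_id,
      median_c = median_curvature(prof),
      median_ls = median_ls(ls_map, mask),
      area_px = sum(mask))
    mask_idx[[g$gland_id]] <- which(mask)
  }
  geom <- do.call(rbind, geom)
  rownames(geom) <- NULL
  # draw the per-core sample budget uniformly over the epithelial union
  all_idx <- unlist(mask_idx, use.names = FALSE)
  take <- if (length(all_idx) <= cfg$n_samples) all_idx else
    with_seed(sample_seed, sample(all_idx, cfg$n_samples))
  px <- cbind(((take - 1L) %% shape[1]) + 1L, ((take - 1L) %/% shape[1]) + 1L)
  samples <- responses_at_pixels(img$pixels, px, bank)
  list(core_id = img$core_id, geom = geom, samples = samples)
}

#' Gland texture features under one or more texton codebooks
#'
#' Recomputes each gland's filter responses on its crop window, assigns
#' textons under every supplied codebook, and returns the gland-level
#' texture descriptor (per-dimension median of the windowed texton
#' histograms over the gland, renormalized).
#'
#' @param core List with `image` and `annotations`.
#' @param cfg A [pipeline_config()].
#' @param bank Filter bank.
#' @param codebooks Named list of [fit_textons()] codebooks.
#' @return Data frame `core_id, gland_id, codebook, T1..TK`.
#' @export
core_texture_features <- function(core, cfg, bank, codebooks) {
  img <- core$image
  shape <- dim(img$pixels)
  support <- nrow(bank$kernels[[1]])
  out <- list()
  for (g in core$annotations) {
    mask <- rasterize_gland_mask(g, shape)
    cr <- gland_crop(g, shape, cfg$texture_window, support)
    rows <- (cr$conv_r[1]:cr$conv_r[2]) + 1L
    cols <- (cr$conv_c[1]:cr$conv_c[2]) + 1L
    mc <- (support - 1L) %/% 2L
    # the half-kernel band around the histogram support is discarded, so the
    # cheaper unpadded transform is valid whenever that band holds true
    # image content (i.e. the crop was not clipped at the raster border)
    full_margin <- cr$conv_r[1] == cr$hist_r[1] - mc &&
      cr$conv_r[2] == cr$hist_r[2] + mc &&
      cr$conv_c[1] == cr$hist_c[1] - mc && cr$conv_c[2] == cr$hist_c[2] + mc
    resp <- filter_responses(img$pixels[rows, cols], bank,
                             pad = if (full_margin) "none" else "reflect")
    d <- dim(resp)
    dim(resp) <- c(d[1] * d[2], d[3])            # flatten once, no copy
    # histogram-support subraster inside the convolution crop; textons are
    # only needed there, so assignment is restricted to those rows
    hr <- (cr$hist_r[1]:cr$hist_r[2]) - cr$conv_r[1] + 1L
    hc <- (cr$hist_c[1]:cr$hist_c[2]) - cr$conv_c[1] + 1L
    hidx <- as.vector(outer(hr, (hc - 1L) * d[1], `+`))
    resp_h <- resp[hidx, , drop = FALSE]
    mhist <- mask[(cr$hist_r[1]:cr$hist_r[2]) + 1L,
                  (cr$hist_c[1]:cr$hist_c[2]) + 1L]
    for (cb_name in names(codebooks)) {
      cb <- codebooks[[cb_name]]
      tex <- matrix(assign_textons(resp_h, cb), length(hr), length(hc))
      tv <- texton_histogram_feature(tex, mhist, cb$K, cfg$texture_window)
      row <- data.frame(core_id = g$core_id, gland_id = g$gland_id,
                        codebook = cb_name)
      row[paste0("T", seq_len(cb$K))] <- as.list(tv)
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Three-fold cross-validated core classification
#'
#' The full evaluation protocol: cores are split into `n_folds` (default 3)
#' nearly equal, class-stratified groups; for each trial, the texton
#' codebook and the LDA classifier are fitted on the training folds only,
#' validation glands are scored, gland likelihoods are aggregated into core
#' scores (both mean and median variants are recorded), and the per-core
#' validation scores from all trials are pooled into a single ROC analysis.
#' A provenance guard refuses to score any core that contributed to the
#' codebook or classifier it is scored with.
#'
#' @param cohort List with `cores` (each `list(image, annotations)`) and
#'   `labels` (data frame `core_id, label`), e.g. from [generate_cohort()]
#'   or [read_cohort()].
#' @param cfg A [pipeline_config()].
#' @return A `CVResult`: list with `core_scores` (pooled data frame),
#'   `roc` (ROC of the configured aggregation), `roc_mean`, `roc_median`,
#'   `folds`, and `config`.
#' @export
threefold_cv <- function(cohort, cfg = pipeline_config()) {
  labels <- cohort$labels
  cores <- cohort$cores
  stopifnot(all(labels$core_id %in% names(cores)))
  bank <- build_lm_bank()
  folds <- assign_folds(labels$core_id, labels$label, cfg$n_folds,
                        seed = derive_seed(cfg$seed, "folds"))
  # phase A: geometry, scattering, and codebook samples per core
  ctx <- lapply(labels$core_id, function(id)
    extract_core_features(cores[[id]], cfg, bank))
  names(ctx) <- labels$core_id
  # phase B: one texton codebook per training split
  codebooks <- lapply(seq_len(cfg$n_folds), function(f) {
    train_ids <- labels$core_id[folds[labels$core_id] != f]
    fit_textons(do.call(rbind, lapply(ctx[train_ids], `[[`, "samples")),
                K = cfg$K, seed = derive_seed(cfg$seed, sprintf("kmeans%d", f)),
                source_cores = train_ids)
  })
  names(codebooks) <- sprintf("fold%d", seq_len(cfg$n_folds))
  # phase C: gland texture features under every fold's codebook
  tex <- do.call(rbind, lapply(labels$core_id, function(id)
    core_texture_features(cores[[id]], cfg, bank, codebooks)))
  geom <- do.call(rbind, lapply(ctx, `[[`, "geom"))
  gland_rows <- list(); core_rows <- list()
  for (f in seq_len(cfg$n_folds)) {
    cb <- codebooks[[sprintf("fold%d", f)]]
    train_ids <- labels$core_id[folds[labels$core_id] != f]
    val_ids <- labels$core_id[folds[labels$core_id] == f]
    tex_f <- tex[tex$codebook == sprintf("fold%d", f),
                 setdiff(names(tex), "codebook")]
    feats <- assemble_features(geom[c("core_id", "gland_id", "median_c")],
                               geom[c("core_id", "gland_id", "median_ls")],
                               tex_f, labels)
    model <- train_lda(feats[feats$core_id %in% train_ids, ],
                       shrinkage = cfg$shrinkage)
    check_no_leakage(cb$source_cores, val_ids, "texton codebook")
    check_no_leakage(model$training_cores, val_ids, "LDA model")
    fv <- feats[feats$core_id %in% val_ids, ]
    scores <- predict_lda(model, fv)
    gland_rows[[f]] <- data.frame(core_id = fv$core_id, gland_id = fv$gland_id,
                                  label = fv$label, fold = f, score = scores)
    for (id in val_ids) {
      s <- scores[fv$core_id == id]
      lab <- labels$label[labels$core_id == id]
      core_rows[[length(core_rows) + 1L]] <- data.frame(
        core_id = id, label = lab, fold = f,
        score_mean = mean(s), score_median = stats::median(s),
        score_sd = stats::sd(s), n_glands = length(s))
    }
  }
  core_scores <- do.call(rbind, core_rows)
  rownames(core_scores) <- NULL
  roc_mean <- roc_analysis(core_scores$score_mean, core_scores$label)
  roc_median <- roc_analysis(core_scores$score_median, core_scores$label)
  structure(
    list(core_scores = core_scores,
         gland_scores = do.call(rbind, gland_rows),
         roc = if (cfg$aggregation == "mean") roc_mean else roc_median,
         roc_mean = roc_mean, roc_median = roc_median,
         folds = folds, config = cfg),
    class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("<CVResult> %d cores, %d folds\n",
              nrow(x$core_scores), x$config$n_folds))
  cat(sprintf("  mean aggregation:   AUC %.3f, sens %.2f, spec %.2f\n",
              x$roc_mean$auc, x$roc_mean$operating_point$sensitivity,
              x$roc_mean$operating_point$specificity))
  cat(sprintf("  median aggregation: AUC %.3f, sens %.2f, spec %.2f\n",
              x$roc_median$auc, x$roc_median$operating_point$sensitivity,
              x$roc_median$operating_point$specificity))
  invisible(x)
}

#' Run feature extraction over a cohort
#'
#' Computes the full 52-dimensional gland feature table for a cohort using a
#' single texton codebook fitted on all cores (no cross-validation; for CV
#' use [threefold_cv()], which refits the codebook per training split).
#'
#' @param cohort List with `cores` and `labels`.
#' @param cfg A [pipeline_config()].
#' @return Data frame from [assemble_features()].
#' @export
run_features <- function(cohort, cfg = pipeline_config()) {
  bank <- build_lm_bank()
  ctx <- lapply(cohort$labels$core_id, function(id)
    extract_core_features(cohort$cores[[id]], cfg, bank))
  names(ctx) <- cohort$labels$core_id
  cb <- fit_textons(do.call(rbind, lapply(ctx, `[[`, "samples")),
                    K = cfg$K, seed = derive_seed(cfg$seed, "kmeans"),
                    source_cores = cohort$labels$core_id)
  tex <- do.call(rbind, lapply(cohort$labels$core_id, function(id)
    core_texture_features(cohort$cores[[id]], cfg, bank, list(all = cb))))
  geom <- do.call(rbind, lapply(ctx, `[[`, "geom"))
  assemble_features(geom[c("core_id", "gland_id", "median_c")],
                    geom[c("core_id", "gland_id", "median_ls")],
                    tex[setdiff(names(tex), "codebook")],
                    cohort$labels)
}

#' Run the full synthetic-cohort evaluation
#'
#' Generates a synthetic cohort, runs three-fold cross-validation, and
#' returns (optionally writes) a summary report.
#'
#' @param synth_cfg A [synthetic_cohort_config()].
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory for `core_scores.csv`, `roc.csv` and
#'   `summary.json`.
#' @return List with `cv` (a `CVResult`) and `summary` (named list of
#'   headline numbers).
#' @export
run_all <- function(synth_cfg = synthetic_cohort_config(),
                    cfg = pipeline_config(), out_dir = NULL) {
  cohort <- generate_cohort(synth_cfg)
  cv <- threefold_cv(cohort, cfg)
  summary <- list(
    n_cores = nrow(cv$core_scores),
    aggregation = cfg$aggregation,
    auc = cv$roc$auc,
    sensitivity = cv$roc$operating_point$sensitivity,
    specificity = cv$roc$operating_point$specificity,
    operating_threshold = cv$roc$operating_point$threshold,
    auc_mean_agg = cv$roc_mean$auc,
    auc_median_agg = cv$roc_median$auc,
    seed = cfg$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cv$core_scores, file.path(out_dir, "core_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(threshold = cv$roc$thresholds,
                 sensitivity = cv$roc$sensitivity,
                 specificity = cv$roc$specificity),
      file.path(out_dir, "roc.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cv = cv, summary = summary)
}
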