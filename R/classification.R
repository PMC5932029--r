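#' Assemble gland feature vectors
#'
#' Joins the three per-gland feature families into the combined predictor:
#' median perimeter curvature, median scattering mean free path, and the
#' 50-dimensional texton-histogram texture descriptor, in that fixed column
#' order — 52 dimensions in total. Glands missing any family, or carrying a
#' non-finite value, are dropped with a message.
#'
#' @param curvature Data frame `core_id, gland_id, median_c`.
#' @param scattering Data frame `core_id, gland_id, median_ls`.
#' @param texture Data frame `core_id, gland_id, T1..TK`.
#' @param labels Data frame `core_id, label`.
#' @return Data frame with columns `core_id`, `gland_id`, `label`,
#'   `median_c`, `median_ls`, `T1..TK`, sorted by core then gland.
#' @export
assemble_features <- function(curvature, scattering, texture, labels) {
  key <- function(d) paste(d$core_id, d$gland_id, sep = "\r")
  m1 <- merge(curvature, scattering, by = c("core_id", "gland_id"))
  m2 <- merge(m1, texture, by = c("core_id", "gland_id"))
  dropped <- setdiff(unique(c(key(curvature), key(scattering), key(texture))),
                     key(m2))
  feat_cols <- setdiff(names(m2), c("core_id", "gland_id"))
  finite <- apply(as.matrix(m2[, feat_cols]), 1, function(r) all(is.finite(r)))
  if (any(!finite))
    dropped <- c(dropped, key(m2)[!finite])
  if (length(dropped))
    message(sprintf("assemble_features: dropped %d gland(s) with missing or non-finite features: %s",
                    length(dropped),
                    paste(gsub("\r", "/", dropped), collapse = ", ")))
  m2 <- m2[finite, , drop = FALSE]
  lab <- stats::setNames(labels$label, labels$core_id)
  unknown <- setdiff(unique(m2$core_id), names(lab))
  if (length(unknown))
    stop(sprintf("core id(s) missing from label table: %s",
                 paste(unknown, collapse = ", ")))
  out <- data.frame(core_id = m2$core_id, gland_id = m2$gland_id,
                    label = unname(lab[m2$core_id]),
                    m2[, feat_cols, drop = FALSE])
  out <- out[order(out$core_id, out$gland_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("core_id", "gland_id", "label"))
  as.matrix(features[, cols, drop = FALSE])
}

#' Train a two-class linear discriminant on gland features
#'
#' Standard two-class LDA with a shared within-class covariance. Because the
#' 52-dimensional predictor is estimated from at most a few hundred glands —
#' and the texture block sums to 1, making the pooled covariance exactly
#' singular — the covariance is shrunk toward a scaled identity,
#' `(1 - lambda) S + lambda * mean(diag(S)) * I`. With `shrinkage = "auto"`
#' the intensity is the Ledoit-Wolf-style estimate (clamped to a small
#' positive floor); `shrinkage = 0` recovers plain LDA.
#'
#' The malignancy likelihood of a gland is its posterior probability of the
#' malignant class under the fitted Gaussian model (equal priors by default).
#'
#' @param features Feature data frame from [assemble_features()] (training
#'   glands only), or a bare numeric matrix.
#' @param labels Class labels (`benign`/`malignant`); taken from `features`
#'   when omitted.
#' @param shrinkage `"auto"` or a number in \[0, 1\].
#' @param priors Named prior probabilities for `benign` and `malignant`.
#' @return An `LDAModel`: list with weights `w`, intercept `b`, class means,
#'   shrinkage used, and the training core ids (for leakage checks).
#' @export
train_lda <- function(features, labels = NULL, shrinkage = "auto",
                      priors = c(benign = 0.5, malignant = 0.5)) {
  if (is.data.frame(features)) {
    labels <- labels %||% features$label
    x <- feature_matrix(features)
    cores <- unique(features$core_id)
  } else {
    x <- as.matrix(features)
    cores <- character()
  }
  y <- as.character(labels)
  if (!all(y %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'")
  if (length(unique(y)) < 2)
    stop("training set contains a single class; LDA needs both")
  if (min(table(y)) < 2)
    stop("need at least 2 glands per class to estimate the covariance")
  if (any(!is.finite(x))) stop("non-finite entries in the feature matrix")
  mu0 <- colMeans(x[y == "benign", , drop = FALSE])
  mu1 <- colMeans(x[y == "malignant", , drop = FALSE])
  xc <- x
  xc[y == "benign", ] <- sweep(x[y == "benign", , drop = FALSE], 2, mu0)
  xc[y == "malignant", ] <- sweep(x[y == "malignant", , drop = FALSE], 2, mu1)
  n <- nrow(x)
  S <- crossprod(xc) / (n - 2)
  lambda <- if (identical(shrinkage, "auto")) lw_shrinkage(xc) else as.numeric(shrinkage)
  if (lambda < 0 || lambda > 1) stop("shrinkage must lie in [0, 1]")
  nu <- mean(diag(S))
  Sr <- (1 - lambda) * S + diag(lambda * nu, ncol(S))
  ch <- tryCatch(chol(Sr), error = function(e)
    stop("pooled covariance is singular even after shrinkage; increase `shrinkage`"))
  w <- backsolve(ch, backsolve(ch, mu1 - mu0, transpose = TRUE))
  b <- -sum(w * (mu0 + mu1)) / 2 + log(priors[["malignant"]] / priors[["benign"]])
  structure(
    list(w = w, b = b, mu_benign = mu0, mu_malignant = mu1,
         shrinkage = lambda, priors = priors,
         training_cores = as.character(cores)),
    class = "LDAModel")
}

# Ledoit-Wolf-style shrinkage intensity toward nu*I, computed from the
# class-centered data (Schafer-Strimmer form).
lw_shrinkage <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  S <- crossprod(xc) / n
  nu <- mean(diag(S))
  # variance of the entries of S
  x2 <- xc * xc
  varS <- (crossprod(x2) / n - S^2) / n
  num <- sum(varS)
  den <- sum((S - diag(nu, p))^2)
  if (den <= 0) return(1)
  min(1, max(num / den, 1e-3))
}

#' Gland malignancy likelihoods from a trained LDA model
#'
#' @param model An [train_lda()] model.
#' @param features Feature data frame or matrix of glands to score.
#' @return Numeric vector of posterior probabilities of malignancy in
#'   \[0, 1\].
#' @export
predict_lda <- function(model, features) {
  stopifnot(inherits(model, "LDAModel"))
  x <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  if (ncol(x) != length(model$w))
    stop("feature dimensionality does not match the model")
  z <- drop(x %*% model$w) + model$b
  1 / (1 + exp(-z))
}

#' Aggregate gland likelihoods into a core-level score
#'
#' The core's malignancy score is the mean (reference configuration) or the
#' median of the likelihood scores of its glands.
#'
#' @param gland_scores Numeric vector of gland likelihoods in \[0, 1\].
#' @param core_id Core identifier.
#' @param label True class label, if known.
#' @param aggregation `"mean"` or `"median"`.
#' @return A `CoreScore`: list with `core_id`, `gland_scores`, `core_score`,
#'   `aggregation`, `label`, and `score_sd` (spread of gland scores).
#' @export
score_core <- function(gland_scores, core_id, label = NA_character_,
                       aggregation = c("mean", "median")) {
  aggregation <- match.arg(aggregation)
  if (!length(gland_scores)) stop("a core needs at least one gland score")
  agg <- if (aggregation == "mean") mean(gland_scores) else
    stats::median(gland_scores)
  structure(
    list(core_id = as.character(core_id), gland_scores = gland_scores,
         core_score = agg, aggregation = aggregation, label = label,
         score_sd = stats::sd(gland_scores)),
    class = "CoreScore")
}

#' Stratified near-equal fold assignment of cores
#'
#' Cores (not glands) are split into `n_folds` nearly equal groups,
#' stratified by class so every training split contains both classes.
#'
#' @param core_ids Character vector of core identifiers.
#' @param labels Class label per core.
#' @param n_folds Number of folds (default 3).
#' @param seed RNG seed.
#' @return Integer fold index per core (named by core id).
#' @export
assign_folds <- function(core_ids, labels, n_folds = 3, seed = 1L) {
  stopifnot(length(core_ids) == length(labels))
  fold <- integer(length(core_ids))
  with_seed(seed, {
    classes <- unique(labels)
    for (ci in seq_along(classes)) {
      i <- which(labels == classes[ci])
      if (length(i) < n_folds)
        stop(sprintf("class '%s' has %d core(s); need at least %d for %d-fold CV",
                     classes[ci], length(i), n_folds, n_folds))
      # rotate which folds take this class's overflow so overall fold sizes
      # stay nearly equal (68 cores -> 23/23/22)
      base <- (rep_len(seq_len(n_folds), length(i)) + ci - 2L) %% n_folds + 1L
      fold[i] <- sample(base)
    }
  })
  stats::setNames(fold, core_ids)
}

#' Guard against train/validation leakage
#'
#' Errors when a model or codebook fitted on `training_cores` is about to
#' score one of its own cores.
#'
#' @param training_cores Core ids the object was fitted on.
#' @param scoring_cores Core ids about to be scored.
#' @param what Description used in the error message.
#' @return `TRUE` invisibly.
#' @export
check_no_leakage <- function(training_cores, scoring_cores, what = "model") {
  overlap <- intersect(training_cores, scoring_cores)
  if (length(overlap))
    stop(sprintf(
      "leakage: %s was fitted on validation core(s) %s",
      what, paste(overlap, collapse = ", ")))
  invisible(TRUE)
}

#' ROC analysis of core scores
#'
#' Sweeps a threshold over the pooled core scores (malignant = positive
#' class), computing sensitivity and specificity at every cut, the area
#' under the curve by the trapezoidal rule, and the optimum operating point
#' under equal misclassification costs — the threshold maximizing
#' sensitivity + specificity, with ties broken toward higher sensitivity
#' (a missed cancer costs more than a false alarm in practice, so among
#' equally good cuts the more sensitive one is preferred).
#'
#' @param scores Numeric core scores (higher = more malignant).
#' @param labels Class label per core (`benign`/`malignant`).
#' @return A `ROCResult`: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, and `operating_point` (threshold, sensitivity,
#'   specificity).
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == "malignant"
  if (!any(pos) || all(pos)) stop("ROC needs both classes")
  if (length(unique(scores)) == 1) {
    warning("all core scores identical; ROC is uninformative (AUC 0.5)")
    return(structure(list(
      thresholds = unique(scores), sensitivity = 1, specificity = 0,
      auc = 0.5,
      operating_point = list(threshold = unique(scores), sensitivity = 1,
                             specificity = 0)), class = "ROCResult"))
  }
  # classify as malignant when score >= threshold
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), 0)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  j <- sens + spec
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec, auc = auc,
         operating_point = list(threshold = thr[best],
                                sensitivity = sens[best],
                                specificity = spec[best])),
    class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("<ROCResult> AUC %.3f; operating point: threshold %.3f, sensitivity %.2f, specificity %.2f\n",
              x$auc, x$operating_point$threshold,
              x$operating_point$sensitivity, x$operating_point$specificity))
  invisible(x)
}
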