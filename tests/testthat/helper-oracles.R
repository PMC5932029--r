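# Independent oracles and fixture builders used across the test files.

# Independent ImageJ ROI encoder (written from the format description, not
# via the package's writer): big-endian 64-byte header + relative shorts.
encode_roi_independent <- function(vertices, path, type_code = 0L) {
  v <- round(as.matrix(vertices))
  left <- min(v[, 1]); top <- min(v[, 2])
  con <- file(path, "wb")
  on.exit(close(con))
  be2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  writeBin(charToRaw("Iout"), con)
  be2(218L)                                 # an older format version
  writeBin(as.raw(c(type_code, 0L)), con)
  be2(top); be2(left); be2(max(v[, 2])); be2(max(v[, 1]))
  be2(nrow(v))
  writeBin(raw(46), con)                    # pad header to 64 bytes
  be2(v[, 1] - left)
  be2(v[, 2] - top)
  invisible(path)
}

# Curvature of each vertex as 1/R of the circumcircle through its
# neighboring triple (brute-force geometric oracle).
circumcircle_curvature <- function(v) {
  n <- nrow(v)
  vapply(seq_len(n), function(i) {
    p1 <- v[if (i == 1) n else i - 1, ]
    p2 <- v[i, ]
    p3 <- v[if (i == n) 1 else i + 1, ]
    a <- sqrt(sum((p2 - p1)^2)); b <- sqrt(sum((p3 - p2)^2))
    cc <- sqrt(sum((p3 - p1)^2))
    cross <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    area <- abs(cross) / 2
    if (area == 0) 0 else 4 * area / (a * b * cc)
  }, 0)
}

# Brute-force point-in-polygon (even-odd ray casting at pixel centers).
brute_force_mask <- function(vertices, shape) {
  inside <- function(px, py) {
    n <- nrow(vertices)
    x <- vertices[, 1]; y <- vertices[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cnt <- 0
    for (e in seq_len(n)) {
      if ((y[e] <= py && yn[e] > py) || (yn[e] <= py && y[e] > py)) {
        xi <- x[e] + (py - y[e]) / (yn[e] - y[e]) * (xn[e] - x[e])
        if (xi > px) cnt <- cnt + 1
        if (abs(xi - px) < 1e-9) return(TRUE)   # boundary pixel: include
      }
      # horizontal edge through the pixel row
      if (y[e] == py && yn[e] == py &&
          px >= min(x[e], xn[e]) && px <= max(x[e], xn[e])) return(TRUE)
    }
    cnt %% 2 == 1
  }
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) for (cl in seq_len(shape[2]))
    m[r, cl] <- inside(cl - 1, r - 1)
  m
}

# Mann-Whitney AUC by exhaustive pair counting.
pair_count_auc <- function(scores, labels) {
  sm <- scores[labels == "malignant"]; sb <- scores[labels == "benign"]
  mean(outer(sm, sb, `>`) + 0.5 * outer(sm, sb, `==`))
}

# A small deterministic simple polygon (randomized star shape) for
# curvature property tests.
random_star_polygon <- function(n, seed, radius = 50) {
  set.seed(seed)
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- radius * (1 + 0.3 * stats::runif(n, -1, 1))
  cbind(x = r * cos(th), y = r * sin(th))
}

# A tiny in-memory cohort for pipeline tests.
tiny_cohort <- function(n_per_class = 3, seed = 42, effect = "strong",
                        image_edge = 384) {
  generate_cohort(synthetic_cohort_config(
    n_benign = n_per_class, n_malignant = n_per_class, image_edge = image_edge,
    glands_per_core = c(2, 2), effect = effect, seed = seed))
}

fast_cfg <- function(seed = 1, n_samples = 800, K = 12) {
  pipeline_config(n_samples = n_samples, K = K, seed = seed)
}

# Round a double matrix through IEEE float32 precision.
float32_round <- function(m) {
  matrix(readBin(writeBin(as.numeric(m), raw(), size = 4), "numeric",
                 length(m), size = 4), nrow(m), ncol(m))
}

# Smooth random field (for downsampling mean-preservation checks).
gauss_smooth_fixture <- function(n) {
  z <- matrix(stats::rnorm(n * n), n, n)
  k <- stats::dnorm(seq(-12, 12), sd = 4)
  k <- k / sum(k)
  z <- apply(z, 2, function(col) stats::filter(c(rev(col[1:12]), col,
                                                 rev(col[(n - 11):n])),
                                               k, sides = 2)[13:(n + 12)])
  z <- t(apply(t(z), 2, function(col) stats::filter(c(rev(col[1:12]), col,
                                                      rev(col[(n - 11):n])),
                                                    k, sides = 2)[13:(n + 12)]))
  z + 1
}
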