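test_that("the default filter bank has 58 L1-normalized kernels", {
  bank <- build_lm_bank()
  expect_length(bank$kernels, 58)
  expect_equal(as.integer(table(bank$info$family)[c("edge", "bar", "log",
                                                    "gaussian")]),
               c(18L, 18L, 14L, 8L))
  for (i in seq_along(bank$kernels)) {
    expect_equal(sum(abs(bank$kernels[[i]])), 1, tolerance = 1e-12)
    if (bank$info$family[i] %in% c("edge", "bar", "log"))
      expect_lt(abs(sum(bank$kernels[[i]])), 1e-10)
  }
})

test_that("first-derivative kernels are odd under a 180-degree rotation", {
  b0 <- build_lm_bank(orientations = 1, deriv_scales = 2,
                      log_scales = 1, gauss_scales = 1)
  k0 <- b0$kernels[[which(b0$info$family == "edge")[1]]]
  k_pi <- glandmark:::oriented_gaussian_deriv(
    matrix(rep(-24:24, each = 49), 49), matrix(rep(-24:24, 49), 49),
    sc = 2, theta = pi, order = 1)
  k_pi <- k_pi - mean(k_pi); k_pi <- k_pi / sum(abs(k_pi))
  expect_equal(k_pi, -k0, tolerance = 1e-12)
})

test_that("filter responses obey convolution identities", {
  bank <- build_lm_bank()
  # constant image: zero response on every zero-mean kernel
  r <- filter_responses(matrix(0.7, 60, 60), bank)
  zm <- which(bank$info$family %in% c("edge", "bar", "log"))
  expect_lt(max(abs(r[, , zm])), 1e-12)
  # impulse: the convolution of a delta reproduces each kernel
  imp <- matrix(0, 60, 60); imp[30, 30] <- 1
  ri <- filter_responses(imp, bank)
  for (i in c(1, 19, 40, 58)) {
    expect_equal(ri[(30 - 24):(30 + 24), (30 - 24):(30 + 24), i],
                 bank$kernels[[i]], tolerance = 1e-12)
  }
  # a vertical step edge responds most strongly to the matching edge kernel
  step <- matrix(0, 72, 72); step[, 37:72] <- 1
  rs <- filter_responses(step, bank)
  resp_mag <- abs(rs[36, 36, ])
  edge_idx <- which(bank$info$family == "edge")
  best <- edge_idx[which.max(resp_mag[edge_idx])]
  # a vertical step varies along x: the derivative axis v = -sin(theta) x +
  # cos(theta) y aligns with x at theta = pi/2
  expect_equal(bank$info$orientation[best], pi / 2)
  expect_equal(best, which.max(resp_mag))
  expect_error(filter_responses(matrix(0, 10, 10), bank), "smaller")
})

test_that("response sampling is deterministic, exhaustive when short, and unbiased", {
  set.seed(31)
  resp <- array(rnorm(40 * 40 * 3), dim = c(40, 40, 3))
  mask <- matrix(FALSE, 40, 40); mask[5:30, 5:30] <- TRUE
  s1 <- sample_responses(resp, mask, n_samples = 100, seed = 7)
  s2 <- sample_responses(resp, mask, n_samples = 100, seed = 7)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(100L, 3L))
  s3 <- sample_responses(resp, mask, n_samples = 1e6, seed = 7)
  expect_equal(nrow(s3), sum(mask))     # exhaustion: all pixels
  const <- array(2.5, dim = c(40, 40, 3))
  expect_equal(colMeans(sample_responses(const, mask, 50, seed = 1)),
               rep(2.5, 3))
  expect_error(sample_responses(resp, matrix(FALSE, 40, 40), 10, 1), "empty")
})

test_that("sparse patch responses equal the full convolution", {
  set.seed(32)
  bank <- build_lm_bank()
  m <- matrix(rnorm(90 * 80), 90, 80)
  full <- filter_responses(m, bank)
  px <- cbind(c(2, 30, 89, 45), c(75, 3, 40, 41))
  sparse <- responses_at_pixels(m, px, bank)
  for (i in seq_len(nrow(px)))
    expect_equal(sparse[i, ], full[px[i, 1], px[i, 2], ], tolerance = 1e-12)
})

test_that("k-means textons satisfy closed-form cases", {
  set.seed(33)
  pts <- matrix(rnorm(15), 5, 3)
  x <- pts[rep(1:5, each = 30), ]
  cb <- fit_textons(x, K = 5, seed = 2)
  expect_equal(cb$sse, 0, tolerance = 1e-10)
  expect_equal(cb$centroids[order(cb$centroids[, 1]), ],
               pts[order(pts[, 1]), ], tolerance = 1e-12, ignore_attr = TRUE)
  cb1 <- fit_textons(x, K = 1, seed = 2)
  expect_equal(drop(cb1$centroids), colMeans(x), tolerance = 1e-12)
  expect_error(fit_textons(x[1:3, ], K = 5, seed = 1), "exceeds")
})

test_that("k-means recovers well-separated mixture means and lowers SSE monotonically", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 400
    x <- rbind(matrix(rnorm(n * 2, 0, 0.5), ncol = 2),
               matrix(rnorm(n * 2, 8, 0.5), ncol = 2))
    cb <- fit_textons(x, K = 2, seed = s)
    cents <- cb$centroids[order(cb$centroids[, 1]), ]
    se <- 0.5 / sqrt(n)
    expect_lt(max(abs(cents[1, ] - 0)), 3 * se * 3)
    expect_lt(max(abs(cents[2, ] - 8)), 3 * se * 3)
    expect_true(all(diff(cb$sse_trace) <= 1e-9))
    # agreement with an independent implementation on the same task
    km <- stats::kmeans(x, centers = cents, iter.max = 50,
                        algorithm = "Lloyd")
    expect_equal(km$centers[order(km$centers[, 1]), ], cents,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("texton assignment matches a brute-force nearest-centroid search", {
  set.seed(34)
  cb <- structure(list(centroids = matrix(rnorm(50 * 6), 50, 6), K = 50,
                       source_cores = character()),
                  class = "TextonCodebook")
  x <- matrix(rnorm(300 * 6), 300, 6)
  a <- assign_textons(x, cb)
  brute <- apply(x, 1, function(r)
    which.min(colSums((t(cb$centroids) - r)^2)))
  expect_equal(a, brute)
  # exact centroid hit and tie rule
  expect_equal(assign_textons(cb$centroids[7, , drop = FALSE], cb), 7L)
  tie_cb <- structure(list(centroids = rbind(c(0, 0), c(2, 0), c(0, 2),
                                             c(2, 0)), K = 4,
                           source_cores = character()),
                      class = "TextonCodebook")
  # (2, 1) is equidistant from the identical centroids 2 and 4: lowest wins
  expect_equal(assign_textons(matrix(c(2, 1), 1), tie_cb), 2L)
})

test_that("windowed texton histograms match a naive sliding-window count", {
  set.seed(35)
  K <- 6
  tr <- matrix(sample.int(K, 64 * 64, replace = TRUE), 64, 64)
  th <- texton_histograms(tr, K, window_edge = 9)
  expect_lt(max(abs(apply(th, c(1, 2), sum) - 1)), 1e-12)
  p <- glandmark:::pad_reflect(tr, 4, 4, 4, 4)
  for (i in c(1, 13, 64)) for (j in c(5, 40, 64)) {
    win <- p[i:(i + 8), j:(j + 8)]
    expect_equal(th[i, j, ], tabulate(win, K) / 81, tolerance = 1e-12)
  }
  # uniform raster: histogram is a basis vector, and so is the gland feature
  tr3 <- matrix(3L, 32, 32)
  mask <- matrix(TRUE, 32, 32)
  expect_equal(texton_histogram_feature(tr3, mask, K = 5, window_edge = 8),
               c(0, 0, 1, 0, 0))
  half <- cbind(matrix(3L, 16, 8), matrix(5L, 16, 8))
  hh <- texton_histograms(half, K = 5, window_edge = 16)
  expect_equal(hh[8, 8, ], c(0, 0, 0.5, 0, 0.5))
})

test_that("gland texture features match the per-pixel histogram medians", {
  set.seed(36)
  K <- 5
  tr <- matrix(sample.int(K, 48 * 48, replace = TRUE), 48, 48)
  mask <- matrix(FALSE, 48, 48); mask[10:35, 12:40] <- TRUE
  tv <- texton_histogram_feature(tr, mask, K, window_edge = 7)
  th <- texton_histograms(tr, K, window_edge = 7)
  ref <- vapply(seq_len(K), function(k) median(th[, , k][mask]), 0)
  ref <- ref / sum(ref)
  expect_equal(tv, ref, tolerance = 1e-12)
  expect_equal(sum(tv), 1, tolerance = 1e-12)
  expect_error(texton_histogram_feature(tr, mask & FALSE, K, 7), "empty")
})

test_that("texture features alone separate the generator's texture classes", {
  # linear probe on the texture descriptor only, small patches, held-out eval
  K <- 8
  bank <- build_lm_bank()
  featurize <- function(class, seed) {
    p <- synthetic_class_params(class)
    core <- generate_core(class, p, seed = seed, image_edge = 288,
                          n_glands = 1)
    g <- core$annotations[[1]]
    mask <- rasterize_gland_mask(g, c(288, 288))
    resp <- filter_responses(core$image$pixels, bank)
    list(resp = resp, mask = mask, core_id = g$core_id)
  }
  accs <- vapply(1:3, function(rep) {
    train_b <- lapply(1:2, function(i) featurize("benign", 600 + 10 * rep + i))
    train_m <- lapply(1:2, function(i) featurize("malignant", 700 + 10 * rep + i))
    samples <- do.call(rbind, lapply(c(train_b, train_m), function(fz)
      sample_responses(fz$resp, fz$mask, 800, seed = rep)))
    cb <- fit_textons(samples, K = K, seed = rep)
    tex_of <- function(fz) {
      a <- assign_textons(fz$resp, cb)
      texton_histogram_feature(a, fz$mask, K, window_edge = 30)
    }
    xtr <- do.call(rbind, lapply(c(train_b, train_m), tex_of))
    model <- train_lda(xtr, rep(c("benign", "malignant"), each = 2),
                       shrinkage = 0.2)
    correct <- 0
    for (s in 1:3) {
      tb <- featurize("benign", 800 + 10 * rep + s)
      tm <- featurize("malignant", 900 + 10 * rep + s)
      correct <- correct + (predict_lda(model, rbind(tex_of(tb))) < 0.5) +
        (predict_lda(model, rbind(tex_of(tm))) >= 0.5)
    }
    correct / 6
  }, 0)
  expect_gt(mean(accs), 0.8)
})
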