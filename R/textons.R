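#' Per-pixel filter-bank responses
#'
#' Convolves the analysis-resolution phase image with every kernel of the
#' filter bank (true convolution, symmetric reflective boundary), producing a
#' response vector per pixel. The padded image spectrum is computed once and
#' kernel spectra are cached per bank and image size, so banks of many
#' kernels cost little more than one FFT per kernel.
#'
#' @param img A [phase_image()] (or bare numeric matrix) at the analysis
#'   resolution.
#' @param bank A [build_lm_bank()] filter bank.
#' @param pad `"reflect"` (default) reflects the image at its borders;
#'   `"none"` computes an unpadded circular convolution, valid only when the
#'   caller discards the outer half-kernel band of the output (used
#'   internally on crops that already carry a true-content margin).
#' @return A 3-D array `rows x cols x n_kernels` of responses, in bank order.
#' @export
filter_responses <- function(img, bank, pad = c("reflect", "none")) {
  stopifnot(inherits(bank, "FilterBank"))
  pad <- match.arg(pad)
  m <- if (inherits(img, "PhaseImage")) img$pixels else as.matrix(img)
  ks <- nrow(bank$kernels[[1]])
  if (min(dim(m)) < ks)
    stop(sprintf("image (%d x %d) is smaller than the %d x %d kernels",
                 nrow(m), ncol(m), ks, ks))
  pd <- prepare_conv(m, ks, ks, pad)
  out <- array(0, dim = c(nrow(m), ncol(m), length(bank$kernels)))
  for (i in seq_along(bank$kernels)) {
    out[, , i] <- conv2_reflect(m, bank$kernels[[i]], img_fft = pd$fft,
                                pad_info = pd,
                                cache_key = sprintf("%s_%02d", bank$id, i))
  }
  out
}

#' Filter-bank responses at selected pixels
#'
#' Computes the response vectors of a sparse set of pixels by direct
#' convolution (patch gather times kernel matrix), with symmetric reflective
#' padding at the raster border. Equivalent to indexing
#' [filter_responses()] at those pixels, but far cheaper when only a small
#' sample of pixels is needed (e.g. codebook-fitting samples).
#'
#' @param img Numeric matrix (or [phase_image()]) at the analysis resolution.
#' @param pixels Two-column matrix of (row, col) 1-based pixel indices.
#' @param bank A [build_lm_bank()] filter bank.
#' @return Matrix `nrow(pixels) x n_kernels` of responses in bank order.
#' @export
responses_at_pixels <- function(img, pixels, bank) {
  stopifnot(inherits(bank, "FilterBank"))
  m <- if (inherits(img, "PhaseImage")) img$pixels else as.matrix(img)
  ks <- nrow(bank$kernels[[1]])
  r <- (ks - 1L) %/% 2L
  p <- pad_reflect(m, r, r, r, r)
  np <- nrow(p)
  # convolution pairs the patch at offset (er, ec) with the flipped kernel
  kmat <- vapply(bank$kernels, function(k) as.vector(k[ks:1, ks:1]),
                 numeric(ks * ks))
  base <- (pixels[, 2] + r - 1L) * np + (pixels[, 1] + r)  # padded linear idx
  off <- as.vector(outer(-r:r, (-r:r) * np, `+`))
  patches <- matrix(p[outer(base, off, `+`)], nrow(pixels), ks * ks)
  patches %*% kmat
}

#' Sample response vectors from epithelial pixels
#'
#' Draws up to `n_samples` response vectors uniformly without replacement
#' from the pixels marked in `mask` (the union of annotated gland interiors).
#' When the mask holds fewer pixels than requested, all of them are taken.
#'
#' @param responses Response array from [filter_responses()].
#' @param mask Logical epithelial mask matching the first two dimensions.
#' @param n_samples Number of vectors to draw (reference configuration:
#'   10000 per core).
#' @param seed RNG seed making the draw reproducible.
#' @return Matrix `n x n_kernels` of sampled response vectors.
#' @export
sample_responses <- function(responses, mask, n_samples = 10000, seed = 1L) {
  stopifnot(length(dim(responses)) == 3,
            identical(dim(mask), dim(responses)[1:2]))
  idx <- which(mask)
  if (!length(idx)) stop("empty epithelial mask: nothing to sample")
  take <- if (length(idx) <= n_samples) idx else
    with_seed(seed, sample(idx, n_samples))
  d <- dim(responses)
  flat <- matrix(responses, d[1] * d[2], d[3])
  flat[take, , drop = FALSE]
}

#' Fit a texton codebook by k-means
#'
#' Clusters pooled training-set response vectors with k-means (squared
#' Euclidean distance, k-means++ initialization, Lloyd updates). Iteration
#' stops when cluster assignments stabilize or after `max_iter` rounds.
#' Clusters that empty out are reseeded to the point farthest from its
#' centroid. The cluster centroids are the textons.
#'
#' The codebook records the identifiers of the cores whose samples produced
#' it; downstream cross-validation uses this provenance to refuse scoring
#' any core that contributed to its own codebook.
#'
#' @param samples Matrix `n x d` of pooled response vectors (training cores
#'   only).
#' @param K Number of textons (reference configuration: 50).
#' @param seed RNG seed for initialization.
#' @param max_iter Iteration cap (default 300).
#' @param source_cores Character vector of contributing core identifiers.
#' @return A `TextonCodebook`: list with `centroids` (`K x d`), `K`,
#'   `fit_seed`, `sse` (final within-cluster sum of squares), `sse_trace`,
#'   `iterations`, and `source_cores`.
#' @export
fit_textons <- function(samples, K = 50, seed = 1L, max_iter = 300,
                        source_cores = character()) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (K > n)
    stop(sprintf("K = %d exceeds the number of samples (%d)", K, n))
  with_seed(seed, {
    cent <- kmeanspp_init(samples, K)
    fit <- lloyd_kmeans(samples, cent, max_iter)
  })
  if (any(duplicated(fit$centroids)))
    warning("texton codebook contains identical centroids")
  structure(
    list(centroids = fit$centroids, K = K, fit_seed = seed,
         sse = fit$sse_trace[length(fit$sse_trace)],
         sse_trace = fit$sse_trace, iterations = fit$iterations,
         source_cores = as.character(source_cores)),
    class = "TextonCodebook")
}

# k-means++ seeding: iteratively pick centers with probability proportional
# to squared distance from the nearest chosen center.
kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  xs <- rowSums(x * x)
  centers <- matrix(0, K, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- pmax(xs - 2 * drop(x %*% centers[1, ]) + sum(centers[1, ]^2), 0)
  if (K > 1) for (k in 2:K) {
    if (all(d2 == 0)) i <- sample.int(n, 1)
    else i <- sample.int(n, 1, prob = d2)
    centers[k, ] <- x[i, ]
    cand <- pmax(xs - 2 * drop(x %*% centers[k, ]) + sum(centers[k, ]^2), 0)
    d2 <- pmin(d2, cand)
  }
  centers
}

# Row-wise argmax with first-index tie breaking (much faster than max.col
# for tall matrices).
row_argmax <- function(m) {
  best <- m[, 1]
  idx <- rep.int(1L, nrow(m))
  for (k in seq_len(ncol(m))[-1]) {
    hit <- m[, k] > best
    if (any(hit)) {
      idx[hit] <- k
      best[hit] <- m[hit, k]
    }
  }
  list(idx = idx, value = best)
}

# Lloyd iterations with BLAS-backed distance computation; converges when the
# assignment vector stops changing. The nearest centroid maximizes
# 2 x.c - |c|^2, computed as one product with the augmented matrix [x, 1].
lloyd_kmeans <- function(x, centers, max_iter) {
  n <- nrow(x); K <- nrow(centers)
  xs <- rowSums(x * x)
  xa <- cbind(x, 1)
  assign_prev <- integer(n)
  sse_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ca <- rbind(2 * t(centers), -rowSums(centers * centers))
    am <- row_argmax(xa %*% ca)
    a <- am$idx
    sse <- sum(xs - am$value)
    sse_trace <- c(sse_trace, sse)
    counts <- tabulate(a, K)
    for (k in which(counts == 0)) {             # reseed empty clusters
      far <- which.max(xs - am$value)
      centers[k, ] <- x[far, ]
      a[far] <- k
      counts <- tabulate(a, K)
    }
    newc <- rowsum(x, a) / as.numeric(counts)
    if (identical(a, assign_prev)) {
      centers <- newc
      break
    }
    centers <- newc
    assign_prev <- a
  }
  list(centroids = centers, sse_trace = sse_trace, iterations = it)
}

#' Assign each pixel to its nearest texton
#'
#' @param responses Response array from [filter_responses()] (or an `n x d`
#'   matrix of response vectors).
#' @param codebook A [fit_textons()] codebook.
#' @return Integer raster (or vector) of texton indices in `1..K`; ties are
#'   broken toward the lowest index.
#' @export
assign_textons <- function(responses, codebook) {
  stopifnot(inherits(codebook, "TextonCodebook"))
  is_raster <- length(dim(responses)) == 3
  if (is_raster) {
    d <- dim(responses)
    flat <- matrix(responses, d[1] * d[2], d[3])
  } else flat <- as.matrix(responses)
  if (ncol(flat) != ncol(codebook$centroids))
    stop("response dimensionality does not match the codebook")
  ca <- rbind(2 * t(codebook$centroids),
              -rowSums(codebook$centroids^2))
  a <- row_argmax(cbind(flat, 1) %*% ca)$idx
  if (is_raster) matrix(a, d[1], d[2]) else a
}

#' Per-pixel texton histograms over a sliding window
#'
#' For each pixel, the normalized histogram of texton indices in the
#' surrounding `window_edge x window_edge` window (reference configuration:
#' 60 x 60), with symmetric reflective padding at the raster border. Each
#' histogram sums to 1.
#'
#' @param texton_raster Integer raster of texton indices from
#'   [assign_textons()].
#' @param K Number of textons.
#' @param window_edge Window edge in pixels (default 60; even windows lean
#'   one pixel toward the trailing side).
#' @return Array `rows x cols x K` of normalized histograms.
#' @export
texton_histograms <- function(texton_raster, K, window_edge = 60) {
  stopifnot(is.matrix(texton_raster))
  w2 <- as.numeric(window_edge)^2
  out <- array(0, dim = c(nrow(texton_raster), ncol(texton_raster), K))
  for (k in seq_len(K)) {
    out[, , k] <- box_sum_reflect((texton_raster == k) * 1, window_edge) / w2
  }
  out
}

#' Gland-level texture feature from texton histograms
#'
#' The 50-dimensional gland texture descriptor: the per-dimension (marginal)
#' median of the per-pixel texton histograms over the gland's pixels,
#' renormalized to sum 1.
#'
#' @param texton_raster Integer texton raster covering the gland.
#' @param gland_mask Logical mask of gland pixels (same dimensions).
#' @param K Number of textons.
#' @param window_edge Histogram window edge (default 60).
#' @return Numeric vector of length `K`, summing to 1.
#' @export
texton_histogram_feature <- function(texton_raster, gland_mask, K,
                                     window_edge = 60) {
  stopifnot(identical(dim(texton_raster), dim(gland_mask)))
  if (!any(gland_mask)) stop("empty gland mask")
  w <- as.integer(window_edge)
  lo <- (w - 1L) %/% 2L
  hi <- w - 1L - lo
  pt <- pad_reflect(texton_raster, lo, hi, lo, hi)
  gi <- which(gland_mask, arr.ind = TRUE)
  r <- gi[, 1]; cl <- gi[, 2]
  med <- numeric(K)
  w2 <- as.numeric(w)^2
  present <- which(tabulate(pt, K) > 0)   # absent textons count zero everywhere
  for (k in present) {
    # zero-border integral image of the texton-k indicator; window count at
    # a gland pixel is a 4-point lookup
    cc <- t(col_cumsum(t(col_cumsum((pt == k) * 1))))
    ii <- matrix(0, nrow(cc) + 1L, ncol(cc) + 1L)
    ii[-1L, -1L] <- cc
    counts <- ii[cbind(r + w, cl + w)] - ii[cbind(r, cl + w)] -
      ii[cbind(r + w, cl)] + ii[cbind(r, cl)]
    med[k] <- stats::median(counts) / w2
  }
  s <- sum(med)
  if (s == 0) stop("degenerate texture feature: all-zero histogram medians")
  med / s
}
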