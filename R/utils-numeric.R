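# Internal numeric helpers: reflective padding, FFT convolution with a
# kernel-spectrum cache, integral-image box sums, and scoped RNG seeding.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream label, staying inside
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

# Symmetric (edge-including) reflective padding of a matrix.
pad_reflect <- function(m, top, bottom = top, left = top, right = top) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(top < nr + 1, bottom < nr + 1, left < nc + 1, right < nc + 1)
  ri <- c(rev(seq_len(top)), seq_len(nr), nr + 1 - seq_len(bottom))
  ci <- c(rev(seq_len(left)), seq_len(nc), nc + 1 - seq_len(right))
  m[ri, ci, drop = FALSE]
}

# Smallest 5-smooth integer >= n (efficient FFT sizes).
good_fft_size <- function(n) {
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(k)
    k <- k + 1
  }
}

# Cache of kernel spectra keyed by (bank id, padded size).
.gm_fft_cache <- new.env(parent = emptyenv())

kernel_fft <- function(kernel, nr, nc, cache_key = NULL) {
  key <- if (is.null(cache_key)) NULL else sprintf("%s_%d_%d", cache_key, nr, nc)
  if (!is.null(key) && !is.null(.gm_fft_cache[[key]])) return(.gm_fft_cache[[key]])
  kp <- matrix(0, nr, nc)
  kp[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  kf <- fft(kp)
  if (!is.null(key)) .gm_fft_cache[[key]] <- kf
  kf
}

# 2-D convolution (true convolution, kernel flipped) of `img` with `kernel`,
# "same" output size, symmetric reflective boundary. When img_fft is supplied
# it must be the FFT of the reflect-padded image at size (nr_pad, nc_pad).
conv2_reflect <- function(img, kernel, img_fft = NULL, pad_info = NULL,
                          cache_key = NULL) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  rr <- (kr - 1L) %/% 2L; rc <- (kc - 1L) %/% 2L
  if (is.null(img_fft)) {
    pad <- prepare_conv(img, kr, kc)
    img_fft <- pad$fft; pad_info <- pad
  }
  kf <- kernel_fft(kernel, pad_info$nr, pad_info$nc, cache_key)
  full <- Re(fft(img_fft * kf, inverse = TRUE)) / (pad_info$nr * pad_info$nc)
  # kernel center at row rr+1: original pixel i sits at padded row i + top,
  # whose centered circular-convolution output lands at full row i + top + rr
  # (modulo the transform size when no padding was applied)
  ri <- (pad_info$top + rr + seq_len(nrow(img)) - 1L) %% pad_info$nr + 1L
  ci <- (pad_info$left + rc + seq_len(ncol(img)) - 1L) %% pad_info$nc + 1L
  full[ri, ci]
}

# Reflect-pad an image for kernels up to (kr, kc) and take its FFT once, so
# many kernels can be applied to the same image cheaply. The 2*rr reflect
# margin already separates opposite content edges by kr - 1 samples, so the
# circular convolution never wraps content into the "same" output region and
# no further zero padding is required.
prepare_conv <- function(img, kr, kc, pad = c("reflect", "none")) {
  pad <- match.arg(pad)
  rr <- (kr - 1L) %/% 2L; rc <- (kc - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  if (pad == "reflect") {
    nr <- good_fft_size(h + 2L * rr)
    nc <- good_fft_size(w + 2L * rc)
    pi_ <- pad_reflect(img, rr, rr, rc, rc)
    top <- rr; left <- rc
  } else {
    # caller guarantees the outer (kr-1)/2 band of the output is discarded:
    # circular wraparound then only ever touches that band
    nr <- good_fft_size(h); nc <- good_fft_size(w)
    pi_ <- img
    top <- 0L; left <- 0L
  }
  pp <- matrix(0, nr, nc)
  pp[seq_len(nrow(pi_)), seq_len(ncol(pi_))] <- pi_
  list(fft = fft(pp), nr = nr, nc = nc, top = top, left = left)
}

# Sliding-window box sums with symmetric reflective padding, via integral
# image. Window of edge k covers rows i - lo .. i + hi where lo = floor((k-1)/2)
# and hi = k - 1 - lo (even windows lean toward the trailing side).
box_sum_reflect <- function(m, k) {
  lo <- (k - 1L) %/% 2L
  hi <- k - 1L - lo
  p <- pad_reflect(m, lo, hi, lo, hi)
  # integral image with a zero border (two passes of column cumsums)
  cc <- t(col_cumsum(t(col_cumsum(p))))
  ii <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  ii[-1L, -1L] <- cc
  nr <- nrow(m); nc <- ncol(m)
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  ii[r1 + k, c1 + k, drop = FALSE] - ii[r1, c1 + k, drop = FALSE] -
    ii[r1 + k, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}

# Column-wise cumulative sums via one full-vector cumsum and a per-column
# carry correction (much faster than apply for wide matrices).
col_cumsum <- function(m) {
  n <- nrow(m)
  a <- matrix(cumsum(m), n)
  if (ncol(a) > 1) {
    carry <- c(0, a[n, -ncol(a)])
    a <- t(t(a) - carry)
  }
  a
}

# Separable Gaussian blur (kernel normalized to sum 1), reflective boundary.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g <- g / sum(g)
  p <- pad_reflect(m, r, r, r, r)
  # filter columns then rows via matrix products with a banded operator
  n1 <- nrow(p); n2 <- ncol(p)
  a <- matrix(0, nrow(m), n1)
  for (j in seq_len(2L * r + 1L)) {
    idx <- seq_len(nrow(m)) + j - 1L
    a[cbind(seq_len(nrow(m)), idx)] <- a[cbind(seq_len(nrow(m)), idx)] + g[j]
  }
  b <- matrix(0, n2, ncol(m))
  for (j in seq_len(2L * r + 1L)) {
    idx <- seq_len(ncol(m)) + j - 1L
    b[cbind(idx, seq_len(ncol(m)))] <- b[cbind(idx, seq_len(ncol(m)))] + g[j]
  }
  a %*% p %*% b
}

`%||%` <- function(a, b) if (is.null(a)) b else a
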