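test_that("a constant phase image yields no valid scattering length", {
  img <- phase_image(matrix(1.3, 40, 40), 1, thickness_um = 5)
  sm <- scattering_length_map(img, kernel_edge = 9)
  expect_true(all(is.na(sm$ls_pixels)))
  expect_equal(sm$n_zero_var, 40 * 40)
})

test_that("checkerboard phase gives ls = L / 0.25 in the interior", {
  cb <- outer(1:60, 1:60, function(i, j) (i + j) %% 2)
  img <- phase_image(cb, 1, thickness_um = 5)
  sm <- scattering_length_map(img, kernel_edge = 9)
  interior <- sm$ls_pixels[10:50, 10:50]
  # an odd window holds (k^2+1)/2 of one level: var = 0.25 (1 - k^-4)
  expect_equal(max(abs(interior - 20)), 0, tolerance = 20 * 1e-3)
})

test_that("ls recovers L/var for an i.i.d. Gaussian phase field", {
  set.seed(21)
  g <- matrix(rnorm(220 * 220, sd = 0.3), 220, 220)
  img <- phase_image(g, 1 / 6.2, thickness_um = 5)
  sm <- scattering_length_map(img, kernel_edge = 149)
  mid <- sm$ls_pixels[105:115, 105:115]
  expect_false(anyNA(mid))
  expect_equal(mean(mid), 5 / 0.09, tolerance = 0.05)
  # convergence: a larger kernel gets closer to the closed form
  sm2 <- scattering_length_map(img, kernel_edge = 75)
  err1 <- abs(mean(sm$ls_pixels, na.rm = TRUE) - 5 / 0.09)
  err2 <- abs(mean(sm2$ls_pixels, na.rm = TRUE) - 5 / 0.09)
  expect_lt(err1, err2 + 0.5)
})

test_that("ls obeys the exact invariances of the variance filter", {
  set.seed(22)
  g <- matrix(rnorm(80 * 80, sd = 0.4), 80, 80)
  s1 <- scattering_length_map(phase_image(g, 1, thickness_um = 5), 7)$ls_pixels
  # adding a constant leaves ls unchanged (shift invariance)
  s2 <- scattering_length_map(phase_image(g + 2.71, 1, thickness_um = 5), 7)$ls_pixels
  expect_equal(s2, s1, tolerance = 1e-9)
  # scaling phase by 2 scales ls by exactly 1/4 (power-of-two: bit-exact)
  s3 <- scattering_length_map(phase_image(2 * g, 1, thickness_um = 5), 7)$ls_pixels
  expect_identical(s3, s1 / 4)
  # halving L halves ls exactly
  s4 <- scattering_length_map(phase_image(g, 1, thickness_um = 2.5), 7)$ls_pixels
  expect_identical(s4, s1 / 2)
})

test_that("the variance kernel rescales with resolution to ~24 um extent", {
  expect_equal(ls_kernel_edge(1 / 6.2), 149L)
  expect_equal(ls_kernel_edge(1 / 1.59), 39L)
  expect_true(ls_kernel_edge(0.5) %% 2 == 1)
  img <- phase_image(matrix(rnorm(100), 10, 10), 1)
  expect_error(scattering_length_map(img, 11), "exceeds")
  expect_error(scattering_length_map(img, 4), "odd")
})

test_that("gland median ls excludes invalid pixels and errors when none valid", {
  ls <- matrix(20, 30, 30)
  ls[, 16:30] <- 40
  sm <- structure(list(ls_pixels = ls, kernel_edge = 5, thickness_um = 5,
                       n_zero_var = 0), class = "ScatteringMap")
  mask <- matrix(FALSE, 30, 30)
  mask[11:20, 11:20] <- TRUE                  # straddles both halves equally
  expect_equal(median_ls(sm, mask), 30)
  uni <- matrix(TRUE, 30, 30)
  sm$ls_pixels[] <- 20
  expect_equal(median_ls(sm, uni), 20)
  sm$ls_pixels[] <- NA_real_
  expect_error(median_ls(sm, uni), "no valid")
})

test_that("malignant synthetic glands have longer ls than benign", {
  wins <- 0L; n_rep <- 10L
  for (s in seq_len(n_rep)) {
    b <- generate_core("benign", synthetic_class_params("benign"),
                       seed = 500 + s, image_edge = 288, n_glands = 1)
    m <- generate_core("malignant", synthetic_class_params("malignant"),
                       seed = 500 + s, image_edge = 288, n_glands = 1)
    lb <- median_ls(scattering_length_map(b$image),
                    rasterize_gland_mask(b$annotations[[1]], c(288, 288)))
    lm <- median_ls(scattering_length_map(m$image),
                    rasterize_gland_mask(m$annotations[[1]], c(288, 288)))
    wins <- wins + (lm > lb)
  }
  expect_gte(wins, 9L)
})
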