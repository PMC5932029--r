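make_feature_df <- function(n, label, core_ids, seed = 1, shift = 0) {
  set.seed(seed)
  tex <- matrix(rexp(n * 50), n, 50)
  tex <- tex / rowSums(tex)
  df <- data.frame(core_id = core_ids, gland_id = sprintf("g%d", seq_len(n)),
                   label = label, median_c = rnorm(n, 0.03 + shift, 0.005),
                   median_ls = rnorm(n, 50 + 100 * shift, 5))
  df[paste0("T", 1:50)] <- tex
  df
}

test_that("assembled gland feature vectors have 1 + 1 + 50 = 52 dimensions", {
  curv <- data.frame(core_id = "c1", gland_id = c("g1", "g2"),
                     median_c = c(0.02, 0.04))
  scat <- data.frame(core_id = "c1", gland_id = c("g1", "g2"),
                     median_ls = c(30, 45))
  tex <- data.frame(core_id = "c1", gland_id = c("g1", "g2"))
  tex[paste0("T", 1:50)] <- as.list(rep(1 / 50, 50))
  labels <- data.frame(core_id = "c1", label = "benign")
  f <- assemble_features(curv, scat, tex, labels)
  x <- f[, setdiff(names(f), c("core_id", "gland_id", "label"))]
  expect_equal(ncol(x), 52)
  expect_equal(names(x)[1:2], c("median_c", "median_ls"))
  expect_equal(rowSums(f[paste0("T", 1:50)]), c(1, 1), ignore_attr = TRUE)
  # a gland missing one family is dropped with a message
  expect_message(
    f2 <- assemble_features(curv, scat[1, ], tex, labels), "dropped")
  expect_equal(nrow(f2), 1)
  # permuting input order leaves the sorted table unchanged
  f3 <- assemble_features(curv[2:1, ], scat[2:1, ], tex, labels)
  expect_equal(f3, f)
})

test_that("LDA reproduces the closed-form 1-D threshold and separates wide classes", {
  set.seed(41)
  x <- matrix(c(rnorm(300, 0, 1), rnorm(300, 4, 1)), ncol = 1)
  y <- rep(c("benign", "malignant"), each = 300)
  m <- train_lda(x, y, shrinkage = 0)
  # equal priors: decision threshold is the midpoint of the class means
  expect_equal(-m$b / m$w, (mean(x[1:300]) + mean(x[301:600])) / 2,
               tolerance = 1e-6)
  # far-separated isotropic classes: training accuracy 1
  x2 <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 2),
              matrix(rnorm(60, 10, 0.3), ncol = 2))
  y2 <- rep(c("benign", "malignant"), each = 30)
  m2 <- train_lda(x2, y2, shrinkage = 0)
  expect_equal(mean((predict_lda(m2, x2) >= 0.5) == (y2 == "malignant")), 1)
  expect_error(train_lda(x2, rep("benign", 60)), "single class")
})

test_that("shrinkage LDA matches MASS::lda posteriors when shrinkage is 0", {
  skip_if_not_installed("MASS")
  set.seed(42)
  x <- rbind(matrix(rnorm(200, 0), ncol = 4),
             matrix(rnorm(200, 1.5), ncol = 4))
  y <- rep(c("benign", "malignant"), each = 50)
  m <- train_lda(x, y, shrinkage = 0)
  ref <- MASS::lda(x, grouping = y, prior = c(0.5, 0.5))
  post <- predict(ref, x)$posterior[, "malignant"]
  expect_equal(predict_lda(m, x), unname(post), tolerance = 1e-8)
})

test_that("LDA on identical class distributions is uninformative", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(80 * 5), 80, 5)
    y <- rep(c("benign", "malignant"), 40)
    m <- train_lda(x[1:60, ], y[1:60], shrinkage = 0.1)
    roc_analysis(predict_lda(m, x[61:80, ]), y[61:80])$auc
  }, 0)
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("singular texture block requires and gets shrinkage", {
  set.seed(43)
  df <- rbind(make_feature_df(20, "benign", rep("b1", 20), seed = 1),
              make_feature_df(20, "malignant", rep("m1", 20), seed = 2,
                              shift = 0.01))
  expect_error(train_lda(df, shrinkage = 0), "singular")
  m <- train_lda(df, shrinkage = "auto")
  expect_gt(m$shrinkage, 0)
  expect_length(m$w, 52)
  expect_true(all(predict_lda(m, df) >= 0 & predict_lda(m, df) <= 1))
})

test_that("core scores aggregate gland likelihoods as specified", {
  cs <- score_core(c(0.2, 0.4, 0.9), "c1", "malignant", aggregation = "mean")
  expect_equal(cs$core_score, 0.5)
  expect_equal(score_core(c(0.2, 0.4, 0.9), "c1", aggregation = "median")$core_score,
               0.4)
  expect_true(cs$core_score >= min(cs$gland_scores) &&
                cs$core_score <= max(cs$gland_scores))
  expect_equal(cs$score_sd, sd(c(0.2, 0.4, 0.9)))
  expect_error(score_core(numeric(0), "c1"), "at least one")
})

test_that("fold assignment is stratified, near-equal and exhaustive", {
  ids <- sprintf("c%02d", 1:68)
  labs <- rep(c("benign", "malignant"), each = 34)
  f <- assign_folds(ids, labs, n_folds = 3, seed = 5)
  expect_equal(sort(as.integer(table(f))), c(22L, 23L, 23L))
  expect_equal(sort(unique(f)), 1:3)
  # every core appears exactly once
  expect_equal(length(f), 68)
  expect_false(any(duplicated(names(f))))
  # stratification: each fold has 11-12 of each class
  tb <- table(f, labs)
  expect_true(all(tb >= 11 & tb <= 12))
  expect_error(assign_folds(ids[1:4], c("benign", "benign", "benign",
                                        "malignant"), 3, 1),
               "at least")
})

test_that("the leakage guard trips on any train/validation overlap", {
  expect_silent(check_no_leakage(c("a", "b"), c("c", "d")))
  expect_error(check_no_leakage(c("a", "b"), c("b", "c"), "texton codebook"),
               "leakage.*texton codebook")
  cb <- fit_textons(matrix(rnorm(60), 20, 3), K = 2, seed = 1,
                    source_cores = c("c1", "c2"))
  expect_error(check_no_leakage(cb$source_cores, "c2", "codebook"), "c2")
})

test_that("ROC analysis matches pair counting and an independent implementation", {
  lb <- c("benign", "benign", "malignant", "malignant")
  r <- roc_analysis(c(0.1, 0.2, 0.8, 0.9), lb)
  expect_equal(r$auc, 1)
  expect_equal(r$operating_point$sensitivity, 1)
  expect_equal(r$operating_point$specificity, 1)
  set.seed(44)
  for (s in 1:5) {
    sc <- runif(60)
    labs <- sample(rep(c("benign", "malignant"), 30))
    r2 <- roc_analysis(sc, labs)
    expect_equal(r2$auc, pair_count_auc(sc, labs), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      pr <- suppressMessages(pROC::roc(labs, sc,
                                       levels = c("benign", "malignant"),
                                       direction = "<"))
      expect_equal(r2$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    }
    # monotone sweep arrays
    expect_true(all(diff(r2$sensitivity) <= 0))
    expect_true(all(diff(r2$specificity) >= 0))
  }
  # null labels give AUC near 1/2
  set.seed(45)
  aucs <- vapply(1:30, function(i)
    roc_analysis(runif(40), sample(rep(c("benign", "malignant"), 20)))$auc, 0)
  expect_gte(mean(aucs), 0.44)
  expect_lte(mean(aucs), 0.56)
  expect_warning(roc_analysis(rep(0.5, 4), lb), "identical")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(46)
  sc <- runif(40)
  labs <- sample(rep(c("benign", "malignant"), 20))
  base <- roc_analysis(sc, labs)$auc
  for (f in list(function(x) 3 * x - 1, function(x) x^3,
                 function(x) 1 / (1 + exp(-5 * x)))) {
    expect_equal(roc_analysis(f(sc), labs)$auc, base, tolerance = 1e-12)
  }
})

test_that("the operating point maximizes sens + spec with ties toward sensitivity", {
  # scores where two thresholds tie on Youden's index
  sc <- c(0.1, 0.3, 0.45, 0.7, 0.9)
  labs <- c("benign", "malignant", "benign", "malignant", "malignant")
  r <- roc_analysis(sc, labs)
  j <- r$sensitivity + r$specificity
  expect_equal(r$operating_point$sensitivity + r$operating_point$specificity,
               max(j))
  tied <- which(j == max(j))
  expect_equal(r$operating_point$sensitivity, max(r$sensitivity[tied]))
})
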