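test_that("standardization imputes medians and z-scores by population SD", {
  tab <- synthetic_feature_table(3, list(no_shift()), seed = 1)
  tab$MEAN <- c(1, 2, 3)
  tab$RNG <- c(7, 7, 7)
  tab$VAR <- c(1, NA, 3)
  std <- standardize_features(tab)
  expect_equal(std$MEAN, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(std$RNG, c(0, 0, 0))
  expect_equal(std$VAR, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_error(standardize_features(tab[1, ]), "at least 2")
})

test_that("MMD matches its closed forms and the kernel-sum oracle", {
  set.seed(2)
  a <- matrix(rnorm(20), 5, 4)
  expect_lt(mmd_distance(a, a), 1e-12)

  x <- matrix(c(0, 0), 1); y <- matrix(c(3, 4), 1)
  h <- 2.5
  expect_equal(mmd_distance(x, y, bandwidth = h),
               2 - 2 * exp(-25 / (2 * h^2)), tolerance = 1e-12)

  for (seed in 1:10) {
    set.seed(seed)
    a <- matrix(rnorm(8 * 3), 8, 3)
    b <- matrix(rnorm(6 * 3, 1), 6, 3)
    expect_equal(mmd_distance(a, b, bandwidth = 1.3),
                 max(oracle_mmd(a, b, 1.3), 0), tolerance = 1e-9)
    expect_equal(mmd_distance(a, b), mmd_distance(b, a))
  }
  expect_error(mmd_distance(matrix(0, 2, 3), matrix(0, 2, 4)), "mismatch")
})

test_that("MMD grows with a planted mean shift between two Gaussians", {
  vals <- vapply(c(0, 1, 2, 4), function(shift) {
    set.seed(10)
    a <- matrix(rnorm(40 * 5), 40)
    b <- matrix(rnorm(40 * 5, mean = shift), 40)
    mmd_distance(a, b, bandwidth = 2)
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("pairwise MMD matrix agrees with elementwise recomputation", {
  tab <- synthetic_feature_table(
    10, list(no_shift(), c(rep(3, 11), rep(0, 11)), rep(1, 22)), seed = 3)
  M <- pairwise_mmd(tab, "site", bandwidth = 1.5)
  expect_equal(diag(M), c(site1 = 0, site2 = 0, site3 = 0))
  expect_equal(M, t(M))
  std <- standardize_features(tab)
  X <- as.matrix(std[, feature_names()])
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    a <- X[std$site == paste0("site", pair[1]), ]
    b <- X[std$site == paste0("site", pair[2]), ]
    expect_equal(M[pair[1], pair[2]], max(oracle_mmd(a, b, 1.5), 0),
                 tolerance = 1e-9)
  }
})

test_that("classifiers separate disjoint domains and not identical ones", {
  sep <- synthetic_feature_table(50, list(no_shift(), rep(6, 22)), seed = 4)
  expect_gte(domain_classification(sep, "site", "svm_linear", seed = 1), 0.95)
  expect_gte(domain_classification(sep, "site", "random_forest", seed = 1),
             0.95)

  null <- synthetic_feature_table(100, list(no_shift(), no_shift()), seed = 5)
  accs <- vapply(1:10, function(s)
    domain_classification(null, "site", "random_forest", seed = s), 0)
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("degenerate classification inputs raise informative errors", {
  one_class <- synthetic_feature_table(20, list(no_shift()), seed = 6)
  expect_error(domain_classification(one_class, "site"), "2 domain classes")
  tiny <- synthetic_feature_table(3, list(no_shift(), no_shift()), seed = 7)
  expect_error(domain_classification(tiny, "site", folds = 5L), "fewer than")
  expect_error(domain_classification(tiny, "nope"), "label column")
})

test_that("label permutation collapses accuracy to chance", {
  sep <- synthetic_feature_table(40, list(no_shift(), rep(6, 22)), seed = 8)
  set.seed(9)
  sep$site <- sample(sep$site)
  acc <- mean(vapply(1:5, function(s)
    domain_classification(sep, "site", "random_forest", seed = s), 0))
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("a single shifted feature tops the importance ranking", {
  shift <- rep(0, 22); shift[which(feature_names() == "HFR")] <- 5
  tab <- synthetic_feature_table(40, list(no_shift(), shift), seed = 10)
  imp <- feature_importance(tab, "site", seed = 1)
  expect_identical(imp$feature[1], "HFR")
  expect_setequal(imp$feature, feature_names())
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
})

test_that("null data yields no dominant feature", {
  maxima <- vapply(1:10, function(s) {
    tab <- synthetic_feature_table(30, list(no_shift(), no_shift()),
                                   seed = 100 + s)
    max(feature_importance(tab, "site", seed = s)$importance)
  }, 0)
  expect_lt(max(maxima), 0.15)
})

test_that("2-D embeddings are deterministic and correctly shaped", {
  tab <- synthetic_feature_table(15, list(no_shift(), rep(4, 22)), seed = 11)
  for (m in c("tsne", "umap")) {
    co1 <- suppressMessages(embed_2d(tab, m, seed = 5))
    co2 <- suppressMessages(embed_2d(tab, m, seed = 5))
    expect_equal(dim(co1), c(30, 2))
    expect_identical(co1, co2)
    expect_identical(attr(co1, "method"), m)
  }
  expect_error(embed_2d(tab[1:4, ], "tsne"), "at least 5")
})

test_that("well-separated domains embed with a clear silhouette", {
  tab <- synthetic_feature_table(
    30, list(no_shift(), c(rep(8, 11), rep(0, 11)), rep(-8, 22)), seed = 12)
  lab <- as.integer(factor(tab$site))
  for (m in c("tsne", "umap")) {
    co <- suppressMessages(embed_2d(tab, m, seed = 3))
    sil <- cluster::silhouette(lab, stats::dist(co))
    expect_gte(mean(sil[, 3]), 0.3)
  }
})

test_that("domain_shift assembles a coherent report object", {
  tab <- synthetic_feature_table(20, list(no_shift(), rep(5, 22)), seed = 13)
  rep_ <- suppressMessages(domain_shift(tab, "site", seed = 2))
  expect_s3_class(rep_, "shift_report")
  expect_equal(dim(rep_$mmd), c(2, 2))
  expect_true(all(rep_$accuracy >= 0 & rep_$accuracy <= 1))
  expect_setequal(rep_$importance$feature, feature_names())
  expect_equal(nrow(rep_$embedding$tsne), 40)
  out <- capture.output(print(rep_))
  expect_true(any(grepl("MMD", out)))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(rep_); grDevices::dev.off()
  expect_true(file.exists(f))
})
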