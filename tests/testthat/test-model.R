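# Genotype model: importance ranking, VIF filtering, LDA + logistic layer,
# prediction contracts, determinism, serialisation.

make_labels <- function(n_per = 10) {
  factor(rep(c("FF", "VF", "VV"), each = n_per), levels = c("FF", "VF", "VV"))
}

test_that("a label-copy feature is ranked first almost always", {
  hits <- 0
  for (s in 1:20) {
    y <- make_labels(8)
    x <- withr::with_seed(1000 + s, data.frame(
      signal = as.integer(y) + rnorm(24, 0, 0.15),
      n1 = rnorm(24), n2 = rnorm(24), n3 = rnorm(24), n4 = rnorm(24),
      n5 = rnorm(24)))
    r <- rank_features(x, y, seed = s, num_trees = 150, n_perm = 2)
    if (r$feature[1] == "signal") hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("all-noise features stay within the permutation-null importance band", {
  y <- make_labels(8)
  x <- withr::with_seed(7, as.data.frame(matrix(rnorm(24 * 6), 24,
                                                dimnames = list(NULL, paste0("n", 1:6)))))
  obs <- rank_features(x, y, seed = 1, num_trees = 150, n_perm = 2)
  # null band: importances under label permutation
  null_max <- sapply(1:10, function(s) {
    yp <- withr::with_seed(2000 + s, sample(y))
    max(rank_features(x, yp, seed = s, num_trees = 150,
                      n_perm = 2)$importance)
  })
  expect_lte(max(obs$importance), quantile(null_max, 0.95) + 1e-9)
})

test_that("duplicated informative features both reach the top under plain importance", {
  y <- make_labels(8)
  x <- withr::with_seed(11, data.frame(
    s1 = as.integer(y) + rnorm(24, 0, 0.2),
    n1 = rnorm(24), n2 = rnorm(24), n3 = rnorm(24)))
  x$s2 <- x$s1
  r <- rank_features(x, y, seed = 3, num_trees = 200, conditional = FALSE,
                     n_perm = 3)
  expect_setequal(r$feature[1:2], c("s1", "s2"))
})

test_that("VIFs match the inverse-correlation-matrix oracle", {
  x <- withr::with_seed(5, {
    z <- matrix(rnorm(200 * 5), 200, 5)
    z[, 2] <- 0.7 * z[, 1] + 0.3 * z[, 2]
    z[, 4] <- 0.5 * z[, 3] - 0.5 * z[, 5] + 0.4 * z[, 4]
    as.data.frame(z)
  })
  v <- vif_values(x)
  oracle <- diag(solve(cor(as.matrix(x)))) # independent route
  expect_equal(unname(v), unname(oracle), tolerance = 1e-8)
})

test_that("VIF filtering removes exact duplicates and keeps orthogonal sets", {
  # principal-component scores are exactly uncorrelated
  x <- withr::with_seed(6, as.data.frame(
    prcomp(matrix(rnorm(200), 40, 5))$x))
  colnames(x) <- paste0("f", 1:5)
  r <- filter_vif(x)
  expect_identical(r$selected, colnames(x))
  expect_true(all(abs(r$vif - 1) < 1e-8))

  x2 <- withr::with_seed(8, data.frame(a = rnorm(20)))
  x2$b <- x2$a
  x2$c <- rnorm(20)
  r2 <- filter_vif(x2, ranking_order = c("a", "b", "c"))
  expect_identical(r2$removed, "b") # higher-ranked duplicate is kept
  expect_identical(r2$selected, c("a", "c"))
})

test_that("separable classes are fit to 100% training accuracy, deterministically", {
  sc <- small_cohort()
  fn <- feature_names()
  ok <- complete.cases(sc$features[fn])
  x <- sc$features[ok, fn]
  y <- sc$features$genotype[ok]
  f1 <- fcgr_fit(x, y, seed = 4)
  f2 <- fcgr_fit(x, y, seed = 4)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$selected_features, f2$selected_features)
  pr <- predict(f1, x)
  expect_identical(as.character(pr$class), as.character(y))
})

test_that("prediction probabilities are a proper simplex and argmax matches", {
  sc <- small_cohort()
  fn <- feature_names()
  ok <- complete.cases(sc$features[fn])
  fit <- fcgr_fit(sc$features[ok, fn], sc$features$genotype[ok], seed = 2)
  pr <- predict(fit, sc$features[ok, fn])
  probs <- as.matrix(pr[, c("FF", "VF", "VV")])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_identical(as.character(pr$class),
                   c("FF", "VF", "VV")[max.col(probs, ties.method = "first")])
})

test_that("a sample at a class centroid is called with high confidence", {
  sc <- small_cohort()
  fn <- feature_names()
  ok <- complete.cases(sc$features[fn])
  x <- sc$features[ok, fn]; y <- sc$features$genotype[ok]
  fit <- fcgr_fit(x, y, seed = 2)
  centroid <- as.data.frame(lapply(x[y == "VV", fit$selected_features,
                                     drop = FALSE], mean))
  pr <- predict(fit, centroid)
  expect_identical(as.character(pr$class), "VV")
  expect_gt(pr$VV, 0.9)
})

test_that("missing selected features flag the sample unpredictable", {
  sc <- small_cohort()
  fn <- feature_names()
  ok <- complete.cases(sc$features[fn])
  fit <- fcgr_fit(sc$features[ok, fn], sc$features$genotype[ok], seed = 2)
  bad <- sc$features[ok, fn][1:2, ]
  bad[1, fit$selected_features[1]] <- NA
  pr <- predict(fit, bad)
  expect_true(is.na(pr$class[1]))
  expect_false(is.na(pr$class[2]))
  expect_error(predict(fit, bad[, -match(fit$selected_features[1], fn)]),
               "missing selected feature")
})

test_that("affine rescaling of a selected feature leaves predictions unchanged", {
  sc <- small_cohort()
  fn <- feature_names()
  ok <- complete.cases(sc$features[fn])
  x <- sc$features[ok, fn]; y <- sc$features$genotype[ok]
  fit0 <- fcgr_fit(x, y, seed = 6)
  sel <- fit0$selected_features
  x2 <- x
  x2[[sel[1]]] <- 100 * x2[[sel[1]]] + 42 # affine map
  fit2 <- fcgr_fit(x2, y, seed = 6, features = sel)
  fit1 <- fcgr_fit(x, y, seed = 6, features = sel)
  p1 <- predict(fit1, x)
  p2 <- predict(fit2, x2)
  expect_equal(as.matrix(p1[, c("FF", "VF", "VV")]),
               as.matrix(p2[, c("FF", "VF", "VV")]), tolerance = 1e-6)
})

test_that("the in-house LDA agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  sc <- study_cohorts()
  fn <- c("rMFI_NKdimML", "rF_NKdimML", "Ft_NKdimneg_L")
  ok <- complete.cases(sc$train[fn])
  x <- scale(as.matrix(sc$train[ok, fn]))
  y <- factor(sc$train$genotype[ok], c("FF", "VF", "VV"))
  ours <- fcgrflow:::lda_fit(x, y)
  ref <- MASS::lda(x, grouping = y)
  s_ours <- x %*% ours$scaling
  s_ref <- scale(x, center = colMeans(x), scale = FALSE) %*% ref$scaling
  # axes agree up to sign
  expect_gt(abs(cor(s_ours[, 1], s_ref[, 1])), 0.999)
  if (ncol(s_ours) > 1 && ncol(s_ref) > 1)
    expect_gt(abs(cor(s_ours[, 2], s_ref[, 2])), 0.99)
})

test_that("degenerate designs fall back to ridge LDA instead of failing", {
  # one sample per class: within-class scatter is exactly zero
  x <- data.frame(a = c(0, 5, 10), b = c(1, 1.2, 0.8))
  y <- factor(c("FF", "VF", "VV"), c("FF", "VF", "VV"))
  fit <- fcgr_fit(x, y, seed = 1, features = "a")
  pr <- predict(fit, data.frame(a = c(0.2, 9.5)))
  expect_identical(as.character(pr$class), c("FF", "VV"))
  # both features at once must still produce a defined fit
  fit2 <- fcgr_fit(x, y, seed = 1, features = c("a", "b"))
  expect_false(anyNA(predict(fit2, x)$class))
})

test_that("model JSON serialisation round-trips predictions exactly", {
  sc <- small_cohort()
  fn <- feature_names()
  ok <- complete.cases(sc$features[fn])
  fit <- fcgr_fit(sc$features[ok, fn], sc$features$genotype[ok], seed = 9)
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  fit2 <- read_model_json(path)
  p1 <- predict(fit, sc$features[ok, fn])
  p2 <- predict(fit2, sc$features[ok, fn])
  expect_identical(as.character(p1$class), as.character(p2$class))
  expect_equal(as.matrix(p1[, c("FF", "VF", "VV")]),
               as.matrix(p2[, c("FF", "VF", "VV")]), tolerance = 1e-12)
})

test_that("rank_features rejects broken inputs", {
  y <- make_labels(3)
  x <- data.frame(a = rnorm(9), b = rnorm(9))
  x$a[3] <- NA
  expect_error(rank_features(x, y), "missing values")
  expect_error(rank_features(data.frame(a = rnorm(4)),
                             factor(c("FF", "FF", "VF", "VF"),
                                    c("FF", "VF", "VV"))),
               "must be present")
  expect_warning(
    rank_features(data.frame(a = rnorm(5), b = rnorm(5)),
                  factor(c("FF", "FF", "VF", "VF", "VV"),
                         c("FF", "VF", "VV")),
                  num_trees = 50, n_perm = 1),
    "single sample")
})
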