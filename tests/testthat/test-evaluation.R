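# Evaluation: F1 accounting, cross-validation partitions and leakage
# behaviour, learning curves, the MFI-boundary baseline, acceptance checks.

test_that("weighted F1 matches a hand-computed confusion matrix", {
  # chosen matrix: FF 10/12 correct, VF 8/10, VV 4/6
  truth <- rep(c("FF", "VF", "VV"), c(12, 10, 6))
  pred <- c(rep("FF", 10), "VF", "VV",
            rep("VF", 8), "FF", "VV",
            rep("VV", 4), "VF", "VF")
  r <- classification_report(truth, pred)
  # by hand: F1_c = 2 TP / (col sum + row sum)
  f1_ff <- 2 * 10 / (11 + 12)
  f1_vf <- 2 * 8 / (11 + 10)
  f1_vv <- 2 * 4 / (6 + 6)
  expect_equal(unname(r$f1), c(f1_ff, f1_vf, f1_vv), tolerance = 1e-12)
  expect_equal(r$weighted_f1,
               (12 * f1_ff + 10 * f1_vf + 6 * f1_vv) / 28, tolerance = 1e-12)
  expect_identical(r$ff_cross_errors, 3L) # FF->VF, FF->VV, VF->FF
})

test_that("weighted F1 equals macro F1 on balanced cohorts", {
  truth <- rep(c("FF", "VF", "VV"), each = 10)
  pred <- withr::with_seed(3, sample(truth))
  r <- classification_report(truth, pred)
  expect_lt(abs(r$weighted_f1 - r$macro_f1), 1e-12)
})

test_that("k-fold CV tests every sample exactly once and aces separable data", {
  # wide-margin cohort: genotype classes far apart relative to donor noise
  cfg <- test_cfg(mem154_location = c(FF = 1.8, VF = 4, VV = 5.5),
                  donor_sd = 0.05)
  co <- simulate_cohort(cfg, 18, c(FF = 4, VF = 4, VV = 2), seed = 311)
  tab <- suppressWarnings(build_feature_table(co))
  fn <- feature_names()
  ok <- complete.cases(tab[fn])
  x <- tab[ok, fn]; y <- tab$genotype[ok]
  cv <- kfold_cv(x, y, k = 6, seed = 11, num_trees = 200)
  expect_identical(sort(unique(cv$folds)), 1:6)
  expect_identical(sum(tabulate(cv$folds)), nrow(x)) # each sample once
  expect_lte(diff(range(tabulate(cv$folds))), 3) # stratified remainders
  expect_false(any(is.na(cv$predictions)))
  expect_equal(cv$weighted_f1, 1)
  expect_identical(cv$ff_cross_errors, 0L)
  expect_error(kfold_cv(x, y, k = nrow(x) + 1), "exceeds")
})

test_that("selection inside folds is honest: leaked selection inflates accuracy", {
  # random labels, many noise features: selecting on the full data then
  # cross-validating must look better than the leakage-free pipeline
  n <- 30
  diffs <- sapply(1:3, function(s) {
    y <- withr::with_seed(s, sample(rep(c("FF", "VF", "VV"), each = n / 3)))
    x <- withr::with_seed(100 + s,
      as.data.frame(matrix(rnorm(n * 40), n,
                           dimnames = list(NULL, paste0("f", 1:40)))))
    honest <- kfold_cv(x, y, k = 5, seed = s, num_trees = 100,
                       n_perm = 1)$accuracy
    # leaked: feature chosen using all labels, folds reuse it
    leak_f <- names(which.max(sapply(x, function(v)
      abs(summary(lm(as.integer(factor(y)) ~ v))$r.squared))))
    folds <- fcgrflow:::stratified_folds(factor(y), 5, s)
    pred <- rep(NA_character_, n)
    for (f in 1:5) {
      fit <- fcgr_fit(x[folds != f, , drop = FALSE], y[folds != f],
                      seed = s, features = leak_f)
      pred[folds == f] <- as.character(predict(fit, x[folds == f, ,
                                                      drop = FALSE])$class)
    }
    mean(pred == y, na.rm = TRUE) - honest
  })
  expect_gt(mean(diffs), 0.02)
})

test_that("grouped LOOCV never trains on the test patient and reports per time point", {
  # scaled-down version of the repeated-measures cohort (the study had 52
  # patients at 4 time points; 15 x 2 keeps the same structure)
  cfg <- test_cfg(n_events_per_sample = 3000)
  co <- simulate_cohort(cfg, 15, c(FF = 2, VF = 2, VV = 1),
                        timepoints = c("C1", "C2"), seed = 401)
  tab <- suppressWarnings(build_feature_table(co))
  fn <- feature_names()
  ok <- complete.cases(tab[fn])
  res <- grouped_loocv(tab[ok, fn], tab$genotype[ok], tab$donor_id[ok],
                       tab$timepoint[ok], seed = 1, num_trees = 150,
                       n_perm = 1)
  expect_true(res$leakage_free)
  expect_setequal(names(res$per_timepoint), c("C1", "C2"))
  expect_gte(res$weighted_f1, 0.85)
})

test_that("grouped LOOCV with singleton patients reduces to plain LOOCV", {
  sc <- small_cohort()
  fn <- feature_names()
  ok <- complete.cases(sc$features[fn])
  # pick 4 donors per class so no leave-one-out step empties a class
  yy <- sc$features$genotype[ok]
  pick <- unlist(lapply(c("FF", "VF", "VV"),
                        function(cl) which(yy == cl)[1:4]))
  x <- sc$features[ok, fn][pick, ]
  y <- yy[pick]
  ids <- paste0("P", 1:12)
  res <- grouped_loocv(x, y, ids, seed = 2, num_trees = 150, n_perm = 1)
  # manual plain LOOCV with the same per-iteration seeds
  pred <- rep(NA_character_, 12)
  for (i in 1:12) {
    fit <- fcgr_fit(x[-i, ], y[-i], seed = derive_seed(2, i),
                    num_trees = 150, n_perm = 1)
    pred[i] <- as.character(predict(fit, x[i, , drop = FALSE])$class)
  }
  expect_identical(as.character(res$predictions), pred)
})

test_that("learning curve respects composition contracts and degenerate draws", {
  sc <- small_cohort()
  fn <- feature_names()
  ok <- complete.cases(sc$features[fn])
  x <- sc$features[ok, fn]; y <- sc$features$genotype[ok]
  # full pool, both schemes infeasible -> use pool composition scheme only
  n <- nrow(x)
  counts <- table(y)
  full <- learning_curve(x, y, x, y, sizes = n,
                         schemes = list(pool = c(FF = counts[["FF"]],
                                                 VF = counts[["VF"]],
                                                 VV = counts[["VV"]])),
                         reps = 3, seed = 5, num_trees = 150, n_perm = 1)
  expect_identical(full$summary$sd_accuracy, 0) # every draw is the full pool
  expect_error(learning_curve(x, y, x, y, sizes = 2, reps = 2, seed = 1),
               "infeasible")
})

test_that("mean learning-curve accuracy does not degrade with more donors", {
  sc <- study_cohorts()
  fn <- feature_names()
  ok_tr <- complete.cases(sc$train[fn])
  ok_te <- complete.cases(sc$test[fn])
  lc <- suppressWarnings(learning_curve(
    sc$train[ok_tr, fn], sc$train$genotype[ok_tr],
    sc$test[ok_te, fn], sc$test$genotype[ok_te],
    sizes = c(3, 6, 9), reps = 20, seed = 31, num_trees = 200, n_perm = 1))
  for (sch in unique(lc$summary$scheme)) {
    m <- lc$summary[lc$summary$scheme == sch, ]
    m <- m[order(m$size), ]
    slopes <- diff(m$mean_accuracy) / diff(m$size)
    expect_gte(min(slopes), -0.02)
    expect_gte(m$mean_accuracy[m$size == 6], m$mean_accuracy[m$size == 3])
  }
})

test_that("the MFI baseline solves separable 1D data and matches brute force", {
  # linearly separated on the MEM axis alone (LNK uninformative)
  mem <- c(1, 2, 3, 10, 11, 12, 30, 31, 32)
  lnk <- rep(5, 9)
  y <- rep(c("FF", "VF", "VV"), each = 3)
  b <- fit_baseline(mem, lnk, y)
  expect_identical(b$training_accuracy, 1)
  expect_identical(as.character(predict_baseline(b, c(2, 11, 31), rep(5, 3))),
                   c("FF", "VF", "VV"))

  # n = 15 with overlap: midpoint search vs dense-grid brute force
  set.seed(21)
  mem2 <- c(rnorm(5, 2), rnorm(5, 4), rnorm(5, 6))
  lnk2 <- c(rnorm(5, 6), rnorm(5, 4), rnorm(5, 4))
  y2 <- rep(c("FF", "VF", "VV"), each = 5)
  b2 <- fit_baseline(mem2, lnk2, y2)
  expect_equal(b2$training_accuracy,
               baseline_brute_force(mem2, lnk2, y2), tolerance = 1e-12)
})

test_that("the naive baseline does not beat the full model", {
  sc <- study_cohorts()
  fn <- feature_names()
  all_tab <- rbind(sc$train, sc$test)
  ok <- complete.cases(all_tab[fn])
  tab <- all_tab[ok, ]
  accs <- sapply(1:3, function(s) {
    cv <- kfold_cv(tab[fn], tab$genotype, k = 5, seed = s,
                   num_trees = 200, n_perm = 1)
    b <- fit_baseline(tab$MFI_M_NKdim_M, tab$MFI_L_NKdim_L, tab$genotype)
    c(model = cv$accuracy, baseline = b$training_accuracy)
  })
  expect_gte(mean(accs["model", ]), mean(accs["baseline", ]))
})

test_that("acceptance check enforces both published criteria", {
  mk <- function(wf1, ff_cross) {
    structure(list(weighted_f1 = wf1, ff_cross_errors = ff_cross),
              class = "fcgr_cv_report")
  }
  expect_true(check_acceptance(mk(0.94, 0L))$pass)
  r <- check_acceptance(mk(0.95, 1L))
  expect_false(r$pass)
  expect_false(r$no_ff_cross_error)
  r2 <- check_acceptance(mk(0.89, 0L))
  expect_false(r2$pass)
  expect_false(r2$weighted_f1_ok)
})
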