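# Evaluation procedures: stratified 10-fold CV, leakage-safe grouped LOOCV,
# learning curves over training-set size and class composition, the naive
# MFI-boundary baseline, and the published acceptance check (weighted F1 >=
# 90% and zero FF <-> VF/VV confusions). Every selection step (forest
# ranking, VIF) is refit inside each training fold — no selection leakage.

#' Confusion matrix and F1 scores
#'
#' @param truth true genotype labels
#' @param pred predicted genotype labels
#' @return list with `confusion` (3x3, rows = truth), `f1` (per class),
#'   `weighted_f1` (per-class F1 weighted by true-class support), `macro_f1`,
#'   `accuracy` and `ff_cross_errors` (count of FF <-> VF/VV confusions)
#' @export
classification_report <- function(truth, pred) {
  truth <- as_genotype(truth)
  pred <- factor(as.character(pred), levels = GENOTYPES)
  cm <- table(truth = truth, pred = pred)
  f1 <- vapply(GENOTYPES, function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  support <- rowSums(cm)
  wf1 <- if (sum(support) > 0) sum(f1 * support) / sum(support) else NA_real_
  ff_cross <- cm["FF", "VF"] + cm["FF", "VV"] +
    cm["VF", "FF"] + cm["VV", "FF"]
  list(confusion = cm, f1 = f1, weighted_f1 = wf1, macro_f1 = mean(f1),
       accuracy = sum(diag(cm)) / sum(cm),
       ff_cross_errors = as.integer(ff_cross), support = support)
}

# Stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(y, k, seed, stratify = TRUE) {
  n <- length(y)
  k <- as.integer(k)
  folds <- integer(n)
  with_seed(seed, {
    if (stratify) {
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
      # rotate fold labels so fold sizes stay balanced across classes
      folds <- ((folds + sample.int(k, 1)) %% k) + 1L
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
  })
  folds
}

#' k-fold cross-validation of the full pipeline
#'
#' Folds are stratified by genotype where counts allow; the complete pipeline
#' (ranking, VIF, LDA, LR) is refit inside every training fold and each sample
#' is tested exactly once. Predictions are pooled into one confusion matrix.
#'
#' @param x feature data.frame
#' @param y genotype labels
#' @param k number of folds (default 10)
#' @param seed integer seed (fold assignment + per-fold fits)
#' @param stratify stratify folds by class?
#' @param ... passed to [fcgr_fit()] (e.g. `num_trees`)
#' @return object of class `fcgr_cv_report`: the [classification_report()]
#'   plus `scheme`, `folds`, `predictions` and `seed`
#' @export
kfold_cv <- function(x, y, k = 10, seed = 1L, stratify = TRUE, ...) {
  x <- as.data.frame(x)
  y <- as_genotype(y)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of samples")
  folds <- stratified_folds(y, k, seed, stratify)
  pred <- factor(rep(NA_character_, n), levels = GENOTYPES)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- fcgr_fit(x[tr, , drop = FALSE], y[tr],
                    seed = derive_seed(seed, f), ...)
    pred[!tr] <- predict(fit, x[!tr, , drop = FALSE])$class
  }
  rep0 <- classification_report(y, pred)
  structure(c(rep0, list(scheme = "kfold", k = k, folds = folds,
                         predictions = pred, truth = y, seed = seed)),
            class = "fcgr_cv_report")
}

#' @export
print.fcgr_cv_report <- function(x, ...) {
  cat(sprintf("<fcgr_cv_report> scheme=%s  accuracy=%.3f  weighted F1=%.3f\n",
              x$scheme, x$accuracy, x$weighted_f1))
  cat(sprintf("  FF <-> VF/VV confusions: %d\n", x$ff_cross_errors))
  print(x$confusion)
  invisible(x)
}

#' Grouped leave-one-out cross-validation
#'
#' For every sample, the training set excludes *all* samples sharing the test
#' sample's patient ID (its other time points), preventing leakage from
#' repeated measures. Reports are produced per time point and overall.
#'
#' @param x feature data.frame
#' @param y genotype labels
#' @param patient_id patient identifier per sample
#' @param timepoint time point label per sample
#' @param seed integer seed for the per-iteration fits
#' @param ... passed to [fcgr_fit()]
#' @return object of class `fcgr_loocv_report`: overall
#'   [classification_report()] plus `per_timepoint` reports, `predictions`
#'   and `issues` (iterations where some class vanished from training)
#' @export
grouped_loocv <- function(x, y, patient_id, timepoint = rep("C1", nrow(x)),
                          seed = 1L, ...) {
  x <- as.data.frame(x)
  y <- as_genotype(y)
  patient_id <- as.character(patient_id)
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = GENOTYPES)
  issues <- character(0)
  leakage_free <- TRUE
  for (i in seq_len(n)) {
    tr <- patient_id != patient_id[i]
    if (any(patient_id[tr] == patient_id[i])) leakage_free <- FALSE
    if (any(table(y[tr]) == 0)) {
      issues <- c(issues, sprintf(
        "sample %d: class %s absent from training after excluding patient %s",
        i, setdiff(GENOTYPES, unique(as.character(y[tr]))), patient_id[i]))
      next
    }
    fit <- fcgr_fit(x[tr, , drop = FALSE], y[tr],
                    seed = derive_seed(seed, i), ...)
    pred[i] <- predict(fit, x[i, , drop = FALSE])$class
  }
  per_tp <- lapply(split(seq_len(n), timepoint), function(idx)
    classification_report(y[idx], pred[idx]))
  structure(c(classification_report(y, pred),
              list(scheme = "grouped_loocv", per_timepoint = per_tp,
                   predictions = pred, truth = y, patient_id = patient_id,
                   timepoint = timepoint, issues = issues,
                   leakage_free = leakage_free, seed = seed)),
            class = c("fcgr_loocv_report", "fcgr_cv_report"))
}

#' @export
print.fcgr_loocv_report <- function(x, ...) {
  NextMethod()
  cat("  per time point (weighted F1):",
      paste(sprintf("%s=%.3f", names(x$per_timepoint),
                    vapply(x$per_timepoint, `[[`, numeric(1), "weighted_f1")),
            collapse = "  "), "\n")
  if (length(x$issues)) cat("  issues:", length(x$issues), "\n")
  invisible(x)
}

#' Learning curve over training-set size and class composition
#'
#' For each requested size and composition scheme, draws `reps` random
#' training sets from the pool (class counts by largest-remainder allocation
#' of the scheme), refits the full pipeline, and evaluates accuracy on the
#' fixed test set. Repetition seeds derive from the master seed via a counter.
#'
#' @param pool_x,pool_y training pool (disjoint from the test set)
#' @param test_x,test_y fixed test set
#' @param sizes training sizes (minimum 3, at least one donor per class)
#' @param schemes named list of FF/VF/VV composition weights; defaults to the
#'   population-prevalence 4:4:2 and the balanced 1:1:1 schemes
#' @param reps repetitions per cell (default 100)
#' @param seed master seed
#' @param reselect rerun feature ranking and VIF inside every repetition?
#'   The default (`FALSE`) selects features once on the full pool — the
#'   question the curve answers is how many samples are needed to rebuild an
#'   established model, and per-repetition reselection is statistically
#'   meaningless below ~2 samples per class — then refits standardisation,
#'   LDA and the logistic layer on each drawn subset. The pool is disjoint
#'   from the test set either way, so no information leaks into evaluation.
#' @param features optional fixed feature set (implies `reselect = FALSE`)
#' @param ... passed to [fcgr_fit()]
#' @return object of class `fcgr_learning_curve`: data.frame `summary` with
#'   mean/SD accuracy per (scheme, size), and `accuracies` (reps matrix list)
#' @export
learning_curve <- function(pool_x, pool_y, test_x, test_y,
                           sizes = c(3, 6, 9, 12),
                           schemes = list(`4:4:2` = c(FF = 4, VF = 4, VV = 2),
                                          `1:1:1` = c(FF = 1, VF = 1, VV = 1)),
                           reps = 100, seed = 1L, reselect = FALSE,
                           features = NULL, ...) {
  pool_x <- as.data.frame(pool_x)
  pool_y <- as_genotype(pool_y)
  test_y <- as_genotype(test_y)
  cc <- stats::complete.cases(pool_x)
  if (!all(cc)) {
    warning(sum(!cc), " pool sample(s) with missing features excluded")
    pool_x <- pool_x[cc, , drop = FALSE]
    pool_y <- pool_y[cc]
  }
  if (!reselect && is.null(features)) {
    features <- fcgr_fit(pool_x, pool_y, seed = derive_seed(seed, 0L),
                         ...)$selected_features
  }
  pool_by_class <- split(seq_along(pool_y), pool_y)
  acc <- list()
  rows <- list()
  counter <- 0L
  for (sch in names(schemes)) {
    for (sz in sizes) {
      counts <- largest_remainder(sz, schemes[[sch]])
      if (any(counts < 1))
        stop("composition ", sch, " infeasible at size ", sz)
      if (any(counts > lengths(pool_by_class)))
        stop("pool too small for composition ", sch, " at size ", sz)
      a <- numeric(reps)
      for (r in seq_len(reps)) {
        counter <- counter + 1L
        idx <- with_seed(derive_seed(seed, counter), unlist(
          lapply(GENOTYPES, function(cl)
            sample(pool_by_class[[cl]], counts[[cl]]))))
        fit <- fcgr_fit(pool_x[idx, , drop = FALSE], pool_y[idx],
                        seed = derive_seed(seed, 100000L + counter),
                        features = if (reselect) NULL else features, ...)
        pr <- predict(fit, test_x)$class
        a[r] <- mean(pr == test_y, na.rm = TRUE)
      }
      acc[[paste(sch, sz, sep = "|")]] <- a
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = sch, size = sz, mean_accuracy = mean(a),
        sd_accuracy = stats::sd(a), reps = reps, stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows), accuracies = acc,
                 seed = seed), class = "fcgr_learning_curve")
}

#' @export
print.fcgr_learning_curve <- function(x, ...) {
  cat("<fcgr_learning_curve>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fit the naive MFI-boundary baseline classifier
#'
#' Axis-aligned class regions in the (MEM154 MFI, LNK16 MFI) plane: a pair
#' of MEM thresholds (allele dosage orders MEM binding, so three bands) and
#' one LNK threshold, each cell assigned its majority training class. The
#' search is exhaustive over all midpoints between sorted observed values
#' (band-collapsing boundary candidates included); ties in training accuracy
#' are broken towards the lowest thresholds.
#'
#' @param mem,lnk per-sample NK MFIs of the two clones
#' @param y genotype labels
#' @return object of class `fcgr_baseline`: thresholds, the cell -> class
#'   map and training accuracy
#' @export
fit_baseline <- function(mem, lnk, y) {
  y <- as_genotype(y)
  stopifnot(length(mem) == length(lnk), length(mem) == length(y))
  if (length(unique(mem)) < 2 && length(unique(lnk)) < 2)
    stop("degenerate all-equal MFIs")
  n <- length(y)
  cand <- function(v) {
    s <- sort(unique(v))
    if (length(s) < 2) return(min(v) - 1)
    c(min(v) - 1, (s[-1] + s[-length(s)]) / 2) # leading value: empty band
  }
  cm <- cand(mem); cl <- cand(lnk)
  yi <- as.integer(y)
  best <- list(acc = -1)
  for (tl in cl) {
    hi <- lnk > tl
    for (i in seq_along(cm)) {
      m1 <- mem > cm[i]
      for (j in i:length(cm)) {
        band <- 1L + m1 + (mem > cm[j]) # 1..3
        cell <- band + 3L * hi # 1..6
        cmat <- matrix(tabulate(cell + 6L * (yi - 1L), nbins = 18L),
                       nrow = 6) # cells x classes
        map <- max.col(cmat, ties.method = "first")
        acc <- sum(cmat[cbind(1:6, map)]) / n
        if (acc > best$acc)
          best <- list(acc = acc, tm = c(cm[i], cm[j]), tl = tl, map = map)
      }
    }
  }
  structure(list(mem_thresholds = best$tm, lnk_threshold = best$tl,
                 cell_class = GENOTYPES[best$map],
                 training_accuracy = best$acc),
            class = "fcgr_baseline")
}

#' Predict with the MFI-boundary baseline
#' @param boundaries an [fit_baseline()] result
#' @param mem,lnk NK MFIs of the two clones
#' @return factor of predicted genotypes
#' @export
predict_baseline <- function(boundaries, mem, lnk) {
  band <- 1L + (mem > boundaries$mem_thresholds[1]) +
    (mem > boundaries$mem_thresholds[2])
  cell <- band + 3L * (lnk > boundaries$lnk_threshold)
  factor(boundaries$cell_class[cell], levels = GENOTYPES)
}

#' @export
print.fcgr_baseline <- function(x, ...) {
  cat(sprintf(
    "<fcgr_baseline> MEM154 bands at (%.3g, %.3g), LNK16 at %.3g; training accuracy %.3f\n",
    x$mem_thresholds[1], x$mem_thresholds[2], x$lnk_threshold,
    x$training_accuracy))
  cat("  cell classes (MEM low/mid/high x LNK low/high):",
      paste(x$cell_class, collapse = ", "), "\n")
  invisible(x)
}

#' Check the published acceptance criteria on a CV report
#'
#' Pass requires (1) weighted F1 >= 0.90 and (2) zero confusions between the
#' low-affinity FF and the high-affinity VF/VV variants.
#'
#' @param report an `fcgr_cv_report`
#' @param f1_threshold weighted-F1 bound (default 0.90)
#' @return list with `pass`, per-criterion logicals and `reasons`
#' @export
check_acceptance <- function(report, f1_threshold = 0.90) {
  f1_ok <- isTRUE(report$weighted_f1 >= f1_threshold)
  ff_ok <- isTRUE(report$ff_cross_errors == 0)
  reasons <- character(0)
  if (!f1_ok) reasons <- c(reasons, sprintf(
    "weighted F1 %.3f below %.2f", report$weighted_f1, f1_threshold))
  if (!ff_ok) reasons <- c(reasons, sprintf(
    "%d FF <-> VF/VV misclassification(s)", report$ff_cross_errors))
  list(pass = f1_ok && ff_ok, weighted_f1_ok = f1_ok,
       no_ff_cross_error = ff_ok, weighted_f1 = report$weighted_f1,
       ff_cross_errors = report$ff_cross_errors, reasons = reasons)
}
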