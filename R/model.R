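# Supervised genotype prediction pipeline:
#   conditional-forest feature ranking -> VIF filter -> LDA -> multinomial
#   logistic regression on the discriminant scores.
# The whole pipeline is deterministic given (data, seed).

#' Rank features by conditional permutation importance
#'
#' Fits a random forest and scores each feature by the mean per-tree drop in
#' out-of-bag accuracy when it is permuted (each tree is scored on its own
#' out-of-bag samples and the drops are averaged, the conditional-forest
#' convention). In conditional mode the permutation is performed within
#' strata formed by binning the features most correlated with the one under
#' test (|Spearman r| >= `cor_cutoff`), so that importance reflects the
#' feature's own signal rather than that of correlated companions. Plain
#' (unstratified) permutation importance is available as a fallback.
#'
#' @param x data.frame or matrix of features (no missing values)
#' @param y genotype labels (FF/VF/VV)
#' @param seed integer seed (forest + permutations)
#' @param num_trees number of trees
#' @param conditional permute within correlated-covariate strata?
#' @param cor_cutoff |Spearman correlation| above which a covariate defines
#'   permutation strata (conditional mode)
#' @param n_perm permutation repeats averaged per feature
#' @param top_k number of top-ranked features to flag
#' @return data.frame sorted by decreasing importance with columns `feature`,
#'   `importance`, `rank`, `top`
#' @export
rank_features <- function(x, y, seed = 1L, num_trees = 500,
                          conditional = TRUE, cor_cutoff = 0.5,
                          n_perm = 3L, top_k = 5L) {
  x <- as.data.frame(x)
  y <- as_genotype(y)
  if (anyNA(x)) stop("missing values in feature table")
  tab <- table(y)
  if (any(tab == 0)) stop("every genotype class must be present")
  if (any(tab < 2))
    warning("class(es) with a single sample: ",
            paste(names(tab)[tab < 2], collapse = ", "),
            "; importances will be unstable")
  p <- ncol(x)
  dat <- cbind(x, .y = y)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat, num.trees = num_trees,
    keep.inbag = TRUE, seed = as.integer(seed), num.threads = 1,
    respect.unordered.factors = TRUE)
  inbag <- matrix(unlist(fit$inbag.counts), ncol = fit$num.trees)
  oob <- inbag == 0
  oob_n <- pmax(colSums(oob), 1L)
  yint <- as.integer(y)

  # per-tree OOB accuracies (each tree judged on its own held-out samples)
  tree_acc <- function(xx) {
    pr <- stats::predict(fit, data = xx, predict.all = TRUE,
                         num.threads = 1)$predictions
    colSums((pr == yint) & oob) / oob_n
  }
  base_acc <- tree_acc(x)

  cors <- suppressWarnings(stats::cor(as.matrix(x), method = "spearman"))
  cors[!is.finite(cors)] <- 0
  imp <- numeric(p)
  with_seed(derive_seed(seed, 999), {
    n <- nrow(x)
    for (j in seq_len(p)) {
      strata <- rep(1L, n)
      # stratified permutation needs cells of >= ~4 samples to do anything;
      # below n = 12 it degenerates, so fall back to plain permutation there
      if (conditional && n >= 12) {
        max_cov <- if (n >= 24) 2L else 1L
        comp <- setdiff(order(-abs(cors[j, ]))[1:min(3, p)], j)
        comp <- comp[abs(cors[j, comp]) >= cor_cutoff]
        comp <- comp[seq_len(min(max_cov, length(comp)))]
        if (length(comp)) {
          n_bins <- min(4L, max(2L, floor((n / 4)^(1 / length(comp)))))
          bins <- lapply(comp, function(k)
            as.integer(cut(rank(x[[k]], ties.method = "first"),
                           breaks = n_bins)))
          strata <- as.integer(interaction(as.data.frame(bins), drop = TRUE))
        }
      }
      drops <- replicate(n_perm, {
        xp <- x
        for (s in unique(strata)) {
          idx <- which(strata == s)
          if (length(idx) > 1) xp[idx, j] <- x[sample(idx), j]
        }
        mean(base_acc - tree_acc(xp))
      })
      imp[j] <- mean(drops)
    }
  })
  out <- data.frame(feature = colnames(x), importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top_k
  rownames(out) <- NULL
  out
}

#' Variance inflation factors of a feature set
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing feature j on the others; infinite
#' under exact collinearity.
#'
#' @param x data.frame or matrix of candidate features
#' @return named numeric vector of VIFs
#' @export
vif_values <- function(x) {
  x <- as.data.frame(x)
  p <- ncol(x)
  if (p < 2) return(stats::setNames(rep(1, p), colnames(x)))
  out <- stats::setNames(numeric(p), colnames(x))
  for (j in seq_len(p)) {
    fit <- stats::lm(x[[j]] ~ ., data = x[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared) # perfect fits -> Inf VIF
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Iteratively remove multicollinear features by VIF
#'
#' Removes the highest-VIF feature (ties resolved by dropping the one ranked
#' lower in `ranking_order`) until all remaining VIFs are below `cutoff`.
#' Importance order of survivors is preserved.
#'
#' @param x data.frame of candidate features, columns in importance order
#' @param cutoff VIF threshold (default 5)
#' @param ranking_order optional character vector, most important first
#' @return list with `selected` (feature names, importance order), `vif`
#'   (final VIFs) and `removed`
#' @export
filter_vif <- function(x, cutoff = 5, ranking_order = colnames(x)) {
  x <- as.data.frame(x)
  keep <- colnames(x)
  removed <- character(0)
  repeat {
    if (length(keep) < 2) break
    v <- vif_values(x[, keep, drop = FALSE])
    if (all(v < cutoff)) break
    worst <- v == max(v)
    # among tied worst, drop the lowest-ranked (keep higher-ranked)
    cand <- names(v)[worst]
    drop_ft <- cand[which.max(match(cand, ranking_order))]
    removed <- c(removed, drop_ft)
    keep <- setdiff(keep, drop_ft)
  }
  if (length(keep) < 1) stop("degenerate design: no feature survives VIF")
  keep <- ranking_order[ranking_order %in% keep]
  list(selected = keep,
       vif = vif_values(x[, keep, drop = FALSE]),
       removed = removed)
}

# Regularised linear discriminant analysis. Pooled within-class covariance W
# gets a small ridge when the design is sample-starved (n - g <= p) or W is
# near-singular, so fits at the learning-curve minimum of 3 samples remain
# defined. Axes are scaled to unit within-class variance, as is conventional.
lda_fit <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x)
  y <- droplevels(y)
  g <- nlevels(y)
  p <- ncol(x)
  n <- nrow(x)
  grand <- colMeans(x)
  means <- do.call(rbind, lapply(levels(y), function(l)
    colMeans(x[y == l, , drop = FALSE])))
  rownames(means) <- levels(y)
  W <- matrix(0, p, p)
  for (l in levels(y)) {
    xi <- x[y == l, , drop = FALSE]
    if (nrow(xi) > 1) {
      xc <- sweep(xi, 2, colMeans(xi))
      W <- W + crossprod(xc)
    }
  }
  dfw <- max(n - g, 1)
  W <- W / dfw
  scale0 <- mean(diag(W))
  if (!is.finite(scale0) || scale0 <= 0) scale0 <- 1
  if (n - g <= p || rcond(W) < 1e-10) W <- W + diag(ridge + 0.05 * scale0, p)
  else W <- W + diag(ridge * scale0, p)
  B <- matrix(0, p, p)
  for (l in levels(y)) {
    d <- means[l, ] - grand
    B <- B + sum(y == l) * tcrossprod(d)
  }
  B <- B / n
  M <- solve(W, B)
  ei <- eigen(M)
  k <- min(g - 1, p)
  A <- Re(ei$vectors[, seq_len(k), drop = FALSE])
  # normalise: a' W a = 1 per axis
  for (j in seq_len(k)) {
    s <- sqrt(drop(t(A[, j]) %*% W %*% A[, j]))
    if (s > 0) A[, j] <- A[, j] / s
    # sign convention: largest-|loading| coefficient positive
    i0 <- which.max(abs(A[, j]))
    if (A[i0, j] < 0) A[, j] <- -A[, j]
  }
  colnames(A) <- paste0("LD", seq_len(k))
  list(grand_mean = grand, class_means = means, scaling = A, W = W,
       svd = Re(ei$values[seq_len(k)]))
}

lda_scores <- function(lda, x) {
  x <- as.matrix(x)
  sweep(x, 2, lda$grand_mean) %*% lda$scaling
}

# Multinomial logistic layer over LDA scores, fitted with weak L2 for
# stability on separable score spaces. Coefficients are stored so prediction
# is a plain softmax independent of the fitting object.
fit_logistic <- function(scores, y, decay = 1e-3, seed = 1L) {
  df <- data.frame(.y = y, scores)
  fit <- with_seed(seed,
    nnet::multinom(.y ~ ., data = df, decay = decay, trace = FALSE,
                   maxit = 500))
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                     dimnames = list(levels(y)[2], names(co)))
  list(coef = co, levels = levels(y))
}

softmax_probs <- function(lr, scores) {
  X <- cbind(1, as.matrix(scores))
  eta <- cbind(0, X %*% t(lr$coef)) # baseline class first
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  colnames(p) <- lr$levels
  p
}

#' Fit the FcgammaRIIIa genotype prediction model
#'
#' The full supervised pipeline: z-standardise features (training statistics),
#' rank by conditional permutation importance, keep the top `top_k`
#' (capped at `n - 2` when samples are scarce), drop multicollinear candidates
#' by iterative VIF filtering, retain the `final_k` most distinctive (highest
#' ranked) survivors, and fit LDA on them followed by a multinomial logistic
#' regression on the (<= 2) discriminant scores.
#'
#' @param x data.frame of features (columns from [feature_manifest()] or any
#'   numeric features); rows with missing values in the selected features are
#'   rejected
#' @param y genotype labels FF/VF/VV, all three classes represented
#' @param seed integer seed controlling forest, permutations and LR fit
#' @param top_k candidate count after ranking (default 5)
#' @param vif_cutoff VIF threshold (default 5)
#' @param final_k number of highest-ranked VIF survivors fed into LDA
#'   (default 2, the most distinctive parameters)
#' @param num_trees forest size
#' @param conditional conditional (stratified) permutation importance?
#' @param decay L2 penalty of the logistic layer
#' @param n_perm permutation repeats per feature in the ranking stage
#' @param features optional character vector of feature names to use as-is,
#'   skipping the ranking and VIF stages (used when the model structure is
#'   already established, e.g. refitting on small samples)
#' @return an object of class `fcgr_model`
#' @examples
#' \donttest{
#' cfg <- fcgr_sim_config(n_events_per_sample = 5000)
#' co <- simulate_cohort(cfg, 12, seed = 11)
#' tab <- build_feature_table(co)
#' fit <- fcgr_fit(tab[feature_names()], tab$genotype, seed = 1)
#' fit
#' predict(fit, tab[feature_names()])$class
#' }
#' @export
fcgr_fit <- function(x, y, seed = 1L, top_k = 5L, vif_cutoff = 5,
                     final_k = 2L, num_trees = 500, conditional = TRUE,
                     decay = 1e-3, features = NULL, n_perm = 3L) {
  x <- as.data.frame(x)
  y <- as_genotype(y)
  if (any(table(y) == 0)) stop("all three genotype classes must be present")
  cc <- stats::complete.cases(x)
  if (!all(cc)) {
    warning(sum(!cc), " sample(s) with missing features excluded from fit")
    x <- x[cc, , drop = FALSE]
    y <- droplevels(y[cc])
    y <- factor(as.character(y), levels = GENOTYPES)
  }
  n <- nrow(x)
  # drop constant features: carry no information and break standardisation
  sds <- vapply(x, stats::sd, numeric(1))
  x_use <- x[, sds > 0, drop = FALSE]

  if (is.null(features)) {
    ranking <- rank_features(x_use, y, seed = seed, num_trees = num_trees,
                             conditional = conditional, top_k = top_k,
                             n_perm = n_perm)
    k_eff <- min(top_k, max(1L, n - 2L)) # VIF needs candidates + 2 samples
    candidates <- ranking$feature[seq_len(min(k_eff, nrow(ranking)))]
  } else {
    miss <- setdiff(features, colnames(x_use))
    if (length(miss)) stop("unknown or constant feature(s): ",
                           paste(miss, collapse = ", "))
    ranking <- NULL
    candidates <- features
  }

  mu <- colMeans(x_use[, candidates, drop = FALSE])
  sdv <- vapply(x_use[, candidates, drop = FALSE], stats::sd, numeric(1))
  sdv[sdv == 0] <- 1
  z <- as.data.frame(scale(x_use[, candidates, drop = FALSE],
                           center = mu, scale = sdv))

  if (!is.null(features)) { # fixed structure: report VIFs, drop nothing
    vf <- list(selected = candidates, vif = vif_values(z),
               removed = character(0))
  } else if (length(candidates) >= 2) {
    vf <- filter_vif(z, cutoff = vif_cutoff, ranking_order = candidates)
  } else {
    vf <- list(selected = candidates,
               vif = stats::setNames(1, candidates), removed = character(0))
  }
  sel <- vf$selected
  if (is.null(features)) {
    # the most distinctive survivors: a feature whose permutation importance
    # is not positive carries no detectable signal and cannot be distinctive
    pos <- ranking$feature[ranking$importance > 0]
    informative <- sel[sel %in% pos]
    if (length(informative)) sel <- informative
    else sel <- sel[1L] # degenerate all-noise design: keep the top-ranked
    sel <- sel[seq_len(min(final_k, length(sel)))]
  }
  lda <- lda_fit(as.matrix(z[, sel, drop = FALSE]), y)
  sc <- lda_scores(lda, as.matrix(z[, sel, drop = FALSE]))
  lr <- fit_logistic(sc, y, decay = decay, seed = derive_seed(seed, 17))

  structure(list(
    selected_features = sel,
    ranking = ranking,
    vif = vf$vif,
    vif_removed = vf$removed,
    standardise = list(center = mu[sel], scale = sdv[sel]),
    lda = lda, lr = lr,
    classes = GENOTYPES,
    seed = as.integer(seed),
    n_train = n,
    class_counts = table(y),
    manifest_version = attr(x, "manifest_version") %||% NA_character_,
    call = match.call()),
    class = "fcgr_model")
}

#' Predict genotypes from a fitted model
#'
#' @param object an `fcgr_model`
#' @param newdata data.frame containing the model's selected features
#' @param ... unused
#' @return data.frame with `class` (argmax label, ties broken FF < VF < VV),
#'   one probability column per genotype, and the LDA coordinates. Rows with
#'   missing selected features get `NA` predictions (flagged unpredictable).
#' @export
predict.fcgr_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$selected_features, colnames(newdata))
  if (length(miss)) stop("missing selected feature(s): ",
                         paste(miss, collapse = ", "))
  xs <- newdata[, object$selected_features, drop = FALSE]
  ok <- stats::complete.cases(xs)
  z <- scale(as.matrix(xs), center = object$standardise$center,
             scale = object$standardise$scale)
  sc <- matrix(NA_real_, nrow(z), ncol(object$lda$scaling),
               dimnames = list(NULL, colnames(object$lda$scaling)))
  probs <- matrix(NA_real_, nrow(z), 3,
                  dimnames = list(NULL, object$classes))
  if (any(ok)) {
    sc[ok, ] <- lda_scores(object$lda, z[ok, , drop = FALSE])
    probs[ok, ] <- softmax_probs(object$lr, sc[ok, , drop = FALSE])
  }
  cls <- rep(NA_character_, nrow(z))
  cls[ok] <- object$classes[apply(probs[ok, , drop = FALSE], 1, which.max)]
  out <- data.frame(class = factor(cls, levels = object$classes),
                    probs, sc, check.names = FALSE)
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.fcgr_model <- function(x, ...) {
  cat("FcgammaRIIIa genotype model (forest ranking -> VIF -> LDA -> LR)\n")
  cat("  trained on", x$n_train, "samples (",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
            collapse = ", "), ")\n")
  cat("  selected features:", paste(x$selected_features, collapse = ", "),
      "\n")
  v <- x$vif[names(x$vif) %in% x$selected_features]
  cat("  VIF:", paste(sprintf("%s=%.2f", names(v), v), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.fcgr_model <- function(object, ...) {
  structure(list(model = object), class = "summary.fcgr_model")
}

#' @export
print.summary.fcgr_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nTop-ranked features (conditional permutation importance):\n")
  print(utils::head(m$ranking, 8), row.names = FALSE)
  cat("\nLDA axes (standardised-feature loadings):\n")
  print(round(m$lda$scaling, 3))
  cat("\nLogistic coefficients over LDA scores (baseline FF):\n")
  print(round(m$lr$coef, 3))
  invisible(x)
}

#' @export
coef.fcgr_model <- function(object, ...) object$lr$coef

#' Plot the LDA projection of the training classes
#'
#' @param x an `fcgr_model`
#' @param newdata feature table to project (e.g. the training table)
#' @param y optional genotype labels for colouring
#' @param ... passed to [plot()]
#' @export
plot.fcgr_model <- function(x, newdata, y = NULL, ...) {
  pr <- predict(x, newdata)
  ld <- as.matrix(pr[, grep("^LD", colnames(pr)), drop = FALSE])
  if (ncol(ld) == 1) ld <- cbind(ld, LD2 = 0)
  col <- if (is.null(y)) 1L else as.integer(as_genotype(y)) + 1L
  plot(ld[, 1], ld[, 2], col = col, pch = 19,
       xlab = "LD1", ylab = "LD2", ...)
  if (!is.null(y))
    graphics::legend("topright", legend = GENOTYPES, col = 2:4, pch = 19)
  invisible(pr)
}
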