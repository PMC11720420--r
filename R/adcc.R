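# ADCC quantification: LDH specific lysis, flow-based tumour-kill delta, the
# 154-measure delta/fold-change parameter table over a reconstructed
# 77-parameter manifest, rank-based group statistics (deliberately
# unadjusted: the screen is exploratory), Pearson correlation of the two
# cytotoxicity readouts, and tSNE embedding of z-scored parameters.

#' LDH plate container
#'
#' @param wells data.frame with columns `condition`, `replicate`,
#'   `absorbance` (raw optical densities, >= 0); medium replicates required
#' @return object of class `adcc_plate`
#' @export
adcc_plate <- function(wells) {
  wells <- as.data.frame(wells)
  need <- c("condition", "replicate", "absorbance")
  miss <- setdiff(need, colnames(wells))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"medium" %in% wells$condition)
    stop("medium replicates are required for background correction")
  if (any(wells$absorbance < 0)) stop("absorbances must be >= 0")
  structure(list(wells = wells), class = "adcc_plate")
}

#' @export
print.adcc_plate <- function(x, ...) {
  agg <- stats::aggregate(absorbance ~ condition, x$wells, mean)
  cat("<adcc_plate>", nrow(x$wells), "wells\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

condition_mean <- function(plate, condition) {
  v <- plate$wells$absorbance[plate$wells$condition == condition]
  if (!length(v)) stop("condition absent from plate: ", condition)
  mean(v)
}

#' Specific lysis from LDH absorbances
#'
#' The mean medium absorbance is subtracted from every condition mean first
#' (background correction), then
#' `(treated - untreated co-culture) / (Triton - target alone) * 100`.
#'
#' @param plate an [adcc_plate()]
#' @param treated_condition the antibody-treated co-culture condition
#' @return specific lysis in percent; `NA` with a warning when the
#'   Triton/target-alone denominator is not positive (invalid assay)
#' @examples
#' w <- expand.grid(condition = c("medium", "target_alone", "target_triton",
#'                                "coculture_unstim", "coculture_cet"),
#'                  replicate = 1:3)
#' w$absorbance <- c(0.1, 0.5, 1.3, 0.6, 0.9)[as.integer(w$condition)]
#' specific_lysis(adcc_plate(w), "coculture_cet") # 37.5
#' @export
specific_lysis <- function(plate, treated_condition = "coculture_cet") {
  bg <- condition_mean(plate, "medium")
  treated <- condition_mean(plate, treated_condition) - bg
  unstim <- condition_mean(plate, "coculture_unstim") - bg
  triton <- condition_mean(plate, "target_triton") - bg
  alone <- condition_mean(plate, "target_alone") - bg
  denom <- triton - alone
  if (denom <= 0) {
    warning("invalid assay: Triton - target-alone denominator <= 0")
    return(NA_real_)
  }
  (treated - unstim) / denom * 100
}

#' Relative decrease in viable tumour cells by flow
#'
#' `(%unstimulated - %treated) / %unstimulated * 100`, the flow-cytometric
#' ADCC readout over viable (EpCAM+, DAPI- AnnexinV-) tumour cells.
#'
#' @param pct_viable_unstim,pct_viable_treated viable-tumour percentages
#' @return percentage decrease; `NA` with a warning at zero unstimulated
#'   viability
#' @export
delta_tumour_facs <- function(pct_viable_unstim, pct_viable_treated) {
  if (any(pct_viable_unstim <= 0)) {
    warning("zero unstimulated viability: delta undefined")
    return(ifelse(pct_viable_unstim > 0,
                  (pct_viable_unstim - pct_viable_treated) /
                    pct_viable_unstim * 100, NA_real_))
  }
  (pct_viable_unstim - pct_viable_treated) / pct_viable_unstim * 100
}

#' The 77-parameter ADCC readout manifest
#'
#' Reconstructed enumeration of the marker x population combinations of the
#' co-culture panel: population frequencies, viability classes, marker
#' positive-fractions and MFIs across tumour cells, NK compartments, T cells
#' and monocytes.
#'
#' @param version manifest version (only `"v1"` is shipped)
#' @return data.frame with columns `name`, `population`, `kind`, `marker`
#' @export
adcc_param_manifest <- function(version = "v1") {
  path <- system.file("extdata",
                      paste0("adcc_param_manifest_", version, ".csv"),
                      package = "fcgrflow", mustWork = FALSE)
  m <- if (nzchar(path) && file.exists(path))
    utils::read.csv(path, stringsAsFactors = FALSE)
  else build_adcc_param_manifest()
  stopifnot(nrow(m) == 77, !anyDuplicated(m$name))
  attr(m, "version") <- version
  m
}

build_adcc_param_manifest <- function() {
  rows <- list()
  add <- function(name, population, kind, marker = "")
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, population = population, kind = kind, marker = marker,
      stringsAsFactors = FALSE)
  both <- function(pop, marker) {
    add(sprintf("%s_%s_pct", pop, marker), pop, "marker_pct", marker)
    add(sprintf("%s_%s_mfi", pop, marker), pop, "marker_mfi", marker)
  }
  nk_markers <- c("CD107a", "CD137", "PD1", "NKG2A", "NKG2D", "CD62L")
  add("tumour_freq", "tumour", "freq")
  for (v in c("viable", "dead", "dapi_only", "annexin_only"))
    add(sprintf("tumour_%s_pct", v), "tumour", "viability", v)
  both("tumour", "PDL1"); both("tumour", "CD40")
  for (ch in c("EpCAM", "DAPI", "AnnexinV"))
    add(sprintf("tumour_%s_mfi", ch), "tumour", "marker_mfi", ch)
  add("NK_freq", "NK", "freq")
  add("NK_CD16_pct", "NK", "marker_pct", "CD16")
  add("NK_CD16_mfi", "NK", "marker_mfi", "CD16")
  add("NK_CD56_mfi", "NK", "marker_mfi", "CD56")
  for (mk in nk_markers) both("NK", mk)
  add("NKdim_freq", "NK_dim", "freq")
  add("NKdim_CD16_mfi", "NK_dim", "marker_mfi", "CD16")
  for (mk in nk_markers) both("NKdim", mk)
  add("NKbright_freq", "NK_bright", "freq")
  for (mk in nk_markers) both("NKbright", mk)
  add("T_freq", "T", "freq")
  for (mk in nk_markers) both("T", mk)
  add("mono_freq", "monocytes", "freq")
  for (mk in c("CD40", "PDL1", "CD62L", "PD1")) both("mono", mk)
  do.call(rbind, rows)
}

# population label behind each manifest name prefix
MANIFEST_POPS <- c(tumour = "tumour", NK = "NK", NKdim = "NK_dim",
                   NKbright = "NK_bright", T = "T", mono = "monocytes")

#' Compute the 77-parameter readout of one ADCC panel sample
#'
#' Gates the frame with [gate_adcc_panel()] and summarises population
#' frequencies (percent of singlets, NK subsets percent of NK), tumour
#' viability classes (percent of tumour), marker-positive percentages and
#' marker MFIs (median over the whole population).
#'
#' @param frame an [event_frame()] with the ADCC panel channels
#' @param gated optional precomputed [gate_adcc_panel()] result
#' @param manifest an [adcc_param_manifest()]
#' @return named numeric vector of length 77
#' @export
adcc_readout <- function(frame, gated = NULL,
                         manifest = adcc_param_manifest()) {
  if (is.null(gated)) gated <- gate_adcc_panel(frame)
  masks <- gated$masks
  out <- stats::setNames(rep(NA_real_, nrow(manifest)), manifest$name)
  viab_map <- c(viable = "viable_tumour", dead = "dead_tumour",
                dapi_only = "dapi_only_tumour",
                annexin_only = "annexin_only_tumour")
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    pop <- MANIFEST_POPS[[sub("_.*$", "", r$name)]]
    out[r$name] <- switch(
      r$kind,
      freq = masks[[pop]]$frequency,
      viability = masks[[viab_map[[r$marker]]]]$frequency,
      marker_pct = {
        mm <- gated$marker_masks[[pop]][[r$marker]]
        if (is.null(mm)) NA_real_ else mm$frequency
      },
      marker_mfi = compute_mfi(frame, masks[[pop]], r$marker))
  }
  out
}

#' Build the 154-measure delta / fold-change table
#'
#' For each of the 77 base parameters p: `delta_p = unstimulated_p -
#' treated_p` (so treatment-induced decreases are positive deltas) and
#' `fc_p = treated_p / unstimulated_p` (so FC < 1 encodes a decrease;
#' flagged `NA` when the unstimulated value is 0).
#'
#' @param readout_unstim,readout_treated named 77-parameter vectors sharing
#'   the same manifest
#' @return named numeric vector of length 154 (`delta_*` then `fc_*`)
#' @export
build_param_table <- function(readout_unstim, readout_treated) {
  if (!identical(names(readout_unstim), names(readout_treated)))
    stop("readout manifests do not match")
  delta <- readout_unstim - readout_treated
  fc <- ifelse(readout_unstim == 0, NA_real_,
               readout_treated / readout_unstim)
  out <- c(stats::setNames(delta, paste0("delta_", names(readout_unstim))),
           stats::setNames(fc, paste0("fc_", names(readout_unstim))))
  stopifnot(length(out) == 2 * length(readout_unstim))
  out
}

#' Brunner-Munzel rank test
#'
#' Nonparametric test of the stochastic-equality hypothesis
#' P(X < Y) + 0.5 P(X = Y) = 0.5, using the rank-based variance estimator and
#' a t reference distribution with Welch-type degrees of freedom.
#'
#' @param x,y numeric samples (>= 3 each)
#' @return list with `statistic`, `df`, `p_value` (two-sided) and `estimate`
#'   (the relative effect P(X < Y) + 0.5 P(X = Y))
#' @export
brunner_munzel_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3 || n2 < 3) stop("Brunner-Munzel needs >= 3 per group")
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  ri1 <- rank(x); ri2 <- rank(y)
  m1 <- mean(r1); m2 <- mean(r2)
  pst <- (m2 - (n2 + 1) / 2) / n1 # relative effect P(X<Y)+.5P(X=Y)
  v1 <- sum((r1 - ri1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - ri2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (v1 + v2 == 0) { # all values tied: no evidence against equality
    return(list(statistic = 0, df = Inf, p_value = 1, estimate = pst))
  }
  stat <- n1 * n2 * (m2 - m1) / ((n1 + n2) * sqrt(n1 * v1 + n2 * v2))
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  list(statistic = stat, df = df, p_value = p, estimate = pst)
}

#' Group comparisons over a parameter table
#'
#' Applies the chosen test to every parameter column, with unadjusted
#' p-values at `alpha` — the screen is exploratory by design, favouring
#' sensitivity over family-wise control.
#'
#' @param table data.frame of parameters (rows = donors)
#' @param group group label per donor (2 groups for the rank tests, 3 for
#'   ANOVA + Tukey)
#' @param test `"mann_whitney_u"`, `"brunner_munzel"` or `"anova_tukey"`
#' @param alpha significance level for the `significant` flag
#' @param exact_max per-group size up to which the Mann-Whitney p is exact
#'   (normal approximation with tie correction above)
#' @return data.frame with one row per parameter: `parameter`, `statistic`,
#'   `p_value`, `significant`, `adjusted` (always `FALSE`), group summaries;
#'   ANOVA results carry Tukey pairwise comparisons as an attribute
#' @export
compare_groups <- function(table, group,
                           test = c("mann_whitney_u", "brunner_munzel",
                                    "anova_tukey"),
                           alpha = 0.05, exact_max = 8) {
  test <- match.arg(test)
  table <- as.data.frame(table)
  group <- factor(group)
  ng <- table(group)
  if (test %in% c("mann_whitney_u", "brunner_munzel") && nlevels(group) != 2)
    stop("two groups required for rank tests")
  if (test == "anova_tukey" && nlevels(group) < 3)
    stop("three groups required for ANOVA + Tukey")
  if (any(ng < 2) || (test == "brunner_munzel" && any(ng < 3)))
    stop("insufficient group size")
  tukey <- list()
  rows <- lapply(colnames(table), function(pn) {
    v <- table[[pn]]
    ok <- is.finite(v)
    vv <- v[ok]; gg <- droplevels(group[ok])
    if (nlevels(gg) < nlevels(group) || any(table(gg) < 2))
      return(data.frame(parameter = pn, statistic = NA_real_,
                        p_value = NA_real_, significant = NA,
                        adjusted = FALSE))
    res <- switch(test,
      mann_whitney_u = {
        x1 <- vv[gg == levels(gg)[1]]; x2 <- vv[gg == levels(gg)[2]]
        use_exact <- max(length(x1), length(x2)) <= exact_max &&
          !any(duplicated(c(x1, x2)))
        w <- suppressWarnings(stats::wilcox.test(
          x1, x2, exact = use_exact, correct = TRUE))
        c(w$statistic, w$p.value)
      },
      brunner_munzel = {
        b <- brunner_munzel_test(vv[gg == levels(gg)[1]],
                                 vv[gg == levels(gg)[2]])
        c(b$statistic, b$p_value)
      },
      anova_tukey = {
        fit <- stats::aov(vv ~ gg)
        tukey[[pn]] <<- stats::TukeyHSD(fit)$gg
        s <- summary(fit)[[1]]
        c(s$`F value`[1], s$`Pr(>F)`[1])
      })
    data.frame(parameter = pn, statistic = unname(res[1]),
               p_value = unname(res[2]),
               significant = unname(res[2]) < alpha, adjusted = FALSE)
  })
  out <- do.call(rbind, rows)
  means <- t(vapply(colnames(table), function(pn)
    tapply(table[[pn]], group, mean, na.rm = TRUE),
    numeric(nlevels(group))))
  colnames(means) <- paste0("mean_", levels(group))
  out <- cbind(out, means)
  rownames(out) <- NULL
  if (test == "anova_tukey") attr(out, "tukey") <- tukey
  out
}

#' Correlate the LDH and flow cytotoxicity readouts
#'
#' @param lysis_ldh per-donor specific lysis (LDH)
#' @param delta_facs per-donor flow tumour-kill delta
#' @return list with Pearson `r`, two-sided `p_value`, `n`
#' @export
correlate_readouts <- function(lysis_ldh, delta_facs) {
  ok <- is.finite(lysis_ldh) & is.finite(delta_facs)
  if (sum(ok) < 3) stop("need >= 3 paired values")
  if (stats::sd(lysis_ldh[ok]) == 0 || stats::sd(delta_facs[ok]) == 0)
    stop("zero variance in a readout")
  ct <- stats::cor.test(lysis_ldh[ok], delta_facs[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' tSNE embedding of a z-scored parameter table
#'
#' Columns are z-scored across donors (zero-variance columns dropped with a
#' warning); the exact-mode embedding is deterministic given the seed.
#'
#' @param table data.frame or matrix, rows = donors, columns = parameters
#' @param seed integer seed
#' @param perplexity tSNE perplexity (default 10, suited to cohorts of ~45);
#'   must satisfy `n >= 3 * perplexity + 2`
#' @return matrix of 2D coordinates, one row per donor; the z-scored input is
#'   attached as attribute `"scaled"`
#' @export
embed_tsne <- function(table, seed = 1L, perplexity = 10) {
  x <- as.matrix(table)
  sds <- apply(x, 2, stats::sd)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    warning(sum(drop), " zero-variance parameter(s) dropped before tSNE")
    x <- x[, !drop, drop = FALSE]
  }
  z <- scale(x)
  n <- nrow(z)
  if (n < 3 * perplexity + 2)
    stop("perplexity ", perplexity, " infeasible for n = ", n)
  emb <- with_seed(seed,
    Rtsne::Rtsne(z, dims = 2, perplexity = perplexity, theta = 0,
                 check_duplicates = FALSE, pca = FALSE,
                 max_iter = 500, verbose = FALSE))
  coords <- emb$Y
  rownames(coords) <- rownames(table)
  colnames(coords) <- c("tsne1", "tsne2")
  attr(coords, "scaled") <- z
  coords
}
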