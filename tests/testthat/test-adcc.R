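# ADCC quantification: specific lysis, flow delta, the 154-measure table,
# rank statistics, correlation, embedding.

test_that("specific lysis reproduces its anchor cases", {
  # null effect: treated equals untreated co-culture
  p0 <- make_plate(c(medium = 0.1, target_alone = 0.5, target_triton = 1.1,
                     coculture_unstim = 0.6, coculture_cet = 0.6))
  expect_equal(specific_lysis(p0), 0)
  # full lysis: treated - untreated equals Triton - target alone
  p1 <- make_plate(c(medium = 0.1, target_alone = 0.5, target_triton = 1.1,
                     coculture_unstim = 0.6, coculture_cet = 1.2))
  expect_equal(specific_lysis(p1), 100)
  # hand-computed mid case on raw ODs
  p2 <- make_plate(c(medium = 0.1, target_alone = 0.5, target_triton = 1.3,
                     coculture_unstim = 0.6, coculture_cet = 0.9))
  expect_equal(specific_lysis(p2), 37.5)
})

test_that("specific lysis is invariant to a constant offset on every well", {
  base <- c(medium = 0.1, target_alone = 0.5, target_triton = 1.3,
            coculture_unstim = 0.6, coculture_cet = 0.9)
  expect_equal(specific_lysis(make_plate(base + 0.23)),
               specific_lysis(make_plate(base)), tolerance = 1e-12)
})

test_that("invalid assays are flagged, not silently computed", {
  p <- make_plate(c(medium = 0.1, target_alone = 1.3, target_triton = 0.5,
                    coculture_unstim = 0.6, coculture_cet = 0.9))
  expect_warning(out <- specific_lysis(p), "denominator")
  expect_true(is.na(out))
  expect_error(make_plate(c(target_alone = 0.5, target_triton = 1.3,
                            coculture_unstim = 0.6, coculture_cet = 0.9)),
               "medium")
  expect_error(specific_lysis(make_plate(
    c(medium = 0.1, target_alone = 0.5, target_triton = 1.3,
      coculture_unstim = 0.6)), "coculture_cet"), "absent")
})

test_that("flow tumour-kill delta reproduces its anchors and flags zero baselines", {
  expect_equal(delta_tumour_facs(40, 40), 0)
  expect_equal(delta_tumour_facs(40, 0), 100)
  expect_equal(delta_tumour_facs(40, 30), 25)
  expect_warning(out <- delta_tumour_facs(0, 10), "zero")
  expect_true(is.na(out))
})

test_that("the delta/FC table has 154 mutually consistent measures", {
  man <- adcc_param_manifest()
  expect_identical(nrow(man), 77L)
  u <- stats::setNames(seq(1, 77) + 0.5, man$name)
  tr <- u * 0.8
  tab <- build_param_table(u, tr)
  expect_length(tab, 154)
  # joint invertibility: treated = unstim - delta = unstim * FC per row
  d <- tab[paste0("delta_", man$name)]
  fc <- tab[paste0("fc_", man$name)]
  expect_equal(unname(u - d), unname(tr), tolerance = 1e-12)
  expect_equal(unname(u * fc), unname(tr), tolerance = 1e-12)

  same <- build_param_table(u, u)
  expect_true(all(same[paste0("delta_", man$name)] == 0))
  expect_true(all(same[paste0("fc_", man$name)] == 1))

  # sign convention: a CD16 drop from 80 to 60 is a positive delta
  u2 <- u; t2 <- u
  u2[["NK_CD16_pct"]] <- 80; t2[["NK_CD16_pct"]] <- 60
  tab2 <- build_param_table(u2, t2)
  expect_equal(tab2[["delta_NK_CD16_pct"]], 20)
  expect_equal(tab2[["fc_NK_CD16_pct"]], 0.75)

  expect_error(build_param_table(u, unname(tr)), "manifest")
})

test_that("Mann-Whitney on {1,2,3} vs {4,5,6} matches exact enumeration", {
  res <- compare_groups(data.frame(p = c(1, 2, 3, 4, 5, 6)),
                        rep(c("a", "b"), each = 3), test = "mann_whitney_u")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  # oracle: enumerate all 20 assignments of ranks to group a
  combos <- combn(6, 3)
  u_stats <- apply(combos, 2, function(i) sum(rank(1:6)[i]) - 3 * 4 / 2)
  u_obs <- 0
  p_exact <- mean(pmin(u_stats, 9 - u_stats) <= min(u_obs, 9 - u_obs))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("Brunner-Munzel agrees with Mann-Whitney on large symmetric samples", {
  x <- withr::with_seed(31, rnorm(100))
  y <- withr::with_seed(32, rnorm(100, 0.2))
  bm <- brunner_munzel_test(x, y)
  mw <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_lt(abs(bm$p_value - mw$p.value), 0.05)
  expect_between(bm$estimate, 0, 1)
  expect_error(brunner_munzel_test(1:2, 1:5), ">= 3")
})

test_that("shifted groups at the study arm sizes are detected reliably", {
  hits <- sapply(1:100, function(s) {
    x <- withr::with_seed(4000 + s, rnorm(10))
    y <- withr::with_seed(8000 + s, rnorm(35, 3)) # 3 pooled SDs apart
    wilcox.test(x, y, exact = FALSE)$p.value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("identical groups are never called significant by the rank tests", {
  v <- c(rep(1:5, 2), rep(1:5, 2)) # group b repeats group a exactly
  g <- rep(c("a", "b"), each = 10)
  res <- compare_groups(data.frame(p = v), g, test = "mann_whitney_u")
  expect_gt(res$p_value, 0.9)
  res_bm <- compare_groups(data.frame(p = v), g, test = "brunner_munzel")
  expect_gt(res_bm$p_value, 0.9)
})

test_that("three-group comparisons run ANOVA with Tukey pairs attached", {
  set.seed(9)
  d <- data.frame(p1 = c(rnorm(8), rnorm(8, 3), rnorm(8, 6)),
                  p2 = rnorm(24))
  g <- rep(c("a", "b", "c"), each = 8)
  res <- compare_groups(d, g, test = "anova_tukey")
  expect_lt(res$p_value[res$parameter == "p1"], 0.001)
  expect_gt(res$p_value[res$parameter == "p2"], 0.05)
  tk <- attr(res, "tukey")
  expect_identical(rownames(tk$p1), c("b-a", "c-a", "c-b"))
  expect_error(compare_groups(d, rep(c("a", "b"), each = 12),
                              test = "anova_tukey"), "three groups")
})

test_that("LDH and flow cytotoxicity readouts correlate through the shared latent", {
  cfg <- test_cfg(n_events_adcc = 5000)
  res <- t(sapply(1:50, function(d) {
    g <- c("FF", "VF", "VV")[1 + d %% 3]
    lat <- fcgrflow:::donor_latents(cfg, g, "healthy", 31 * d)
    truth <- list(donor_id = sprintf("D%d", d), genotype = g,
                  cohort = "healthy",
                  latent_lysis_capacity = lat$latent_lysis_capacity)
    p <- simulate_adcc_plate(cfg, truth, seed = 5 * d + 1)
    c(ldh = specific_lysis(p$plate),
      facs = delta_tumour_facs(
        p$readouts$coculture_unstim[["tumour_viable_pct"]],
        p$readouts$coculture_cet[["tumour_viable_pct"]]))
  }))
  ct <- correlate_readouts(res[, "ldh"], res[, "facs"])
  expect_gt(ct$r, 0.8)
  expect_lt(ct$p_value, 1e-6)
  expect_equal(correlate_readouts(1:5, (1:5) * 2)$r, 1)
  expect_equal(correlate_readouts(1:5, -(1:5))$r, -1)
  expect_error(correlate_readouts(rep(1, 5), 1:5), "zero variance")
})

test_that("tSNE embedding is deterministic, z-scored, and separates cohorts", {
  cfg <- test_cfg(n_events_adcc = 4000)
  param_row <- function(cohort, d) {
    g <- c("FF", "VF", "VV")[1 + d %% 3]
    lat <- fcgrflow:::donor_latents(cfg, g, cohort, 77 * d)
    truth <- list(donor_id = sprintf("%s%d", cohort, d), genotype = g,
                  cohort = cohort,
                  latent_lysis_capacity = lat$latent_lysis_capacity)
    p <- simulate_adcc_plate(cfg, truth, seed = 13 * d +
                               (cohort == "mCRC") * 7)
    build_param_table(p$readouts$coculture_unstim, p$readouts$coculture_cet)
  }
  tabs <- rbind(do.call(rbind, lapply(1:16, param_row, cohort = "healthy")),
                do.call(rbind, lapply(17:32, param_row, cohort = "mCRC")))
  labels <- rep(c(1, 2), each = 16)
  keep <- colSums(!is.finite(tabs)) == 0
  emb <- suppressWarnings(embed_tsne(tabs[, keep], seed = 4, perplexity = 8))
  emb2 <- suppressWarnings(embed_tsne(tabs[, keep], seed = 4, perplexity = 8))
  expect_identical(emb[, 1:2], emb2[, 1:2])
  z <- attr(emb, "scaled")
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(labels, dist(emb[, 1:2]))
  expect_gt(mean(sil[, "sil_width"]), 0.25)
  expect_error(embed_tsne(tabs[1:10, keep], perplexity = 10), "infeasible")
})

test_that("the unadjusted exploratory screen flags at the nominal level only", {
  # spot check on a 20-parameter null table; the full calibration lives in
  # the acceptance suite
  set.seed(60)
  d <- as.data.frame(matrix(rnorm(45 * 20), 45))
  g <- rep(c("h", "m"), c(10, 35))
  res <- compare_groups(d, g, test = "mann_whitney_u")
  expect_true(all(!res$adjusted))
  expect_lte(sum(res$significant), 4)
})
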