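# Shared fixtures, built once per test run and cached. Event counts are kept
# small (thousands, not the 1e5 study default) so the suite stays fast; the
# statistical structure is unchanged.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_cfg <- function(...) {
  args <- list(n_events_per_sample = 6000, n_events_adcc = 6000)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(fcgr_sim_config, args)
}

# 18-donor cohort + features: the workhorse for model-level tests
small_cohort <- function() cached("small_cohort", {
  cfg <- test_cfg()
  co <- simulate_cohort(cfg, 18, c(FF = 4, VF = 4, VV = 2), seed = 301)
  list(cohort = co, features = suppressWarnings(build_feature_table(co)))
})

# train/test pair mirroring the study arms, reduced event count
study_cohorts <- function() cached("study_cohorts", {
  cfg <- test_cfg()
  tr <- simulate_cohort(cfg, 39, c(FF = 4, VF = 4, VV = 2), seed = 101)
  te <- simulate_cohort(cfg, 52, c(FF = 42, VF = 40, VV = 17),
                        cohort = "mCRC", seed = 202)
  list(cfg = cfg,
       train = suppressWarnings(build_feature_table(tr)),
       test = suppressWarnings(build_feature_table(te)))
})

# a well-formed LDH plate with identical triplicates per condition
make_plate <- function(ods, replicates = 3) {
  wells <- do.call(rbind, lapply(names(ods), function(cd) data.frame(
    condition = cd, replicate = seq_len(replicates), absorbance = ods[[cd]],
    stringsAsFactors = FALSE)))
  adcc_plate(wells)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}

# independent dense-grid brute force for the MFI-boundary baseline: three
# MEM bands x two LNK halves, majority class per cell
baseline_brute_force <- function(mem, lnk, y, grid_n = 60) {
  yi <- as.integer(factor(y, c("FF", "VF", "VV")))
  gm <- seq(min(mem) - 1, max(mem) + 1, length.out = grid_n)
  gl <- seq(min(lnk) - 1, max(lnk) + 1, length.out = grid_n)
  best <- 0
  for (tl in gl) {
    hi <- lnk > tl
    for (a in seq_along(gm)) for (b in a:length(gm)) {
      cell <- 1L + (mem > gm[a]) + (mem > gm[b]) + 3L * hi
      cmat <- matrix(tabulate(cell + 6L * (yi - 1L), nbins = 18L), nrow = 6)
      best <- max(best, sum(apply(cmat, 1, max)) / length(y))
    }
  }
  best
}
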