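# Construction of the 30 genotyping parameters per sample.
#
# For each anti-CD16 clone c (M = MEM154, L = LNK16) the NK compartment is
# partitioned into CD56bright / CD56dim CD16+ / CD56dim CD16- using CD16
# positivity on clone c's channel. Within every clone-defined subset the MFI
# of both clone channels is taken, plus the subset frequency as % of NK and
# as % of all (non-doublet) events, plus per-subset M/L ratios. The manifest
# is versioned and machine-readable so alternative enumerations can be
# swapped without code change.

FEATURE_SUBSETS <- c(NKbright = "bright", NKdim = "dim_cd16pos",
                     NKdimneg = "dim_cd16neg")
CLONE_CHANNELS <- c(M = "CD16-MEM154", L = "CD16-LNK16")

#' The 30-feature genotyping manifest
#'
#' @param version manifest version (only `"v1"` is shipped)
#' @return data.frame with one row per feature: `name`, `kind` (one of
#'   `mfi`, `freq_nk`, `freq_total`, `ratio_mfi`, `ratio_freq`), `subset`,
#'   `partition` (clone defining the subset), `channel`, and for ratios the
#'   `numerator`/`denominator` feature names
#' @examples
#' nrow(feature_manifest()) # 30
#' @export
feature_manifest <- function(version = "v1") {
  path <- system.file("extdata", paste0("feature_manifest_", version, ".csv"),
                      package = "fcgrflow", mustWork = FALSE)
  if (nzchar(path) && file.exists(path)) {
    m <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    m <- build_feature_manifest()
  }
  stopifnot(nrow(m) == 30, !anyDuplicated(m$name))
  attr(m, "version") <- version
  m
}

# Deterministic in-code builder; the shipped CSV is its frozen output.
build_feature_manifest <- function() {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (p in names(CLONE_CHANNELS)) {
    for (s in names(FEATURE_SUBSETS)) {
      for (ch in names(CLONE_CHANNELS)) {
        add(name = sprintf("MFI_%s_%s_%s", ch, s, p), kind = "mfi",
            subset = s, partition = p, channel = CLONE_CHANNELS[[ch]],
            numerator = "", denominator = "")
      }
      add(name = sprintf("F_%s_%s", s, p), kind = "freq_nk",
          subset = s, partition = p, channel = "",
          numerator = "", denominator = "")
      add(name = sprintf("Ft_%s_%s", s, p), kind = "freq_total",
          subset = s, partition = p, channel = "",
          numerator = "", denominator = "")
    }
  }
  for (s in names(FEATURE_SUBSETS)) {
    add(name = sprintf("rMFI_%sML", s), kind = "ratio_mfi",
        subset = s, partition = "", channel = "",
        numerator = sprintf("MFI_M_%s_M", s),
        denominator = sprintf("MFI_L_%s_L", s))
    add(name = sprintf("rF_%sML", s), kind = "ratio_freq",
        subset = s, partition = "", channel = "",
        numerator = sprintf("F_%s_M", s),
        denominator = sprintf("F_%s_L", s))
  }
  do.call(rbind, rows)
}

#' Median fluorescence intensity over a gated population
#'
#' @param frame an [event_frame()]
#' @param mask a [population_mask()] or logical vector
#' @param channel channel name
#' @return the median intensity; `NA` (flagged missing) for an empty mask
#' @export
compute_mfi <- function(frame, mask, channel) {
  m <- if (inherits(mask, "population_mask")) mask$member else as.logical(mask)
  v <- channel_values(frame, channel, m)
  if (length(v) == 0) return(NA_real_)
  stats::median(v)
}

#' Run the genotyping gating hierarchy on one sample
#'
#' Doublet/debris exclusion, NK gate, and both clone-defined NK subset
#' partitions.
#'
#' @param frame an [event_frame()] with the genotyping panel channels
#' @param thresholds optional named threshold overrides, passed through
#' @return list with `singlets`, `nk`, and `subsets` (one entry per clone)
#' @export
gate_sample <- function(frame, thresholds = list()) {
  singlets <- exclude_doublets(frame)
  nk <- gate_nk(frame, parent = singlets, thresholds = thresholds)
  subsets <- lapply(CLONE_CHANNELS, function(ch)
    split_nk_subsets(frame, nk, clone_channel = ch, thresholds = thresholds))
  list(singlets = singlets, nk = nk, subsets = subsets)
}

#' Construct the 30 genotyping features for one sample
#'
#' @param frame an [event_frame()]
#' @param gates result of [gate_sample()]; computed from `frame` when `NULL`
#' @param manifest a [feature_manifest()]
#' @return named numeric vector of length 30; features of empty subsets are
#'   `NA` (flagged missing, never silently imputed). Ratio features equal the
#'   quotient of their stored constituents exactly.
#' @export
construct_features <- function(frame, gates = NULL,
                               manifest = feature_manifest()) {
  if (is.null(gates)) gates <- gate_sample(frame)
  n_nk <- gates$nk$count
  n_tot <- gates$singlets$count
  out <- stats::setNames(rep(NA_real_, nrow(manifest)), manifest$name)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    if (row$kind %in% c("ratio_mfi", "ratio_freq")) next
    sub <- gates$subsets[[row$partition]][[FEATURE_SUBSETS[[row$subset]]]]
    out[row$name] <- switch(
      row$kind,
      mfi = compute_mfi(frame, sub, row$channel),
      freq_nk = if (n_nk > 0) 100 * sub$count / n_nk else NA_real_,
      freq_total = if (n_tot > 0) 100 * sub$count / n_tot else NA_real_)
  }
  for (i in which(manifest$kind %in% c("ratio_mfi", "ratio_freq"))) {
    row <- manifest[i, ]
    num <- out[[row$numerator]]
    den <- out[[row$denominator]]
    out[row$name] <- if (is.na(num) || is.na(den) || den == 0) NA_real_
                     else num / den
  }
  attr(out, "sample_id") <- frame$sample_id
  attr(out, "manifest_version") <- attr(manifest, "version")
  out
}

#' Build the feature table for a simulated or loaded cohort
#'
#' @param cohort a [simulate_cohort()] result, or a plain list of
#'   `list(frame=, meta=)` samples
#' @param manifest a [feature_manifest()]
#' @param thresholds optional gating threshold overrides
#' @return data.frame with sample metadata columns followed by the 30 features
#' @export
build_feature_table <- function(cohort, manifest = feature_manifest(),
                                thresholds = list()) {
  samples <- if (!is.null(cohort$samples)) cohort$samples else cohort
  rows <- lapply(samples, function(s) {
    fv <- construct_features(s$frame, gate_sample(s$frame, thresholds),
                             manifest)
    cbind(s$meta, as.data.frame(as.list(fv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest_version") <- attr(manifest, "version")
  out
}

#' Names of the 30 feature columns in a feature table
#' @param manifest a [feature_manifest()]
#' @return character vector of feature names
#' @export
feature_names <- function(manifest = feature_manifest()) manifest$name
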