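# Deterministic, density-driven gating.
#
# The gating hierarchy mirrors the two panels: doublet/debris exclusion, then
# CD3-CD14-CD56+ NK selection and clone-wise NK subset splitting for the
# genotyping panel; lineage + viability + activation-marker gates for the
# ADCC co-culture panel. Thresholds are data-driven (KDE valley between the
# two largest modes, falling back to a negative-population percentile) and
# every one of them can be overridden.

#' Data-driven positivity threshold for one channel
#'
#' Finds the minimum of a kernel density estimate between the two largest
#' genuine modes of `log(x)`. Candidate mode pairs must be separated by a
#' real dip (valley density at most `max_valley_ratio` of the lower peak),
#' which ignores sampling jitter on top of a single mode. If the distribution
#' is effectively unimodal, or the secondary mode carries < `min_mass` of
#' events on its side of the valley, returns `NA` so the caller can fall back
#' to a negative-population percentile.
#'
#' @param x positive intensities
#' @param min_mass minimal event mass required on each side of the valley
#' @param max_valley_ratio maximal valley-to-lower-peak density ratio for a
#'   dip to count as a mode separation
#' @return threshold on the original intensity scale, or `NA`
#' @export
density_valley <- function(x, min_mass = 0.02, max_valley_ratio = 0.75) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 50) return(NA_real_)
  lx <- log(x)
  d <- stats::density(lx, n = 512)
  y <- d$y
  # interior local maxima, tallest first, at most 5 candidates
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) < 2) return(NA_real_)
  peaks <- peaks[order(-y[peaks])][seq_len(min(5, length(peaks)))]
  pairs <- utils::combn(seq_along(peaks), 2)
  # try pairs in order of combined height (dominant modes first)
  ord <- order(-(y[peaks[pairs[1, ]]] + y[peaks[pairs[2, ]]]))
  for (k in ord) {
    pk <- peaks[pairs[, k]]
    lo <- min(pk); hi <- max(pk)
    seg <- y[lo:hi]
    vmin <- min(seg)
    if (vmin > max_valley_ratio * min(y[pk])) next
    # wide valleys are nearly flat: the argmin jitters with KDE noise, so
    # place the threshold at the centre of the near-minimum plateau
    plateau <- which(seg <= vmin + 0.05 * min(y[pk]))
    valley <- lo + as.integer(round(mean(range(plateau)))) - 1L
    thr <- d$x[valley]
    p_lo <- mean(lx < thr)
    if (p_lo < min_mass || p_lo > 1 - min_mass) next
    return(exp(thr))
  }
  NA_real_
}

# Threshold with fallback: valley if bimodal, else the 99.5th percentile of a
# negative reference population on the same channel.
threshold_or_fallback <- function(x, negative_ref = NULL, q = 0.995) {
  thr <- density_valley(x)
  if (!is.na(thr)) return(thr)
  if (!is.null(negative_ref) && length(negative_ref) > 0)
    return(as.numeric(stats::quantile(negative_ref, q, names = FALSE)))
  as.numeric(stats::quantile(x, q, names = FALSE))
}

#' Exclude doublets (and optionally debris) on scatter
#'
#' Retains events whose FSC-A/FSC-H ratio lies within a band around the
#' singlet diagonal, and above a debris floor on FSC-A.
#'
#' @param frame an [event_frame()] with FSC-A and FSC-H channels
#' @param band multiplicative half-width of the accepted FSC-A/FSC-H ratio
#'   band around the singlet diagonal
#' @param debris_floor minimum FSC-A; events below are removed as debris
#' @param ratio_center FSC-A/FSC-H ratio of the singlet diagonal; estimated
#'   from the frame's median ratio when `NULL` (assumes singlets dominate)
#' @return a [population_mask()] named `"singlets"`
#' @examples
#' cfg <- fcgr_sim_config(n_events_per_sample = 2000)
#' d <- simulate_donor(cfg, "VF", donor_seed = 3)
#' exclude_doublets(d$frame)
#' @export
exclude_doublets <- function(frame, band = 0.35, debris_floor = 2e4,
                             ratio_center = NULL) {
  need <- c("FSC-A", "FSC-H")
  miss <- setdiff(need, frame$channels)
  if (length(miss)) stop("missing scatter channel(s): ",
                         paste(miss, collapse = ", "))
  n <- n_events(frame)
  if (n == 0)
    return(population_mask(logical(0), "singlets"))
  a <- channel_values(frame, "FSC-A")
  h <- channel_values(frame, "FSC-H")
  ratio <- a / pmax(h, .Machine$double.eps)
  centre <- ratio_center
  if (is.null(centre)) {
    centre <- stats::median(ratio[a >= debris_floor], na.rm = TRUE)
    if (!is.finite(centre)) centre <- stats::median(ratio, na.rm = TRUE)
  }
  keep <- ratio >= centre * (1 - band) & ratio <= centre * (1 + band) &
    a >= debris_floor
  population_mask(keep, "singlets")
}

#' Gate CD3-CD14-CD56+ NK cells
#'
#' Events below the CD3 and CD14 positivity thresholds and above the CD56
#' threshold, within the parent mask (typically the singlet gate).
#'
#' @param frame an [event_frame()]
#' @param parent a [population_mask()] to gate within; defaults to all events
#' @param thresholds optional named list overriding the CD3/CD14/CD56
#'   thresholds; entries default to density valleys
#' @return a [population_mask()] named `"NK"`
#' @export
gate_nk <- function(frame, parent = NULL, thresholds = list()) {
  need <- c("CD3", "CD14", "CD56")
  miss <- setdiff(need, frame$channels)
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  pm <- if (is.null(parent)) rep(TRUE, n_events(frame)) else parent$member
  thr <- lapply(need, function(ch) {
    thresholds[[ch]] %||% threshold_or_fallback(channel_values(frame, ch, pm))
  })
  names(thr) <- need
  member <- pm &
    channel_values(frame, "CD3") < thr$CD3 &
    channel_values(frame, "CD14") < thr$CD14 &
    channel_values(frame, "CD56") > thr$CD56
  out <- population_mask(member, "NK",
                         parent = if (is.null(parent)) "root" else parent$name,
                         parent_member = pm)
  out$thresholds <- thr
  out
}

#' Split NK cells into CD56bright / CD56dim CD16+ / CD56dim CD16- subsets
#'
#' CD56bright vs dim at the density valley of CD56 within NK; CD16 positivity
#' of the dim subset is defined on the requested clone channel (valley if
#' bimodal, else the 99.5th percentile of CD3+ T events on that channel — the
#' internal negative population). The three masks are disjoint and their union
#' is the NK mask, so frequencies sum to 100% of NK.
#'
#' @param frame an [event_frame()]
#' @param nk_mask the NK [population_mask()]
#' @param clone_channel `"CD16-MEM154"` or `"CD16-LNK16"`
#' @param thresholds optional named list with `CD56` and/or the clone channel
#' @return list of three [population_mask()]s: `bright`, `dim_cd16pos`,
#'   `dim_cd16neg`
#' @export
split_nk_subsets <- function(frame, nk_mask,
                             clone_channel = c("CD16-MEM154", "CD16-LNK16"),
                             thresholds = list()) {
  clone_channel <- match.arg(clone_channel)
  if (!clone_channel %in% frame$channels)
    stop("invalid clone channel: ", clone_channel)
  nk <- nk_mask$member
  cd56 <- channel_values(frame, "CD56")
  t56 <- thresholds[["CD56"]]
  if (is.null(t56)) {
    t56 <- density_valley(cd56[nk])
    if (is.na(t56)) # effectively no bright mode visible: take high quantile
      t56 <- as.numeric(stats::quantile(cd56[nk], 0.99, names = FALSE))
  }
  bright <- nk & cd56 > t56
  dim_m <- nk & !bright

  clone <- channel_values(frame, clone_channel)
  tc <- thresholds[[clone_channel]]
  if (is.null(tc)) {
    neg <- NULL
    if ("CD3" %in% frame$channels) {
      t3 <- threshold_or_fallback(channel_values(frame, "CD3"))
      neg <- clone[channel_values(frame, "CD3") > t3]
    }
    tc <- threshold_or_fallback(clone[dim_m], negative_ref = neg)
  }
  pos <- dim_m & clone > tc

  list(bright = population_mask(bright, "NK_bright", "NK", nk),
       dim_cd16pos = population_mask(pos, "NK_dim_CD16pos", "NK", nk),
       dim_cd16neg = population_mask(dim_m & !pos, "NK_dim_CD16neg", "NK", nk),
       thresholds = list(CD56 = t56, clone = tc))
}

ADCC_LINEAGE <- c("EpCAM", "CD14", "CD3", "CD56")
ADCC_MARKERS <- c("CD107a", "CD137", "PD1", "PDL1", "CD40",
                  "NKG2A", "NKG2D", "CD62L", "CD16")

#' Gate the ADCC co-culture panel
#'
#' After doublet/debris exclusion: EpCAM+ tumour cells; among EpCAM- events
#' CD14+ monocytes, then CD3+ T cells, then CD3-CD14-CD56+ NK cells (split
#' into CD56dim CD16+ and CD56bright/CD16low). Tumour viability is classified
#' by DAPI and Annexin V into viable (double-negative), dead (double-positive)
#' and the two single-positive classes. Marker-positive sub-masks are computed
#' for every activation/checkpoint marker on its relevant populations.
#'
#' @param frame an [event_frame()] with the 15-colour ADCC panel channels
#' @param thresholds optional named list of per-channel threshold overrides
#' @return list with `masks` (named [population_mask()]s), `marker_masks`
#'   (nested list population -> marker -> mask) and `thresholds`
#' @export
gate_adcc_panel <- function(frame, thresholds = list()) {
  need <- c("FSC-A", "FSC-H", ADCC_LINEAGE, "DAPI", "AnnexinV", ADCC_MARKERS)
  miss <- setdiff(need, frame$channels)
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))

  singlets <- exclude_doublets(frame)
  sm <- singlets$member
  thr <- list()
  get_thr <- function(ch, values, neg = NULL) {
    t <- thresholds[[ch]] %||% threshold_or_fallback(values, neg)
    thr[[ch]] <<- t
    t
  }
  val <- function(ch) channel_values(frame, ch)

  epcam <- val("EpCAM"); t_ep <- get_thr("EpCAM", epcam[sm])
  tumour <- sm & epcam > t_ep
  nontum <- sm & !tumour
  cd14 <- val("CD14"); t14 <- get_thr("CD14", cd14[nontum])
  mono <- nontum & cd14 > t14
  cd3 <- val("CD3"); t3 <- get_thr("CD3", cd3[nontum & !mono])
  tcell <- nontum & !mono & cd3 > t3
  cd56 <- val("CD56"); t56 <- get_thr("CD56", cd56[nontum & !mono & !tcell])
  nk <- nontum & !mono & !tcell & cd56 > t56

  # NK subsets: bright by CD56 valley within NK, dim split by CD16
  t56b <- thresholds[["CD56_bright"]] %||% density_valley(cd56[nk])
  if (is.na(t56b))
    t56b <- as.numeric(stats::quantile(cd56[nk], 0.99, names = FALSE))
  thr[["CD56_bright"]] <- t56b
  nk_bright <- nk & cd56 > t56b
  cd16 <- val("CD16")
  t16 <- get_thr("CD16", cd16[nk & !nk_bright], neg = cd3[tcell])
  nk_dim <- nk & !nk_bright & cd16 > t16

  # tumour viability
  dapi <- val("DAPI"); annx <- val("AnnexinV")
  td <- get_thr("DAPI", dapi[tumour])
  ta <- get_thr("AnnexinV", annx[tumour])
  dapi_p <- dapi > td; annx_p <- annx > ta
  viable <- tumour & !dapi_p & !annx_p
  dead <- tumour & dapi_p & annx_p

  masks <- list(
    singlets = singlets,
    tumour = population_mask(tumour, "tumour", "singlets", sm),
    viable_tumour = population_mask(viable, "viable_tumour", "tumour", tumour),
    dead_tumour = population_mask(dead, "dead_tumour", "tumour", tumour),
    dapi_only_tumour = population_mask(tumour & dapi_p & !annx_p,
                                       "dapi_only_tumour", "tumour", tumour),
    annexin_only_tumour = population_mask(tumour & !dapi_p & annx_p,
                                          "annexin_only_tumour", "tumour",
                                          tumour),
    monocytes = population_mask(mono, "monocytes", "singlets", sm),
    T = population_mask(tcell, "T", "singlets", sm),
    NK = population_mask(nk, "NK", "singlets", sm),
    NK_dim = population_mask(nk_dim, "NK_dim", "NK", nk),
    NK_bright = population_mask(nk_bright, "NK_bright", "NK", nk))

  marker_pops <- list(
    tumour = c("PDL1", "CD40"),
    monocytes = c("CD40", "PDL1", "CD62L", "PD1"),
    T = c("CD107a", "CD137", "PD1", "NKG2A", "NKG2D", "CD62L"),
    NK = c("CD107a", "CD137", "PD1", "NKG2A", "NKG2D", "CD62L", "CD16"),
    NK_dim = c("CD107a", "CD137", "PD1", "NKG2A", "NKG2D", "CD62L"),
    NK_bright = c("CD107a", "CD137", "PD1", "NKG2A", "NKG2D", "CD62L"))
  marker_masks <- list()
  for (pop in names(marker_pops)) {
    pmask <- masks[[pop]]$member
    mm <- list()
    for (mk in marker_pops[[pop]]) {
      v <- val(mk)
      tm <- thr[[mk]] %||% get_thr(mk, v[sm], neg = NULL)
      mm[[mk]] <- population_mask(pmask & v > tm, paste0(pop, "_", mk, "pos"),
                                  pop, pmask)
    }
    marker_masks[[pop]] <- mm
  }
  list(masks = masks, marker_masks = marker_masks, thresholds = thr)
}
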