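# Synthetic ADCC co-cultures: event-level 15-colour panel frames per
# condition, plus LDH plate absorbances. The LDH signal and the flow-derived
# dead-tumour fraction share the donor's latent lysis capacity so the two
# readouts correlate, FF donors receive lower antibody-induced lysis, and
# mCRC donors carry the configured functional impairments.

ADCC_CHANNELS <- c("FSC-A", "FSC-H", "SSC-A", "EpCAM", "DAPI", "AnnexinV",
                   "CD107a", "CD137", "PD1", "PDL1", "CD40",
                   "NKG2A", "NKG2D", "CD62L", "CD16", "CD56", "CD3", "CD14")

ADCC_CONDITIONS <- c("medium", "target_alone", "target_triton",
                     "coculture_unstim", "coculture_cet", "coculture_cet_ave")

# Positive fractions and CD16 MFI location per population/marker, given the
# condition, cohort and realized lysis. Central place for all ADCC effects.
adcc_truth_params <- function(config, cohort, condition, lysis) {
  eff <- config$cohort_effects
  mcrc <- cohort == "mCRC"
  treated <- condition %in% c("coculture_cet", "coculture_cet_ave")
  synergy <- if (condition == "coculture_cet_ave") 1.3 else 1.0
  act_gain <- if (treated)
    0.25 * synergy * (1 - if (mcrc) eff$activation_induction_reduction else 0)
  else 0
  cd16_drop <- if (treated)
    1.0 * synergy * (1 - if (mcrc) eff$cd16_downreg_attenuation else 0)
  else 0
  pdl1_gain <- if (treated)
    0.35 * (1 - if (mcrc) eff$mono_pdl1_induction_reduction else 0)
  else 0
  pd1_nk <- 0.05 + if (mcrc) eff$pd1_nk_elevation else 0
  # tumour viability classes
  base <- c(viable = 0.85, dead = 0.09, dapi = 0.03, annexin = 0.03)
  killed <- base[["viable"]] * lysis
  viab <- c(viable = base[["viable"]] - killed,
            dead = base[["dead"]] + 0.85 * killed,
            dapi = base[["dapi"]] + 0.075 * killed,
            annexin = base[["annexin"]] + 0.075 * killed)
  tum_pdl1 <- if (treated && !mcrc) 0.40 else 0.60
  list(
    viability = viab / sum(viab),
    tumour = c(PDL1 = tum_pdl1, CD40 = 0.30),
    NK = c(CD107a = 0.05 + act_gain, CD137 = 0.05 + act_gain,
           PD1 = pd1_nk, NKG2A = 0.30, NKG2D = 0.80, CD62L = 0.50),
    nk_cd16_frac = max(0.05, 0.90 - (if (treated) 0.15 * synergy *
      (1 - if (mcrc) eff$cd16_downreg_attenuation else 0) else 0)),
    nk_cd16_loc = 5.0 - cd16_drop,
    T = c(CD107a = if (treated) 0.02 else 0.01, CD137 = 0.05,
          PD1 = if (mcrc) 0.30 else 0.20, NKG2A = 0.05, NKG2D = 0.30,
          CD62L = 0.60),
    mono = c(CD40 = 0.50, PDL1 = 0.30 + pdl1_gain, CD62L = 0.80, PD1 = 0.05))
}

# Realized lysis fraction for a donor under a condition (0 outside co-culture
# with antibody), with a small seeded assay noise.
realized_lysis <- function(truth, config, condition, seed) {
  if (!condition %in% c("coculture_cet", "coculture_cet_ave")) return(0)
  base <- truth$latent_lysis_capacity
  with_seed(seed, max(0, min(1, base + rnorm(1, 0, 0.03))))
}

#' Simulate one ADCC co-culture sample at event level
#'
#' @param config an [fcgr_sim_config()]
#' @param truth one-row donor truth (from [simulate_cohort()]'s `truth`, or a
#'   list with `genotype`, `cohort`, `latent_lysis_capacity`)
#' @param condition one of the co-culture conditions
#' @param seed integer seed
#' @param n_events event count (default `config$n_events_adcc`)
#' @return list with `frame` (an [event_frame()] with the ADCC panel
#'   channels), `lysis` (realized dead fraction among initially viable tumour
#'   cells) and `params` (the generating parameters)
#' @export
simulate_adcc_sample <- function(config, truth, condition = "coculture_unstim",
                                 seed = 1L, n_events = config$n_events_adcc) {
  condition <- match.arg(condition, ADCC_CONDITIONS)
  lys <- realized_lysis(truth, config, condition, derive_seed(seed, 3))
  par <- adcc_truth_params(config, truth$cohort, condition, lys)
  with_seed(seed, {
    n <- as.integer(n_events)
    fr <- c(tumour = 0.09, T = 0.40, monocyte = 0.14,
            NK_dim = 0.08, NK_bright = 0.01, other = 0.28)
    pops <- sample(names(fr), n, replace = TRUE, prob = fr)
    es <- config$event_sd; bg <- config$background_location
    m <- matrix(exp(rnorm(n * length(ADCC_CHANNELS), bg, es)),
                n, length(ADCC_CHANNELS),
                dimnames = list(NULL, ADCC_CHANNELS))
    m[, "FSC-A"] <- rnorm(n, 5.5e4, 7e3)
    m[, "FSC-H"] <- m[, "FSC-A"] * 0.95 + rnorm(n, 0, 1500)
    m[, "SSC-A"] <- rnorm(n, 3.5e4, 6e3)

    pos <- function(idx, ch, frac = 1, loc = 6) {
      hit <- idx & (stats::runif(n) < frac)
      m[hit, ch] <<- exp(rnorm(sum(hit), loc, es))
      hit
    }
    tum <- pops == "tumour"
    pos(tum, "EpCAM")
    vcls <- character(n)
    vcls[tum] <- sample(names(par$viability), sum(tum), replace = TRUE,
                        prob = par$viability)
    pos(vcls %in% c("dead", "dapi"), "DAPI")
    pos(vcls %in% c("dead", "annexin"), "AnnexinV")
    pos(tum, "PDL1", par$tumour[["PDL1"]])
    pos(tum, "CD40", par$tumour[["CD40"]])

    mono <- pops == "monocyte"
    pos(mono, "CD14")
    for (mk in names(par$mono)) pos(mono, mk, par$mono[[mk]])

    tc <- pops == "T"
    pos(tc, "CD3")
    for (mk in names(par$T)) pos(tc, mk, par$T[[mk]])

    nkd <- pops == "NK_dim"; nkb <- pops == "NK_bright"
    pos(nkd, "CD56", loc = 5.5)
    pos(nkb, "CD56", loc = 7.5)
    for (mk in names(par$NK)) pos(nkd | nkb, mk, par$NK[[mk]])
    pos(nkd, "CD16", par$nk_cd16_frac, loc = par$nk_cd16_loc)

    sample_id <- sprintf("%s_%s", truth$donor_id %||% "donor", condition)
    list(frame = event_frame(m, ADCC_CHANNELS, sample_id),
         lysis = lys, params = par,
         truth_pop = pops, truth_viability = vcls)
  })
}

#' Simulate an LDH plate and flow readouts for one donor
#'
#' Builds triplicate absorbances for the required conditions from a simple
#' additive optical-density model: medium background, spontaneous target
#' release, effector background, and antibody-induced lysis proportional to
#' the donor's latent capacity. Flow readouts for the unstimulated and
#' antibody-treated co-cultures are computed by gating simulated event frames
#' with [gate_adcc_panel()], so LDH and flow share the same latent lysis.
#'
#' @param config an [fcgr_sim_config()]
#' @param truth one-row donor truth (see [simulate_adcc_sample()])
#' @param conditions plate conditions; must contain medium, target_alone,
#'   target_triton, coculture_unstim and at least one treated co-culture
#' @param seed integer seed
#' @param replicates wells per condition (default 3)
#' @param n_events events per flow sample
#' @param readouts compute flow readouts (slower) or plate only?
#' @return list with `plate` (an [adcc_plate()]), `readouts` (named list of
#'   77-parameter vectors per co-culture condition) and `lysis` (realized
#'   lysis per treated condition)
#' @export
simulate_adcc_plate <- function(config, truth,
                                conditions = c("medium", "target_alone",
                                               "target_triton",
                                               "coculture_unstim",
                                               "coculture_cet"),
                                seed = 1L, replicates = 3,
                                n_events = config$n_events_adcc,
                                readouts = TRUE) {
  required <- c("medium", "target_alone", "target_triton", "coculture_unstim")
  miss <- setdiff(required, conditions)
  if (length(miss)) stop("missing required condition(s): ",
                         paste(miss, collapse = ", "))
  treated <- intersect(conditions,
                       c("coculture_cet", "coculture_cet_ave"))
  od_medium <- 0.10; od_spont <- 0.40; od_max <- 1.00; od_eff <- 0.15
  lys <- stats::setNames(
    vapply(treated, function(cd)
      realized_lysis(truth, config, cd, derive_seed(seed, 3 + match(cd, ADCC_CONDITIONS))),
      numeric(1)), treated)
  mean_od <- function(cond) {
    switch(cond,
      medium = od_medium,
      target_alone = od_medium + od_spont,
      target_triton = od_medium + od_max,
      coculture_unstim = od_medium + od_spont + od_eff,
      od_medium + od_spont + od_eff + lys[[cond]] * (od_max - od_spont))
  }
  wells <- with_seed(derive_seed(seed, 77), do.call(rbind, lapply(
    conditions, function(cd) data.frame(
      condition = cd, replicate = seq_len(replicates),
      absorbance = pmax(0, rnorm(replicates, mean_od(cd), 0.01)),
      stringsAsFactors = FALSE))))
  plate <- adcc_plate(wells)
  ro <- NULL
  if (readouts) {
    ro <- lapply(stats::setNames(nm = c("coculture_unstim", treated)),
                 function(cd) {
      s <- simulate_adcc_sample(config, truth, cd,
                                seed = derive_seed(seed, 10 + match(cd, ADCC_CONDITIONS)),
                                n_events = n_events)
      adcc_readout(s$frame)
    })
  }
  list(plate = plate, readouts = ro, lysis = lys, truth = truth)
}
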