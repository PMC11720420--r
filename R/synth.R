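# Seeded synthetic flow-data generator.
#
# Emulates the statistical structure of the genotyping staining: PBMC-like
# populations with log-normal marker intensities, genotype-conditional binding
# of the MEM154 and LNK16 anti-CD16 clones on NK cells, donor-level staining
# brightness shared between the two CD16 channels, doublets and debris.

#' Configuration of the synthetic flow-data generator
#'
#' All locations are means of natural-log intensities; events are generated as
#' exp(Normal) per population and channel. The MEM154 location increases with
#' V-allele dosage (binding is nearly abolished on FF receptors) while LNK16
#' stains FF slightly more intensely; both orderings are what the genotype
#' classifier exploits. A donor-level brightness offset applied to both CD16
#' channels emulates staining/instrument variability that raw MFIs inherit but
#' clone ratios cancel.
#'
#' @param seed default integer seed used when operations are not given one
#' @param n_events_per_sample events per simulated sample (default 1e5,
#'   matching a typical 1e5-PBMC staining)
#' @param population_fractions named fractions for T, monocyte, NK_bright,
#'   NK_dim and other events; must sum to 1
#' @param nk_dim_cd16pos_frac fraction of CD56dim NK events that express CD16
#' @param mem154_location named log-intensity means of MEM154 on CD16+ NK
#'   events per genotype (must order VV > VF > FF at multiplier 1)
#' @param lnk16_location named log-intensity means of LNK16 per genotype
#'   (FF stains at least as strongly as VF/VV)
#' @param background_location log-intensity mean of unstained/negative events
#' @param donor_sd between-donor SD of each clone-specific location
#' @param brightness_sd between-donor SD of the shared CD16 staining
#'   brightness offset (applied to both clone channels)
#' @param event_sd within-donor (event-level) log-intensity SD
#' @param separation_multiplier nonnegative scalar scaling genotype-mean
#'   differences around their common centre; 0 makes genotypes identical
#' @param doublet_fraction fraction of events that are simulated doublets
#' @param debris_fraction fraction of low-scatter debris events
#' @param cohort_effects named list of healthy-vs-mCRC effect sizes used by the
#'   ADCC generator: `adcc_reduction` (relative loss of antibody-induced
#'   lysis), `cd16_downreg_attenuation` (relative loss of treatment-induced
#'   CD16 downregulation), `activation_induction_reduction` (relative loss of
#'   CD137/CD107a induction), `mono_pdl1_induction_reduction` (relative loss
#'   of monocyte PDL1 induction), `pd1_nk_elevation` (additive increase of the
#'   PD1+ NK fraction)
#' @param n_events_adcc events per simulated ADCC co-culture sample
#' @return an object of class `fcgr_sim_config`
#' @details Default effect sizes are chosen so that, at the study arm sizes
#'   (10 healthy vs 35 patients), downstream rank tests on the affected
#'   parameters are significant at alpha = 0.05 with high probability.
#' @examples
#' cfg <- fcgr_sim_config(n_events_per_sample = 5000)
#' d <- simulate_donor(cfg, "VV", donor_seed = 7)
#' d$frame
#' @export
fcgr_sim_config <- function(seed = 1L,
                            n_events_per_sample = 1e5,
                            population_fractions = c(T = 0.45, monocyte = 0.15,
                                                     NK_bright = 0.01,
                                                     NK_dim = 0.09,
                                                     other = 0.30),
                            nk_dim_cd16pos_frac = 0.90,
                            mem154_location = c(FF = 1.8, VF = 4.0, VV = 5.0),
                            lnk16_location = c(FF = 4.8, VF = 4.4, VV = 4.4),
                            background_location = 1.5,
                            donor_sd = 0.15,
                            brightness_sd = 2.2,
                            event_sd = 0.50,
                            separation_multiplier = 1,
                            doublet_fraction = 0.02,
                            debris_fraction = 0.02,
                            cohort_effects = list(
                              adcc_reduction = 0.4,
                              cd16_downreg_attenuation = 0.5,
                              activation_induction_reduction = 0.5,
                              mono_pdl1_induction_reduction = 0.5,
                              pd1_nk_elevation = 0.10),
                            n_events_adcc = 2e4) {
  stopifnot(n_events_per_sample > 0,
            abs(sum(population_fractions) - 1) < 1e-9,
            all(population_fractions >= 0),
            donor_sd >= 0, brightness_sd >= 0, event_sd >= 0,
            separation_multiplier >= 0,
            doublet_fraction >= 0, debris_fraction >= 0,
            doublet_fraction + debris_fraction < 1)
  stopifnot(setequal(names(population_fractions),
                     c("T", "monocyte", "NK_bright", "NK_dim", "other")),
            setequal(names(mem154_location), GENOTYPES),
            setequal(names(lnk16_location), GENOTYPES))
  structure(list(seed = as.integer(seed),
                 n_events_per_sample = n_events_per_sample,
                 population_fractions = population_fractions,
                 nk_dim_cd16pos_frac = nk_dim_cd16pos_frac,
                 mem154_location = mem154_location,
                 lnk16_location = lnk16_location,
                 background_location = background_location,
                 donor_sd = donor_sd,
                 brightness_sd = brightness_sd,
                 event_sd = event_sd,
                 separation_multiplier = separation_multiplier,
                 doublet_fraction = doublet_fraction,
                 debris_fraction = debris_fraction,
                 cohort_effects = cohort_effects,
                 n_events_adcc = n_events_adcc),
            class = "fcgr_sim_config")
}

#' @export
print.fcgr_sim_config <- function(x, ...) {
  cat("<fcgr_sim_config>\n")
  cat("  events/sample:", format(x$n_events_per_sample, big.mark = ","),
      " separation x", x$separation_multiplier, "\n")
  cat("  MEM154 locations:",
      paste(sprintf("%s=%.2f", names(x$mem154_location), x$mem154_location),
            collapse = " "), "\n")
  cat("  LNK16 locations: ",
      paste(sprintf("%s=%.2f", names(x$lnk16_location), x$lnk16_location),
            collapse = " "), "\n")
  invisible(x)
}

# Genotype locations after applying the separation multiplier: means are
# contracted towards (or expanded around) their across-genotype centre.
scaled_locations <- function(loc, multiplier) {
  centre <- mean(loc)
  centre + multiplier * (loc - centre)
}

# Donor-level latent draws, deterministic given (config, genotype, cohort,
# donor_seed). Returned locations already include donor noise and brightness.
donor_latents <- function(config, genotype, cohort, donor_seed) {
  with_seed(donor_seed, {
    mem <- scaled_locations(config$mem154_location,
                            config$separation_multiplier)[[genotype]]
    lnk <- scaled_locations(config$lnk16_location,
                            config$separation_multiplier)[[genotype]]
    brightness <- rnorm(1, 0, config$brightness_sd)
    mem_d <- rnorm(1, 0, config$donor_sd)
    lnk_d <- rnorm(1, 0, config$donor_sd)
    # latent cytotoxic capacity used by the ADCC generator; deterministic per
    # donor, FF donors draw from a lower band (low-affinity receptor)
    cap0 <- runif(1, 0.45, 0.95)
    capacity <- if (genotype == "FF") 0.40 * cap0 else cap0
    if (cohort == "mCRC")
      capacity <- capacity * (1 - config$cohort_effects$adcc_reduction)
    list(mem_loc = mem + brightness + mem_d,
         lnk_loc = lnk + brightness + lnk_d,
         brightness = brightness,
         latent_lysis_capacity = capacity)
  })
}

GENO_CHANNELS <- c("FSC-A", "FSC-H", "SSC-A", "CD3", "CD14", "CD56",
                   "CD16-MEM154", "CD16-LNK16")

#' Simulate one stained genotyping sample for a donor
#'
#' Generates an event frame with the genotyping panel channels (scatter, CD3,
#' CD14, CD56 and the two anti-CD16 clones). NK events carry genotype-dependent
#' MEM154/LNK16 log-normal intensities; a configurable fraction of doublets
#' (FSC-A summed from two singlets, FSC-H near singlet level) and low-scatter
#' debris is mixed in. Identical arguments yield bit-identical output.
#'
#' @param config an [fcgr_sim_config()]
#' @param genotype one of `"FF"`, `"VF"`, `"VV"`
#' @param cohort `"healthy"` or `"mCRC"`
#' @param donor_seed integer seed identifying the donor
#' @param timepoint sample time point label (C1, C2, C5, C6)
#' @param sample_seed optional extra seed for the event-level draw, so repeated
#'   samplings of the same donor (time points) differ while donor-level biology
#'   stays fixed; defaults to `donor_seed`
#' @param n_events number of events; defaults to the config value
#' @return list with `frame` (an [event_frame()]), `meta` (donor metadata row)
#'   and `truth` (per-event population labels plus donor latents)
#' @export
simulate_donor <- function(config, genotype, cohort = "healthy",
                           donor_seed = config$seed, timepoint = "C1",
                           sample_seed = donor_seed,
                           n_events = config$n_events_per_sample) {
  stopifnot(inherits(config, "fcgr_sim_config"))
  genotype <- match.arg(genotype, GENOTYPES)
  cohort <- match.arg(cohort, c("healthy", "mCRC"))
  if (n_events <= 0) stop("non-positive event count")
  lat <- donor_latents(config, genotype, cohort, donor_seed)

  with_seed(sample_seed, {
    n <- as.integer(n_events)
    n_debris <- round(n * config$debris_fraction)
    n_doublet <- round(n * config$doublet_fraction)
    n_single <- n - n_debris - n_doublet

    pops <- sample(names(config$population_fractions), n_single,
                   replace = TRUE, prob = config$population_fractions)
    es <- config$event_sd
    bg <- config$background_location

    logint <- function(mu) rnorm(n_single, mu, es)
    # lineage markers: positive ~ exp(N(6, sd)), negative ~ exp(N(bg, sd))
    cd3 <- logint(bg); cd3[pops == "T"] <- rnorm(sum(pops == "T"), 6, es)
    cd14 <- logint(bg)
    cd14[pops == "monocyte"] <- rnorm(sum(pops == "monocyte"), 6, es)
    cd56 <- logint(bg)
    cd56[pops == "NK_dim"] <- rnorm(sum(pops == "NK_dim"), 5.5, es)
    cd56[pops == "NK_bright"] <- rnorm(sum(pops == "NK_bright"), 8.0, es)

    # CD16 clones: genotype-conditional on CD16+ CD56dim NK events only
    is_dim <- pops == "NK_dim"
    cd16pos <- is_dim & (runif(n_single) < config$nk_dim_cd16pos_frac)
    mem <- logint(bg + lat$brightness)
    lnk <- logint(bg + lat$brightness)
    mem[cd16pos] <- rnorm(sum(cd16pos), lat$mem_loc, es)
    lnk[cd16pos] <- rnorm(sum(cd16pos), lat$lnk_loc, es)

    fsc <- rnorm(n_single, 5.0e4, 6e3)
    fsc[pops == "monocyte"] <- rnorm(sum(pops == "monocyte"), 8.0e4, 8e3)
    fsch <- fsc * 0.95 + rnorm(n_single, 0, 1500)
    ssc <- rnorm(n_single, 3.0e4, 5e3)
    ssc[pops == "monocyte"] <- rnorm(sum(pops == "monocyte"), 6.0e4, 7e3)

    single <- cbind(fsc, fsch, ssc,
                    exp(cd3), exp(cd14), exp(cd56), exp(mem), exp(lnk))

    # doublets: sum FSC-A (and fluorescence) of two singlets, FSC-H stays low
    if (n_doublet > 0) {
      i <- sample.int(n_single, n_doublet, replace = TRUE)
      j <- sample.int(n_single, n_doublet, replace = TRUE)
      doub <- single[i, , drop = FALSE] + single[j, , drop = FALSE]
      doub[, 2] <- pmax(single[i, 2], single[j, 2]) * 1.02
    } else doub <- single[0, , drop = FALSE]

    if (n_debris > 0) {
      deb <- cbind(rnorm(n_debris, 6e3, 2e3), rnorm(n_debris, 5.5e3, 2e3),
                   rnorm(n_debris, 4e3, 2e3),
                   exp(rnorm(n_debris, bg, es)), exp(rnorm(n_debris, bg, es)),
                   exp(rnorm(n_debris, bg, es)), exp(rnorm(n_debris, bg, es)),
                   exp(rnorm(n_debris, bg, es)))
    } else deb <- single[0, , drop = FALSE]

    events <- rbind(single, doub, deb)
    labels <- c(pops, rep("doublet", n_doublet), rep("debris", n_debris))
    cd16pos_lab <- c(cd16pos, rep(FALSE, n_doublet + n_debris))
    ord <- sample.int(nrow(events)) # shuffle so truth order carries no signal
    events <- events[ord, , drop = FALSE]
    labels <- labels[ord]
    cd16pos_lab <- cd16pos_lab[ord]

    sample_id <- sprintf("D%06d_%s", donor_seed %% 1000000L, timepoint)
    frame <- event_frame(events, GENO_CHANNELS, sample_id)
    meta <- data.frame(sample_id = sample_id,
                       donor_id = sprintf("D%06d", donor_seed %% 1000000L),
                       genotype = genotype, cohort = cohort,
                       timepoint = timepoint, stringsAsFactors = FALSE)
    list(frame = frame, meta = meta,
         truth = list(population = labels, cd16pos = cd16pos_lab,
                      latents = lat))
  })
}

#' Simulate a donor cohort
#'
#' Genotype counts follow the largest-remainder allocation of the requested
#' proportions; each donor gets a unique ID and one sample per time point.
#'
#' @param config an [fcgr_sim_config()]
#' @param n_donors number of donors (>= 3, at least one per genotype)
#' @param genotype_proportions FF/VF/VV weights, e.g. `c(FF=4, VF=4, VV=2)`
#' @param cohort `"healthy"` or `"mCRC"` for all donors
#' @param timepoints character vector of time point labels per donor
#' @param seed master seed; donor seeds are derived deterministically
#' @param n_events events per sample (defaults to the config value)
#' @return list with `samples` (list of simulate_donor results, one per
#'   donor x timepoint) and `truth` (data.frame of donor ground truth)
#' @export
simulate_cohort <- function(config, n_donors,
                            genotype_proportions = c(FF = 4, VF = 4, VV = 2),
                            cohort = "healthy", timepoints = "C1",
                            seed = config$seed,
                            n_events = config$n_events_per_sample) {
  stopifnot(n_donors >= 3)
  counts <- largest_remainder(n_donors, genotype_proportions)
  if (any(counts < 1))
    stop("proportions cannot yield at least one donor per genotype at n = ",
         n_donors)
  genotypes <- rep(names(counts), counts)
  samples <- list()
  truth <- list()
  for (d in seq_len(n_donors)) {
    dseed <- derive_seed(seed, d)
    lat <- donor_latents(config, genotypes[d], cohort, dseed)
    truth[[d]] <- data.frame(
      donor_id = sprintf("D%06d", dseed %% 1000000L),
      genotype = genotypes[d], cohort = cohort,
      latent_lysis_capacity = lat$latent_lysis_capacity,
      stringsAsFactors = FALSE)
    for (ti in seq_along(timepoints)) {
      s <- simulate_donor(config, genotypes[d], cohort,
                          donor_seed = dseed, timepoint = timepoints[ti],
                          sample_seed = derive_seed(dseed, 1000 + ti),
                          n_events = n_events)
      samples[[length(samples) + 1L]] <- s
    }
  }
  truth <- do.call(rbind, truth)
  if (anyDuplicated(truth$donor_id))
    stop("donor seed collision produced duplicate donor IDs; change seed")
  list(samples = samples, truth = truth, counts = counts)
}
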