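# Readers/writers and run configuration.

#' Read event data from FCS or CSV
#'
#' CSV files need a header row of channel names, one row per event. An
#' optional channel map renames instrument labels (e.g. fluorophores) to
#' marker names; every entry whose source channel is present is applied.
#'
#' @param path file path (`.fcs`, `.csv` or `.tsv`)
#' @param channel_map optional named character vector `c(source = target)`
#' @param sample_id sample identifier; defaults to the file name
#' @return an [event_frame()]
#' @export
read_events <- function(path, channel_map = NULL,
                        sample_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  ef <- switch(ext,
    fcs = read_fcs(path),
    csv = ,
    tsv = {
      sep <- if (ext == "tsv") "\t" else ","
      first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
      if (anyDuplicated(trimws(gsub('"', "", first))))
        stop("duplicate channel names in header")
      d <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE)
      event_frame(as.matrix(d), colnames(d), sample_id)
    },
    stop("unknown format: .", ext))
  ef$sample_id <- sample_id
  if (!is.null(channel_map)) {
    hit <- names(channel_map) %in% ef$channels
    ch <- ef$channels
    ch[match(names(channel_map)[hit], ch)] <- unname(channel_map[hit])
    if (anyDuplicated(ch)) stop("channel map creates duplicate channels")
    ef$channels <- ch
    colnames(ef$events) <- ch
  }
  ef
}

#' Write an event frame to CSV or FCS
#'
#' @param frame an [event_frame()]
#' @param path output path; format chosen by extension
#' @return `path`, invisibly
#' @export
write_events <- function(frame, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    fcs = write_fcs(frame, path),
    csv = utils::write.csv(as.data.frame(frame$events), path,
                           row.names = FALSE),
    stop("unknown format: .", ext))
  invisible(path)
}

RUN_CONFIG_KEYS <- c("seed", "n_events_per_sample", "separation_multiplier",
                     "n_donors_train", "n_donors_test",
                     "genotype_proportions_train", "genotype_proportions_test",
                     "gating_thresholds", "feature_manifest_version",
                     "num_trees", "top_k", "vif_cutoff", "decay",
                     "conditional_importance", "k_folds", "reps", "sizes",
                     "schemes", "output_dir")

#' Read and validate a run configuration (YAML)
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path
#' @return named list of validated settings with class `fcgr_run_config`
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$seed) && (cfg$seed != round(cfg$seed)))
    stop("seed must be an integer")
  structure(cfg, class = "fcgr_run_config")
}

#' Serialise a fitted model to versioned JSON
#'
#' Stores selected features, standardisation statistics, LDA parameters and
#' logistic coefficients — everything [predict.fcgr_model()] needs — plus the
#' manifest version and training fingerprint, in an auditable text format.
#'
#' @param model an `fcgr_model`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    format = "fcgr_model", format_version = 1L,
    manifest_version = model$manifest_version,
    selected_features = model$selected_features,
    standardise = model$standardise,
    lda = list(grand_mean = as.list(model$lda$grand_mean),
               scaling = apply(model$lda$scaling, 2, as.numeric,
                               simplify = FALSE),
               class_means = apply(model$lda$class_means, 1, as.numeric,
                                   simplify = FALSE)),
    lr = list(coef = apply(model$lr$coef, 1, as.numeric, simplify = FALSE),
              coef_names = colnames(model$lr$coef),
              levels = model$lr$levels),
    vif = as.list(model$vif),
    classes = model$classes, seed = model$seed, n_train = model$n_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model serialised by [write_model_json()]
#'
#' @param path JSON path
#' @return an `fcgr_model` usable with [predict.fcgr_model()]
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fcgr_model"))
    stop("not a serialised fcgr_model")
  sel <- obj$selected_features
  scaling <- do.call(cbind, obj$lda$scaling)
  rownames(scaling) <- sel
  colnames(scaling) <- paste0("LD", seq_len(ncol(scaling)))
  cmeans <- do.call(rbind, obj$lda$class_means)
  colnames(cmeans) <- sel
  co <- do.call(rbind, obj$lr$coef)
  colnames(co) <- obj$lr$coef_names
  structure(list(
    selected_features = sel,
    vif = unlist(obj$vif),
    standardise = list(center = unlist(obj$standardise$center),
                       scale = unlist(obj$standardise$scale)),
    lda = list(grand_mean = unlist(obj$lda$grand_mean), scaling = scaling,
               class_means = cmeans),
    lr = list(coef = co, levels = obj$lr$levels),
    classes = obj$classes, seed = obj$seed, n_train = obj$n_train,
    manifest_version = obj$manifest_version,
    ranking = NULL, class_counts = NULL),
    class = "fcgr_model")
}
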