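#' Event-level flow cytometry frame
#'
#' Container for one acquired sample: a numeric matrix with one row per event
#' and one named column per channel (scatter and fluorescence intensities),
#' plus a sample identifier. This is the unit all gating operates on.
#'
#' @param events numeric matrix, one row per event
#' @param channels character vector of unique channel names; defaults to the
#'   column names of `events`
#' @param sample_id character scalar identifying the sample
#' @return an object of class `event_frame`
#' @examples
#' m <- cbind(`FSC-A` = rnorm(10, 5e4, 5e3), `FSC-H` = rnorm(10, 4.8e4, 5e3))
#' ef <- event_frame(m, sample_id = "demo")
#' n_events(ef)
#' @export
event_frame <- function(events, channels = colnames(events), sample_id = "sample") {
  events <- as.matrix(events)
  if (is.null(channels)) stop("channel names are required")
  channels <- as.character(channels)
  if (anyDuplicated(channels)) stop("duplicate channel names")
  if (ncol(events) != length(channels))
    stop("channel count does not match event matrix")
  colnames(events) <- channels
  structure(list(events = events, channels = channels,
                 sample_id = as.character(sample_id)),
            class = "event_frame")
}

#' @export
print.event_frame <- function(x, ...) {
  cat("<event_frame> sample", x$sample_id, "-", nrow(x$events), "events,",
      length(x$channels), "channels\n")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of events in a frame
#' @param frame an [event_frame()]
#' @return integer event count
#' @export
n_events <- function(frame) nrow(frame$events)

#' Extract one channel as a numeric vector
#' @param frame an [event_frame()]
#' @param channel channel name
#' @param mask optional logical event mask
#' @return numeric vector of intensities
#' @export
channel_values <- function(frame, channel, mask = NULL) {
  if (!channel %in% frame$channels)
    stop("channel not present: ", channel)
  v <- frame$events[, channel]
  if (!is.null(mask)) v <- v[mask]
  v
}

#' Population mask over an event frame
#'
#' Boolean membership of each event in a gated population, together with the
#' gate name, its parent gate and the frequency-of-parent in percent.
#'
#' @param member logical vector, one entry per event of the parent frame
#' @param name gate name
#' @param parent name of the parent gate (`"root"` for the full frame)
#' @param parent_member logical membership of the parent population; defaults
#'   to all events
#' @return an object of class `population_mask`
#' @export
population_mask <- function(member, name, parent = "root",
                            parent_member = NULL) {
  member <- as.logical(member)
  member[is.na(member)] <- FALSE
  if (is.null(parent_member)) parent_member <- rep(TRUE, length(member))
  if (any(member & !parent_member))
    stop("child mask exceeds its parent")
  np <- sum(parent_member)
  structure(list(name = name, parent = parent, member = member,
                 count = sum(member),
                 frequency = if (np > 0) 100 * sum(member) / np else NA_real_),
            class = "population_mask")
}

#' @export
print.population_mask <- function(x, ...) {
  cat(sprintf("<population_mask> %s (parent %s): %d events, %.2f%% of parent\n",
              x$name, x$parent, x$count,
              if (is.na(x$frequency)) NaN else x$frequency))
  invisible(x)
}
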