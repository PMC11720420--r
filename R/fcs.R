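# Minimal FCS 3.0/3.1 list-mode I/O.
#
# Supports what cytometer exports of this kind actually contain: one dataset,
# $MODE L, $DATATYPE F (float32) or D (double), little- or big-endian
# $BYTEORD, per-parameter names in $PnN. Writing emits FCS 3.1 float32.

read_fcs_text <- function(raw, begin, end) {
  txt <- rawToChar(raw[(begin + 1):(end + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- trimws(parts[seq(1, length(parts), 2)])
  vals <- parts[seq(2, length(parts), 2)]
  stats::setNames(as.list(vals), toupper(keys))
}

#' Read an FCS 3.0/3.1 file
#'
#' @param path file path
#' @return an [event_frame()]; keyword segment attached as attribute
#'   `"keywords"`
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version)
  off <- function(i, j) as.numeric(trimws(rawToChar(raw[i:j])))
  tb <- off(11, 18); te <- off(19, 26)
  db <- off(27, 34); de <- off(35, 42)
  kw <- read_fcs_text(raw, tb, te)
  if (db == 0) db <- as.numeric(kw[["$BEGINDATA"]])
  if (de == 0) de <- as.numeric(kw[["$ENDDATA"]])
  par <- as.integer(kw[["$PAR"]])
  tot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  mode <- kw[["$MODE"]] %||% "L"
  if (!identical(mode, "L")) stop("only list-mode ($MODE L) supported")
  byteord <- kw[["$BYTEORD"]]
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  size <- switch(dtype, F = 4L, D = 8L,
                 stop("unsupported $DATATYPE: ", dtype))
  con <- rawConnection(raw[(db + 1):(de + 1)])
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = par * tot, size = size,
                  endian = endian)
  m <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  channels <- vapply(seq_len(par), function(i)
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i), character(1))
  if (anyDuplicated(channels)) stop("duplicate channel names in FCS file")
  ef <- event_frame(m, channels,
                    sample_id = kw[["$FIL"]] %||% basename(path))
  attr(ef, "keywords") <- kw
  ef
}

#' Write an event frame as FCS 3.1 (float32, little-endian)
#'
#' @param frame an [event_frame()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fcs <- function(frame, path) {
  m <- frame$events
  par <- ncol(m); tot <- nrow(m)
  delim <- "/"
  kv <- c("$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
          "$PAR" = as.character(par), "$TOT" = as.character(tot),
          "$NEXTDATA" = "0", "$FIL" = frame$sample_id)
  for (i in seq_len(par)) {
    kv[sprintf("$P%dN", i)] <- frame$channels[i]
    kv[sprintf("$P%dB", i)] <- "32"
    kv[sprintf("$P%dE", i)] <- "0,0"
    kv[sprintf("$P%dR", i)] <- format(ceiling(max(m[, i], 1) + 1),
                                      scientific = FALSE)
  }
  # two-pass: placeholder data offsets of fixed width, then fill in
  build_text <- function(bd, ed) {
    kv2 <- c(kv, "$BEGINDATA" = sprintf("%10d", bd),
             "$ENDDATA" = sprintf("%10d", ed))
    paste0(delim, paste0(names(kv2), delim, kv2, delim, collapse = ""))
  }
  header_len <- 58L
  txt <- build_text(0, 0)
  tb <- header_len
  te <- tb + nchar(txt, type = "bytes") - 1L
  bd <- te + 1L
  ed <- bd + 4L * par * tot - 1L
  txt <- build_text(bd, ed)
  stopifnot(nchar(txt, type = "bytes") == te - tb + 1L)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    tb, te, bd, ed, 0L, 0L)
  stopifnot(nchar(header) == header_len)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}
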