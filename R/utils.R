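# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a counter
#'
#' Deterministic splitting of one master seed into independent streams,
#' kept strictly below 2^31 so the result is a valid R integer seed.
#' @param master integer master seed
#' @param counter non-negative integer stream index
#' @return integer seed
#' @export
derive_seed <- function(master, counter) {
  m <- 2147483629 # largest prime < 2^31
  s <- (as.numeric(master) %% m)
  # two rounds of a multiplicative hash; doubles stay exact below 2^53
  s <- (s * 48271 + as.numeric(counter) + 1) %% m
  s <- (s * 69621 + 7) %% m
  as.integer(s)
}

#' Largest-remainder allocation of n units across classes
#'
#' @param n total count
#' @param proportions non-negative weights (normalised internally)
#' @return integer vector summing to `n`, named like `proportions`
#' @export
largest_remainder <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0), sum(proportions) > 0)
  p <- proportions / sum(proportions)
  raw <- n * p
  base <- floor(raw)
  rem <- raw - base
  k <- n - sum(base)
  if (k > 0) {
    # ties broken by class order for determinism
    idx <- order(-rem, seq_along(rem))[seq_len(k)]
    base[idx] <- base[idx] + 1
  }
  out <- as.integer(base)
  names(out) <- names(proportions)
  out
}

#' Genotype levels in canonical order
#' @noRd
GENOTYPES <- c("FF", "VF", "VV")

as_genotype <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), GENOTYPES)
  if (length(bad))
    stop("unknown genotype label(s): ", paste(bad, collapse = ", "))
  factor(y, levels = GENOTYPES)
}

#' Short stable hash of an R object (for config fingerprints)
#' @noRd
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}
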