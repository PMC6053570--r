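## internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' Pipeline stages draw randomness independently: each stage's seed is a
#' deterministic hash of the master seed and the stage name, so a stage can be
#' re-run in isolation and reproduce its in-pipeline behaviour.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- as.integer(master) %% 2147483647L
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647L
  }
  as.integer(h)
}

## checked conversion of a metadata column against a controlled vocabulary
check_vocab <- function(x, allowed, what) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad)) {
    stopf("invalid %s value(s): %s (allowed: %s)", what,
          paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  }
  x
}
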