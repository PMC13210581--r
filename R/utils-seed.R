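#' Derive a deterministic sub-seed from a master seed
#'
#' All stochastic stages draw their own seed from one master seed plus a
#' stage label, so stages are reproducible in isolation and independent of
#' the order in which they run.  The hash is a plain 31-bit polynomial
#' rolling hash of the label string; it stays below `.Machine$integer.max`
#' so the result is always a valid `set.seed()` input.
#'
#' @param master integer master seed.
#' @param ... label components (stage name, set index, ...), coerced to
#'   character and joined with "/".
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  tag <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  bytes <- utf8ToInt(tag)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

## round half away from zero; round() in R rounds half to even which would
## make the 0-1000 suitability scaling depend on the platform's printing
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
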