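

# Deterministic per-gene substream seed. Counter-based: the seed for gene i
# depends only on (master seed, i, salt), so enlarging n_genes never
# reshuffles earlier genes. Constants are arbitrary large primes; the
# modulus keeps the result a valid 32-bit R seed.
substream_seed <- function(seed, index, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- (as.double(seed) %% 2147483629) * 1000003 +
    as.double(index) * 7919 + as.double(salt) * 104729
  as.integer(h %% 2147483629)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper around [stats::p.adjust()] that tolerates missing values
#' (excluded genes keep `NA` and do not enter the correction).
#'
#' @param p numeric vector of raw p-values, possibly with `NA`s.
#' @return numeric vector of BH-adjusted q-values, same length as `p`.
#' @keywords internal
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

# sign as integer with exact-zero passthrough
sign_int <- function(x) as.integer(sign(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}
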