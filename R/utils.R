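# internal helpers shared across modules

#' Round half away from zero
#'
#' Printed data tables round halves away from zero (0.205 -> 0.21), whereas
#' [base::round()] rounds to even. Used for table-parity comparisons only;
#' analysis functions always return full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# values of the strict lower triangle, i.e. the n(n-1)/2 unordered pairs
lower_pairs <- function(m) m[lower.tri(m)]

# deterministic per-iteration seed derived from one user seed; exact in
# double arithmetic and < 2^31, so iteration i is reproducible regardless
# of how many iterations are requested
derive_seed <- function(seed, i) {
  ((seed %% 2147483647) * 69069 + i * 12345) %% 2147483647
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  expr
}

# polynomial rolling hash of a character vector; used for config provenance
# in run logs, not for security
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
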