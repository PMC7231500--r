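#' Alpha-diversity indices
#'
#' Per-sample diversity descriptors for specimen count vectors:
#' `berger_parker()` is the dominance index, the proportion of the single
#' most abundant taxon; `shannon_index()` is \eqn{H = -\sum p_i \ln p_i} in
#' nats; `pielou_evenness()` is \eqn{J = H / \ln s} with \eqn{s} the number
#' of taxa with positive count (base-invariant, requires \eqn{s \ge 2}).
#'
#' @param counts numeric vector of non-negative counts for one sample.
#' @return a single number.
#' @examples
#' berger_parker(c(230, 18, 16))   # dominance
#' shannon_index(c(2, 1, 1))       # 1.0397 nats
#' pielou_evenness(c(2, 1, 1))     # 0.9464
#' @name alpha_indices
NULL

check_counts <- function(counts) {
  if (length(counts) == 0L || anyNA(counts) || any(counts < 0) ||
      sum(counts) <= 0)
    stop("counts must be non-negative with positive total")
  counts
}

#' @rdname alpha_indices
#' @export
berger_parker <- function(counts) {
  check_counts(counts)
  max(counts) / sum(counts)
}

#' @rdname alpha_indices
#' @export
shannon_index <- function(counts) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' @rdname alpha_indices
#' @export
pielou_evenness <- function(counts) {
  check_counts(counts)
  s <- sum(counts > 0)
  if (s < 2L) stop("evenness undefined for a single-taxon sample (log(1) = 0)")
  shannon_index(counts) / log(s)
}

#' Alpha-diversity summary table
#'
#' Computes all per-sample indices on whatever table is passed; to follow a
#' top-n counting protocol, reduce first with [top_n_reduce()]. Evenness is
#' `NA` for single-taxon samples.
#'
#' @param table an `abundance_table`.
#' @return a `data.frame` with columns `sample_id`, `n_specimens`, `n_taxa`,
#'   `berger_parker`, `shannon_H` (nats), `pielou_J`.
#' @export
alpha_summary <- function(table) {
  stopifnot(is_abundance_table(table))
  rows <- lapply(rownames(table), function(id) {
    x <- table[id, ]
    s <- sum(x > 0)
    data.frame(sample_id = id,
               n_specimens = sum(x),
               n_taxa = s,
               berger_parker = berger_parker(x),
               shannon_H = shannon_index(x),
               pielou_J = if (s >= 2) pielou_evenness(x) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
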