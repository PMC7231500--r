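#' Pooled (gamma) species-abundance vector
#'
#' Pools all taxa with their observed abundances over samples into a single
#' regional abundance vector and its proportional version; the basis of the
#' random-assembly null model.
#'
#' @param table an `abundance_table`.
#' @return a `gamma_pool`: list with `taxon_ids`, `pooled_counts`
#'   (integer), `proportions` (sums to 1).
#' @export
gamma_pool <- function(table) {
  stopifnot(is_abundance_table(table))
  pooled <- colSums(unclass(table))
  structure(list(taxon_ids = colnames(table),
                 pooled_counts = as.integer(pooled),
                 proportions = as.numeric(pooled / sum(pooled))),
            class = "gamma_pool")
}

#' @export
print.gamma_pool <- function(x, ...) {
  cat(sprintf("gamma_pool: %d taxa, %d specimens\n",
              length(x$taxon_ids), sum(x$pooled_counts)))
  invisible(x)
}

#' Simulate one random-assembly dataset from a gamma pool
#'
#' Each synthetic sample is an independent multinomial draw of the stated
#' size with the pool proportions as probability weights (resampling with
#' replacement), emulating random assembly from the regional pool at the
#' observed sampling effort.
#'
#' @param pool a `gamma_pool`.
#' @param sample_sizes integer vector of specimen counts, one per synthetic
#'   sample; names become sample ids.
#' @param seed optional integer seed for reproducibility.
#' @return an `abundance_table` with `length(sample_sizes)` samples. Taxa
#'   never drawn are dropped by validation, as for observed tables.
#' @export
simulate_null_dataset <- function(pool, sample_sizes, seed = NULL) {
  stopifnot(inherits(pool, "gamma_pool"))
  if (any(sample_sizes < 1)) stop("sample sizes must be >= 1")
  with_seed(seed, {
    draws <- matrix(vapply(sample_sizes,
                           function(n) stats::rmultinom(1, n, pool$proportions)[, 1],
                           numeric(length(pool$proportions))),
                    nrow = length(pool$proportions))
    m <- t(draws)
    colnames(m) <- pool$taxon_ids
    rownames(m) <- names(sample_sizes) %||% paste0("null_", seq_along(sample_sizes))
    abundance_table(m)
  })
}

#' Gamma-pool null distribution of mean dissimilarity
#'
#' Tests how much of the observed beta diversity could arise from random
#' assembly alone: the observed samples are pooled into a gamma abundance
#' vector ([gamma_pool()]); each iteration resamples a synthetic dataset at
#' the observed sample sizes ([simulate_null_dataset()]) and records its
#' mean pairwise proportional dissimilarity; the observed mean is compared
#' with the resulting null distribution. A single seed drives a splittable
#' stream, so iteration i is reproducible independent of the iteration
#' count.
#'
#' @param table an `abundance_table` with at least two samples.
#' @param iterations number of resampled datasets (default 1000).
#' @param seed integer seed.
#' @param alternative `"greater"` (observed exceeds null, default) or
#'   `"two.sided"`.
#' @return a `null_model_result`: list with `iterations`,
#'   `per_iteration_mean_ppd`, `null_mean`, `null_sd`, `null_se` (sd of the
#'   per-iteration means / sqrt(iterations)), `observed_mean`,
#'   `empirical_p` (add-one corrected, (b+1)/(m+1)), `ses` (standardized
#'   effect size), `seed`.
#' @export
null_distribution <- function(table, iterations = 1000, seed = NULL,
                              alternative = c("greater", "two.sided")) {
  stopifnot(is_abundance_table(table))
  alternative <- match.arg(alternative)
  if (iterations < 1) stop("iterations must be >= 1")
  if (nrow(table) < 2L) stop("need at least two samples")
  pool <- gamma_pool(table)
  sizes <- rowSums(unclass(table))
  observed <- mean_dissimilarity(dissimilarity_matrix(table), "all")$mean
  seed <- seed %||% sample.int(2^31 - 2, 1)
  means <- vapply(seq_len(iterations), function(i) {
    sim <- simulate_null_dataset(pool, sizes, seed = derive_seed(seed, i))
    mean_ppd(sim)
  }, numeric(1))
  nsd <- if (iterations > 1) stats::sd(means) else 0
  b <- sum(means >= observed)
  p <- (b + 1) / (iterations + 1)
  if (alternative == "two.sided") {
    b2 <- sum(means <= observed)
    p <- min(1, 2 * min(p, (b2 + 1) / (iterations + 1)))
  }
  structure(list(iterations = iterations,
                 per_iteration_mean_ppd = means,
                 null_mean = mean(means),
                 null_sd = nsd,
                 null_se = nsd / sqrt(iterations),
                 observed_mean = observed,
                 empirical_p = p,
                 ses = if (nsd > 0) (observed - mean(means)) / nsd else NA_real_,
                 alternative = alternative,
                 seed = seed),
            class = "null_model_result")
}

# fast mean pairwise PPD of a table (scope = all), avoiding matrix objects
# in the null-model inner loop
mean_ppd <- function(table) {
  p <- unclass(table) / rowSums(unclass(table))
  n <- nrow(p)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    pi <- p[i, ]
    for (j in (i + 1L):n) tot <- tot + 1 - sum(pmin(pi, p[j, ]))
  }
  tot / (n * (n - 1) / 2)
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf(paste0(
    "gamma-pool null model (%d iterations, seed %d)\n",
    "  observed mean PPD: %.4f\n",
    "  null mean PPD:     %.4f +/- %.4f (se; sd %.4f)\n",
    "  empirical p (%s): %.4g   SES: %.2f\n"),
    x$iterations, x$seed, x$observed_mean, x$null_mean, x$null_se,
    x$null_sd, x$alternative, x$empirical_p, x$ses))
  invisible(x)
}

#' Serialise a null-model result
#'
#' Writes the per-iteration means as CSV and the summary as JSON.
#'
#' @param result a `null_model_result`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisible `NULL`.
#' @export
write_null_result <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "null_model_result"))
  if (!is.null(csv_path))
    utils::write.csv(data.frame(iteration = seq_len(result$iterations),
                                mean_ppd = result$per_iteration_mean_ppd),
                     csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summary <- result[c("iterations", "null_mean", "null_sd", "null_se",
                        "observed_mean", "empirical_p", "ses", "seed",
                        "alternative")]
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
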