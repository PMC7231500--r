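#' Pairwise proportional dissimilarity (relative Bray-Curtis)
#'
#' The core beta-diversity statistic: with \eqn{x_{ij}} the proportional
#' abundance of taxon \eqn{i} in sample \eqn{j},
#' \deqn{d_{jk} = 1 - \sum_i \min(x_{ij}, x_{ik}).}
#' Counts are normalised to proportions per sample before the sum of
#' minima, which makes the measure invariant to sample size: 0 for
#' identical compositions, 1 for disjoint taxon sets. Equals the
#' Bray-Curtis dissimilarity of the proportion-normalised vectors. Note the
#' measure is a semimetric: the triangle inequality is not guaranteed.
#'
#' @param x,y non-negative abundance (or proportion) vectors aligned on the
#'   same taxon set (absent taxon = 0); both must have positive totals.
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' proportional_dissimilarity(c(4, 0), c(1, 1))  # 0.5
#' @export
proportional_dissimilarity <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must be aligned on the same taxon set")
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0))
    stop("abundances must be non-negative")
  sx <- sum(x); sy <- sum(y)
  if (sx <= 0 || sy <= 0) stop("zero-total abundance vector")
  1 - sum(pmin(x / sx, y / sy))
}

#' Modified Gower dissimilarity
#'
#' Abundances are transformed as \eqn{t(a) = \log_b(a) + 1} for \eqn{a > 0}
#' and \eqn{t(0) = 0}, so that order-of-magnitude changes in abundance are
#' weighted equally; the dissimilarity is the mean absolute difference of
#' the transformed abundances over the taxa present in at least one of the
#' two samples (double zeros excluded). The logarithm base is a convention:
#' the default is base 2 and should be reported alongside results.
#'
#' @param x,y non-negative abundance vectors on the same taxon set.
#' @param log_base logarithm base, > 1 (default 2).
#' @return non-negative dissimilarity.
#' @examples
#' modified_gower_dissimilarity(c(4, 0), c(1, 1))  # 1.5 at base 2
#' @export
modified_gower_dissimilarity <- function(x, y, log_base = 2) {
  if (length(x) != length(y))
    stop("vectors must be aligned on the same taxon set")
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0))
    stop("abundances must be non-negative")
  if (!is.numeric(log_base) || log_base <= 1) stop("log_base must be > 1")
  present <- x > 0 | y > 0
  if (!any(present)) stop("both vectors are all-zero")
  tf <- function(a) ifelse(a > 0, log(a, base = log_base) + 1, 0)
  sum(abs(tf(x[present]) - tf(y[present]))) / sum(present)
}

#' Construct a dissimilarity matrix object
#'
#' @param values square numeric matrix with sample ids as dimnames.
#' @param metric_name label of the metric.
#' @return a `diss_matrix`: a symmetric numeric matrix with zero diagonal
#'   and a `metric` attribute. Convert with `as.dist()` for interoperation
#'   with other multivariate tools.
#' @export
diss_matrix <- function(values, metric_name = "unknown") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("dissimilarity matrix must be square")
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) %||% paste0("sample_", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (max(abs(values - t(values))) > 1e-12) stop("matrix is not symmetric")
  if (max(abs(diag(values))) > 1e-12) stop("diagonal must be zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  attr(values, "metric") <- metric_name
  class(values) <- c("diss_matrix", class(values))
  values
}

#' @export
print.diss_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("diss_matrix (%s): %d samples\n",
              attr(x, "metric") %||% "unknown", nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' All pairwise dissimilarities of an abundance table
#'
#' @param table an `abundance_table` with at least two samples.
#' @param metric `"ppd"` (proportional dissimilarity, default) or
#'   `"modified_gower"`.
#' @param log_base passed to [modified_gower_dissimilarity()].
#' @return a `diss_matrix`.
#' @examples
#' tab <- abundance_table(rbind(s1 = c(a = 4, b = 0), s2 = c(a = 1, b = 1)))
#' dissimilarity_matrix(tab)
#' @export
dissimilarity_matrix <- function(table, metric = c("ppd", "modified_gower"),
                                 log_base = 2) {
  stopifnot(is_abundance_table(table))
  metric <- match.arg(metric)
  n <- nrow(table)
  if (n < 2L) stop("need at least two samples")
  m <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  fun <- switch(metric,
    ppd = proportional_dissimilarity,
    modified_gower = function(x, y) modified_gower_dissimilarity(x, y, log_base))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- tryCatch(fun(table[i, , drop = TRUE], table[j, , drop = TRUE]),
                  error = function(e) stop(sprintf(
                    "pair (%s, %s): %s", rownames(table)[i],
                    rownames(table)[j], conditionMessage(e)), call. = FALSE))
    m[i, j] <- m[j, i] <- d
  }
  diss_matrix(m, metric)
}

#' Mean pairwise dissimilarity with standard error
#'
#' Summarises a dissimilarity matrix the way beta diversity is reported:
#' `scope = "all"` averages the n(n-1)/2 unordered pairs; `"per-sample"`
#' averages the n-1 values of one sample against all others; with a
#' grouping, `"within-group"` averages pairs inside groups (pooled over
#' groups, with a per-group breakdown attached) and `"between-group"`
#' averages cross-group pairs. The standard error is the sd of the
#' contributing pairwise values divided by sqrt(n_pairs); pairwise values
#' are not independent, so it quantifies spread, not sampling error.
#'
#' @param diss a `diss_matrix`.
#' @param scope one of `"all"`, `"per-sample"`, `"within-group"`,
#'   `"between-group"`.
#' @param sample sample id, required for `"per-sample"`.
#' @param grouping named vector mapping sample ids to groups, required for
#'   the group scopes.
#' @return a `mean_dissimilarity`: list with `mean`, `se`, `n_pairs`,
#'   `scope` (and `by_group` for `"within-group"`).
#' @export
mean_dissimilarity <- function(diss, scope = c("all", "per-sample",
                                               "within-group", "between-group"),
                               sample = NULL, grouping = NULL) {
  stopifnot(inherits(diss, "diss_matrix"))
  scope <- match.arg(scope)
  vals <- switch(scope,
    "all" = lower_pairs(unclass(diss)),
    "per-sample" = {
      if (is.null(sample) || !sample %in% rownames(diss))
        stop("per-sample scope needs a valid sample id")
      unclass(diss)[sample, setdiff(rownames(diss), sample)]
    },
    "within-group" = ,
    "between-group" = {
      if (is.null(grouping)) stop("group scope needs a grouping")
      g <- as.character(unlist(grouping)[rownames(diss)])
      if (anyNA(g)) stop("grouping must cover all samples")
      idx <- which(lower.tri(diss), arr.ind = TRUE)
      same <- g[idx[, 1]] == g[idx[, 2]]
      unclass(diss)[idx[same == (scope == "within-group"), , drop = FALSE]]
    })
  if (length(vals) < 1L) stop("no contributing pairs for scope ", scope)
  out <- list(mean = mean(vals),
              se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0,
              n_pairs = length(vals), scope = scope)
  if (scope == "within-group") {
    g <- as.character(unlist(grouping)[rownames(diss)])
    idx <- which(lower.tri(diss), arr.ind = TRUE)
    same <- g[idx[, 1]] == g[idx[, 2]]
    by <- tapply(unclass(diss)[idx[same, , drop = FALSE]], g[idx[same, 1]], mean)
    out$by_group <- by
  }
  class(out) <- "mean_dissimilarity"
  out
}

#' @export
print.mean_dissimilarity <- function(x, ...) {
  cat(sprintf("mean dissimilarity (%s): %.4f +/- %.4f (se), %d pairs\n",
              x$scope, x$mean, x$se, x$n_pairs))
  invisible(x)
}

#' Dissimilarity between pooled group compositions
#'
#' Counts are summed within each group into one pooled composition per
#' group and proportional dissimilarity is computed between the pooled
#' compositions. By default no second top-n reduction is applied to the
#' pooled vectors; pass `reduce_n` to re-reduce after pooling.
#'
#' @param table an `abundance_table`.
#' @param grouping named vector mapping every sample id to a group; at
#'   least two groups.
#' @param reduce_n optional integer: re-apply [top_n_reduce()] to the
#'   pooled compositions.
#' @return a `diss_matrix` over groups.
#' @export
pooled_group_dissimilarity <- function(table, grouping, reduce_n = NULL) {
  stopifnot(is_abundance_table(table))
  grouping <- unlist(grouping)
  missing <- setdiff(rownames(table), names(grouping))
  if (length(missing))
    stop("samples without a group: ", paste(missing, collapse = ", "))
  g <- as.character(grouping[rownames(table)])
  if (length(unique(g)) < 2L) stop("need at least two groups")
  pooled <- abundance_table(rowsum(unclass(table), g, reorder = FALSE))
  if (!is.null(reduce_n)) pooled <- top_n_reduce(pooled, reduce_n)
  dissimilarity_matrix(pooled, "ppd")
}

#' Read / write square dissimilarity matrices as CSV
#'
#' The CSV carries sample ids as the first row and first column. On read,
#' an upper-triangle-only matrix (empty or NA cells below the diagonal) is
#' accepted and symmetrised.
#'
#' @param path file path.
#' @param metric_name metric label to attach on read.
#' @return [read_dissimilarity_matrix()] returns a `diss_matrix`;
#'   [write_dissimilarity_matrix()] returns `path` invisibly.
#' @export
read_dissimilarity_matrix <- function(path, metric_name = "ppd") {
  df <- read_delim_auto(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- names(df)[-1]
  if (!identical(rownames(m), colnames(m)))
    m <- m[, match(rownames(m), colnames(m)), drop = FALSE]
  dg <- diag(m)
  dg[is.na(dg)] <- 0
  diag(m) <- dg
  low <- lower.tri(m)
  m[low][is.na(m[low])] <- t(m)[low][is.na(m[low])]
  up <- upper.tri(m)
  m[up][is.na(m[up])] <- t(m)[up][is.na(m[up])]
  if (anyNA(m)) stop("dissimilarity matrix has unresolvable missing cells")
  diss_matrix(m, metric_name)
}

#' @rdname read_dissimilarity_matrix
#' @param diss a `diss_matrix` to write.
#' @export
write_dissimilarity_matrix <- function(diss, path) {
  stopifnot(inherits(diss, "diss_matrix"))
  df <- data.frame(sample_id = rownames(diss), unclass(diss),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
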