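#' One-factor PERMANOVA on a dissimilarity matrix
#'
#' Partitions the sum of squared dissimilarities between and within groups
#' (Anderson's pseudo-F): with \eqn{N} samples in \eqn{a} groups,
#' \deqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2, \qquad
#'       SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,}
#' \eqn{SS_{between} = SS_{total} - SS_{within}},
#' \eqn{F = (SS_{between}/(a-1)) / (SS_{within}/(N-a))}, and
#' \eqn{R^2 = SS_{between}/SS_{total}}. The p-value is the proportion of
#' group-label permutations (observed assignment included, so p >=
#' 1/(permutations+1)) with \eqn{F^* \ge F}.
#'
#' @param diss a `diss_matrix`.
#' @param grouping named vector mapping every sample id to a group.
#' @param permutations number of random label permutations (default 999).
#' @param seed seed for the permutations.
#' @return a `permanova_result`: list with the sums of squares, degrees of
#'   freedom, `pseudo_F`, `r_squared`, `p_value`, `permutations`, `seed`.
#' @export
permanova <- function(diss, grouping, permutations = 999, seed = NULL) {
  stopifnot(inherits(diss, "diss_matrix"))
  grouping <- unlist(grouping)
  g <- as.character(grouping[rownames(diss)])
  if (anyNA(g)) stop("grouping must cover all samples")
  groups <- unique(g)
  n <- nrow(diss)
  a <- length(groups)
  if (a < 2L) stop("degenerate design: all samples in one group")
  d2 <- unclass(diss)^2
  ss_total <- sum(lower_pairs(d2)) / n
  ss_within_of <- function(labels) {
    s <- 0
    for (grp in unique(labels)) {
      idx <- which(labels == grp)
      if (length(idx) > 1)
        s <- s + sum(lower_pairs(d2[idx, idx, drop = FALSE])) / length(idx)
    }
    s
  }
  ssw <- ss_within_of(g)
  ssb <- ss_total - ssw
  df_b <- a - 1L
  df_w <- n - a
  f_of <- function(ssw) ((ss_total - ssw) / df_b) / (ssw / df_w)
  f_obs <- f_of(ssw)
  seed <- seed %||% sample.int(2^31 - 2, 1)
  with_seed(seed, {
    exceed <- sum(vapply(seq_len(permutations), function(k) {
      f_of(ss_within_of(sample(g))) >= f_obs - 1e-12
    }, logical(1)))
  })
  structure(list(ss_total = ss_total, ss_between = ssb, ss_within = ssw,
                 df_between = df_b, df_within = df_w,
                 pseudo_F = f_obs, r_squared = ssb / ss_total,
                 p_value = (exceed + 1) / (permutations + 1),
                 permutations = permutations, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(paste0(
    "PERMANOVA (one factor, %d permutations)\n",
    "  SS between: %.4f (df %d)   SS within: %.4f (df %d)\n",
    "  pseudo-F: %.3f   R2: %.4f   p: %.4g\n"),
    x$permutations, x$ss_between, x$df_between, x$ss_within, x$df_within,
    x$pseudo_F, x$r_squared, x$p_value))
  invisible(x)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centring of \eqn{-d^2/2} followed by eigendecomposition.
#' Semimetric dissimilarities (such as proportional dissimilarity)
#' generally produce negative eigenvalues; these are retained and reported
#' (not an error), and coordinates are returned for the positive axes only.
#'
#' @param diss a `diss_matrix`.
#' @return an `ordination_result`: list with `coordinates` (positive axes,
#'   scaled by sqrt(eigenvalue)), `eigenvalues` (all, descending),
#'   `negative_eigenvalues` flag, `method = "pcoa"`, plus `axes_neg`
#'   coordinates on the imaginary axes (used for corrected dispersion).
#' @export
pcoa <- function(diss) {
  stopifnot(inherits(diss, "diss_matrix"))
  n <- nrow(diss)
  a <- -0.5 * unclass(diss)^2
  centred <- a - matrix(rowMeans(a), n, n) -
    matrix(colMeans(a), n, n, byrow = TRUE) + mean(a)
  eig <- eigen(centred, symmetric = TRUE)
  values <- eig$values
  tol <- max(abs(values)) * 1e-9
  pos <- which(values > tol)
  neg <- which(values < -tol)
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(values[pos]), length(pos))
  dimnames(coords) <- list(rownames(diss),
                           if (length(pos)) paste0("PCo", seq_along(pos)))
  axes_neg <- eig$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(abs(values[neg])), length(neg))
  rownames(axes_neg) <- rownames(diss)
  structure(list(coordinates = coords, eigenvalues = values,
                 negative_eigenvalues = length(neg) > 0,
                 axes_neg = axes_neg, method = "pcoa"),
            class = "ordination_result")
}

#' Non-metric multidimensional scaling
#'
#' Rank-order-preserving embedding minimising Kruskal stress-1, via
#' monotone (isotonic) regression of the configuration distances on the
#' dissimilarity order, taking the best of several random starts plus a
#' metric (PCoA) start. Stress is on the 0-1 scale. Computed with
#' \pkg{vegan}'s NMDS engine; results are deterministic under a fixed seed,
#' but stress can land in different local optima across implementations, so
#' treat small differences as noise.
#'
#' @param diss a `diss_matrix`.
#' @param k number of dimensions (default 2; requires `n >= k + 1`).
#' @param restarts number of random starts (default 20).
#' @param max_iter,tol iteration cap and convergence tolerance.
#' @param seed integer seed.
#' @return an `ordination_result`: list with `coordinates`, `stress`,
#'   `converged`, `restarts`, `method = "nmds"`.
#' @export
nmds <- function(diss, k = 2, restarts = 20, max_iter = 500, tol = 1e-7,
                 seed = NULL) {
  stopifnot(inherits(diss, "diss_matrix"))
  if (k >= nrow(diss)) stop("k must be smaller than the number of samples")
  with_seed(seed %||% 42, {
    fit <- vegan::metaMDS(stats::as.dist(unclass(diss)), k = k,
                          try = restarts, trymax = restarts,
                          maxit = max_iter, sfgrmin = tol,
                          autotransform = FALSE, wascores = FALSE,
                          trace = 0)
  })
  coords <- fit$points
  rownames(coords) <- rownames(diss)
  structure(list(coordinates = coords, stress = fit$stress,
                 converged = isTRUE(fit$converged > 0), restarts = restarts,
                 method = "nmds"),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  if (x$method == "nmds")
    cat(sprintf("NMDS: %d samples in %d dimensions, stress-1 = %.4f\n",
                nrow(x$coordinates), ncol(x$coordinates), x$stress))
  else
    cat(sprintf("PCoA: %d samples, %d positive axes%s\n",
                nrow(x$coordinates), ncol(x$coordinates),
                if (x$negative_eigenvalues) " (negative eigenvalues present)" else ""))
  invisible(x)
}

#' Multivariate dispersion: distances to group centroids
#'
#' Embeds the samples by principal coordinates and measures each sample's
#' distance to its group centroid with the standard imaginary-axis
#' correction for semimetric input: squared distance = (distance on the
#' positive axes)^2 minus (distance on the imaginary axes)^2, floored at
#' zero before the square root.
#'
#' @param diss a `diss_matrix`.
#' @param grouping named vector mapping every sample id to a group; a
#'   single group measures dispersion around the overall centroid.
#' @return list with `distances` (named per sample), `centroids` (group
#'   centroids on the positive axes), `grouping`.
#' @export
dispersion_of_homogeneity <- function(diss, grouping) {
  stopifnot(inherits(diss, "diss_matrix"))
  grouping <- unlist(grouping)
  g <- as.character(grouping[rownames(diss)])
  if (anyNA(g)) stop("grouping must cover all samples")
  emb <- pcoa(diss)
  pos <- emb$coordinates
  neg <- emb$axes_neg
  sizes <- table(g)
  group_mean <- function(m) {
    s <- rowsum(m, g)
    s / as.vector(sizes[rownames(s)])
  }
  cen_pos <- group_mean(pos)
  cen_neg <- group_mean(neg)
  dist2 <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    cp <- cen_pos[g[i], , drop = TRUE]
    cn <- if (ncol(neg) > 0) cen_neg[g[i], , drop = TRUE] else numeric(0)
    d2 <- sum((pos[i, ] - cp)^2)
    if (ncol(neg) > 0) d2 <- d2 - sum((neg[i, ] - cn)^2)
    dist2[i] <- max(d2, 0)
  }
  singles <- names(which(table(g) == 1))
  if (length(singles))
    warning("group(s) of size 1 have centroid distance 0: ",
            paste(singles, collapse = ", "))
  list(distances = stats::setNames(sqrt(dist2), rownames(diss)),
       centroids = cen_pos,
       grouping = stats::setNames(g, rownames(diss)))
}
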