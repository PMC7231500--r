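#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371.0 km (the conventional
#' mean Earth radius). Vectorised over coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (N/E positive).
#' @return distance in kilometres.
#' @examples
#' haversine_distance(46.53995, 12.16390, 46.53427, 11.92253)  # ~18.5 km
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # radius already in km
}

# flat-earth approximation; monotone sensitivity alternative at small extents
equirectangular_distance <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  x <- (lon2 - lon1) * to_rad * cos((lat1 + lat2) / 2 * to_rad)
  y <- (lat2 - lat1) * to_rad
  6371 * sqrt(x^2 + y^2)
}

#' Pairwise geographic distance matrix
#'
#' @param metadata data frame with `sample_id`, `latitude`, `longitude`
#'   columns (see [read_sample_metadata()]).
#' @param method `"haversine"` (default) or `"equirectangular"` (sensitivity
#'   check; both preserve rank order at small spatial extents).
#' @return a symmetric `geo_distance_matrix` in kilometres with zero
#'   diagonal.
#' @export
geo_distance_matrix <- function(metadata,
                                method = c("haversine", "equirectangular")) {
  method <- match.arg(method)
  need <- c("sample_id", "latitude", "longitude")
  if (!all(need %in% names(metadata)))
    stop("metadata requires columns: ", paste(need, collapse = ", "))
  if (anyNA(metadata$latitude) || anyNA(metadata$longitude))
    stop("missing coordinates")
  n <- nrow(metadata)
  ids <- metadata$sample_id
  fun <- if (method == "haversine") haversine_distance else equirectangular_distance
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- fun(metadata$latitude[i], metadata$longitude[i],
             metadata$latitude[j], metadata$longitude[j])
    m[i, j] <- m[j, i] <- d
  }
  class(m) <- c("geo_distance_matrix", class(m))
  m
}

#' Distance decay of community similarity
#'
#' Correlates the n(n-1)/2 pairwise dissimilarities with the corresponding
#' geographic distances. Spearman uses average ranks; p-values come from
#' the standard large-sample approximations. Caveat (reported, not fixed
#' here): pairwise values are not independent, so these p-values are
#' anti-conservative; `permutations > 0` adds a Mantel-style permutation p
#' for comparison.
#'
#' @param diss a `diss_matrix`.
#' @param geo a `geo_distance_matrix` over the same samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param permutations optional number of Mantel permutations (0 = skip).
#' @param seed seed for the permutations.
#' @return list with `coefficient`, `p_value`, `n_pairs`, `method`, and
#'   `mantel_p` when permutations were requested.
#' @export
distance_decay <- function(diss, geo, method = c("spearman", "pearson"),
                           permutations = 0, seed = NULL) {
  stopifnot(inherits(diss, "diss_matrix"))
  method <- match.arg(method)
  if (!identical(rownames(diss), rownames(geo)))
    stop("dissimilarity and distance matrices must cover the same samples")
  if (nrow(diss) < 3L) stop("need at least three samples")
  dv <- lower_pairs(unclass(diss))
  gv <- lower_pairs(unclass(geo))
  if (stats::sd(dv) == 0 || stats::sd(gv) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(dv, gv, method = method, exact = FALSE))
  out <- list(coefficient = unname(ct$estimate), p_value = ct$p.value,
              n_pairs = length(dv), method = method)
  if (permutations > 0) {
    obs <- out$coefficient
    n <- nrow(diss)
    with_seed(seed, {
      perm <- vapply(seq_len(permutations), function(k) {
        ord <- sample.int(n)
        suppressWarnings(stats::cor(
          dv, lower_pairs(unclass(geo)[ord, ord]), method = method))
      }, numeric(1))
    })
    out$mantel_p <- (sum(abs(perm) >= abs(obs)) + 1) / (permutations + 1)
  }
  out
}

#' Correlation of alpha diversity with water depth
#'
#' Spearman rank correlation between a per-sample alpha-diversity value and
#' depth, depth oriented deeper-positive. The sign therefore depends on the
#' depth orientation convention; the magnitude is the robust quantity.
#'
#' @param alpha numeric vector of per-sample index values.
#' @param depth numeric vector of depths (metres) or relative depth ranks,
#'   deeper positive.
#' @return list with `rho` and `p_value` (two-sided).
#' @export
alpha_depth_correlation <- function(alpha, depth) {
  if (length(alpha) != length(depth)) stop("length mismatch")
  keep <- !(is.na(alpha) | is.na(depth))
  if (sum(keep) < 3L) stop("need at least three paired observations")
  if (stats::sd(alpha[keep]) == 0 || stats::sd(depth[keep]) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(alpha[keep], depth[keep],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}

#' Split samples into depth groups
#'
#' `k = 2` is a median split by rank of depth (deeper-positive): the
#' ceiling(n/2) shallowest samples versus the rest. `k = 3` assigns the
#' ceiling(n/2) shallowest samples to `"shallow"` and splits the remainder
#' evenly into `"intermediate"` and `"deep"` (for 8 samples: 4/2/2).
#'
#' @param depth named numeric vector (deeper positive); names are sample
#'   ids.
#' @param k 2 or 3.
#' @return named character vector of group labels.
#' @export
depth_groups <- function(depth, k = 2) {
  if (is.null(names(depth))) stop("depth vector must be named by sample id")
  n <- length(depth)
  ord <- rank(depth, ties.method = "first")
  if (k == 2) {
    g <- ifelse(ord <= ceiling(n / 2), "shallow", "deep")
  } else if (k == 3) {
    n_shallow <- ceiling(n / 2)
    rest <- n - n_shallow
    n_mid <- ceiling(rest / 2)
    g <- ifelse(ord <= n_shallow, "shallow",
                ifelse(ord <= n_shallow + n_mid, "intermediate", "deep"))
  } else stop("k must be 2 or 3")
  stats::setNames(g, names(depth))
}

#' Kruskal-Wallis test on pooled depth-group compositions
#'
#' Community composition data within each depth group are combined into one
#' pooled abundance vector; the per-taxon abundances of the pooled vectors
#' (taxa with positive pooled count) are the observations, and their rank
#' distributions are compared across groups with the Kruskal-Wallis rank
#' sum test (tie-corrected, chi-squared approximation).
#'
#' @param table an `abundance_table`.
#' @param grouping named vector mapping every sample id to a depth group.
#' @return list with `statistic` (H), `p_value`, `df`, and the pooled
#'   observation list `observations`.
#' @export
kruskal_wallis_depth_groups <- function(table, grouping) {
  stopifnot(is_abundance_table(table))
  grouping <- unlist(grouping)
  g <- as.character(grouping[rownames(table)])
  if (anyNA(g)) stop("grouping must cover all samples")
  if (length(unique(g)) < 2L) stop("need at least two groups")
  pooled <- rowsum(unclass(table), g)
  obs <- lapply(rownames(pooled), function(grp) {
    v <- pooled[grp, ]
    v <- v[v > 0]
    if (length(v) < 2L)
      stop("group '", grp, "' has fewer than two positive-abundance taxa")
    unname(v)
  })
  names(obs) <- rownames(pooled)
  kt <- stats::kruskal.test(obs)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), observations = obs)
}
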