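#' Reduce each sample to its n most abundant taxa (ties included)
#'
#' Field protocols that count only the most abundant species per sample keep
#' every taxon tied with the count at rank `n`, rather than truncating
#' arbitrarily; a sample can therefore retain more than `n` taxa. Counts of
#' retained taxa are unchanged; all other counts are set to zero and taxa
#' that end up with zero total are dropped. The operation is idempotent.
#'
#' @param table an `abundance_table`.
#' @param n number of most abundant taxa to keep per sample (default 10).
#' @return a reduced `abundance_table`.
#' @examples
#' tab <- abundance_table(rbind(s = c(a = 5, b = 3, c = 3, d = 1)))
#' top_n_reduce(tab, 2)  # keeps a, b and the tied c
#' @export
top_n_reduce <- function(table, n = 10) {
  stopifnot(is_abundance_table(table))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  m <- unclass(table)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    pos <- sort(x[x > 0], decreasing = TRUE)
    if (length(pos) <= n) next
    cutoff <- pos[n]
    m[i, x < cutoff] <- 0L
  }
  abundance_table(m)
}

#' Remove named taxa from an abundance table
#'
#' Used e.g. to drop a taxonomic group that is not counted consistently
#' across datasets. The removal is logged: the result carries an attribute
#' `"exclusion_log"`, a data frame of specimens removed per sample.
#'
#' @param table an `abundance_table`.
#' @param taxa character vector of taxon ids to remove; ids absent from the
#'   table are ignored.
#' @return an `abundance_table` without the named taxa.
#' @export
exclude_taxa <- function(table, taxa) {
  stopifnot(is_abundance_table(table))
  taxa <- intersect(as.character(taxa), colnames(table))
  if (length(taxa) == 0L) {
    attr(table, "exclusion_log") <-
      data.frame(sample_id = rownames(table),
                 removed = rep(0L, nrow(table)))
    return(table)
  }
  removed <- rowSums(table[, taxa, drop = FALSE])
  keep <- setdiff(colnames(table), taxa)
  if (length(keep) == 0L || any(rowSums(table[, keep, drop = FALSE]) < 1L))
    stop("exclusion would empty sample(s): ",
         paste(rownames(table)[rowSums(table[, keep, drop = FALSE]) < 1L],
               collapse = ", "))
  out <- abundance_table(unclass(table)[, keep, drop = FALSE])
  attr(out, "exclusion_log") <-
    data.frame(sample_id = rownames(table), removed = as.integer(removed))
  out
}

#' Combine samples into sites
#'
#' Samples taken from the same environment, site and depth are merged by
#' summing their counts; the total specimen count is conserved exactly.
#' Metadata rows are merged alongside: fields identical within a site are
#' carried over; conflicting fields raise an error under `conflict =
#' "error"` or keep the first sample's value under `conflict = "first"`.
#'
#' @param table an `abundance_table`.
#' @param grouping named character vector or list mapping every sample id in
#'   `table` to a site id.
#' @param metadata optional metadata `data.frame` with a `sample_id` column.
#' @param conflict `"error"` (default) or `"first"`.
#' @return the merged `abundance_table` if `metadata` is `NULL`, otherwise
#'   `list(table =, metadata =)`.
#' @export
merge_by_site <- function(table, grouping, metadata = NULL,
                          conflict = c("error", "first")) {
  stopifnot(is_abundance_table(table))
  conflict <- match.arg(conflict)
  grouping <- unlist(grouping)
  missing <- setdiff(rownames(table), names(grouping))
  if (length(missing))
    stop("samples without a site assignment: ", paste(missing, collapse = ", "))
  site <- as.character(grouping[rownames(table)])
  sites <- unique(site)
  m <- rowsum(unclass(table), site, reorder = FALSE)
  out <- abundance_table(m[sites, , drop = FALSE])
  if (is.null(metadata)) return(out)
  md <- metadata[match(rownames(table), metadata$sample_id), , drop = FALSE]
  merged <- lapply(sites, function(s) {
    rows <- md[site == s, , drop = FALSE]
    one <- rows[1, , drop = FALSE]
    one$sample_id <- s
    for (col in setdiff(names(rows), "sample_id")) {
      if (col == "n_specimens" && is.numeric(rows[[col]])) {
        # specimen totals are additive, never a conflict
        one[[col]] <- sum(rows[[col]], na.rm = TRUE)
        next
      }
      vals <- unique(rows[[col]])
      vals <- vals[!is.na(vals)]
      if (length(vals) > 1 && conflict == "error")
        stop(sprintf("conflicting '%s' within site '%s'", col, s))
    }
    one
  })
  md_out <- do.call(rbind, merged)
  rownames(md_out) <- NULL
  list(table = out, metadata = md_out)
}

#' Per-attribute direction table for relative depth inference
#'
#' Orientation of the classical soft-bottom depth criteria, `+1` meaning
#' larger values indicate deeper settings: deposit feeding and articulated
#' bivalves increase with depth, so the suspension/deposit ratio points
#' shallow; grazers, gastropod abundance and diversity, encrustation and
#' reef-builder fragments are shallow-water signals while the
#' carnivore/grazer ratio rises with depth.
#'
#' @return named numeric vector of +1/-1 directions.
#' @export
depth_attribute_directions <- function() {
  c(suspension_deposit_ratio = -1,
    carnivore_grazer_ratio = +1,
    articulated_bivalves = +1,
    gastropod_abundance = -1,
    gastropod_diversity = -1,
    encrustation = -1,
    reef_builder_fragments = -1)
}

#' Infer relative water-depth ranks from ecological attributes
#'
#' Each attribute is converted to an average rank over samples, oriented so
#' that larger means deeper (per-attribute directions), multiplied by its
#' weight, summed, and centred to mean zero. Positive scores indicate deeper
#' settings. An attribute constant across samples contributes zero spread
#' (with a warning). Deterministic.
#'
#' @param profiles data frame or matrix of attribute scores, one row per
#'   sample; rownames or a `sample_id` column give the ids.
#' @param weights named non-negative weights per attribute; default equal.
#' @param directions named +1/-1 vector; defaults to
#'   [depth_attribute_directions()] for recognised names and +1 otherwise.
#' @return named numeric vector of centred depth-rank scores (deeper
#'   positive).
#' @export
infer_depth_rank <- function(profiles, weights = NULL, directions = NULL) {
  if (is.data.frame(profiles) && "sample_id" %in% names(profiles)) {
    ids <- as.character(profiles$sample_id)
    profiles <- as.matrix(profiles[setdiff(names(profiles), "sample_id")])
    rownames(profiles) <- ids
  } else {
    profiles <- as.matrix(profiles)
  }
  if (nrow(profiles) < 2L) stop("need at least two samples")
  attrs <- colnames(profiles)
  if (is.null(attrs)) stop("attributes must be named")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(attrs)), attrs)
  if (!all(attrs %in% names(weights)))
    stop("every scored attribute needs a weight")
  weights <- weights[attrs]
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  default_dir <- depth_attribute_directions()
  if (is.null(directions)) {
    directions <- stats::setNames(rep(1, length(attrs)), attrs)
    known <- intersect(attrs, names(default_dir))
    directions[known] <- default_dir[known]
  }
  directions <- directions[attrs]
  score <- rep(0, nrow(profiles))
  for (a in attrs) {
    v <- profiles[, a]
    if (length(unique(v)) == 1L) {
      warning("attribute '", a, "' is constant across samples")
      next
    }
    score <- score + weights[[a]] * directions[[a]] * rank(v, ties.method = "average")
  }
  score <- score - mean(score)
  stats::setNames(score, rownames(profiles))
}
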