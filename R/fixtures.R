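#' Packaged reef-basin datasets
#'
#' Small plain-text fixtures shipped with the package, transcribed from the
#' published data tables of two reef-associated soft-bottom studies:
#'
#' * `cassian_new4()` — specimen counts of the four newly collected
#'   Triassic (Cassian Formation) bulk samples, already reduced to the ten
#'   most abundant species per sample with ties retained and with
#'   foraminifers excluded from the Rumerlo ski slope sample; taxon names
#'   are canonicalised (qualifiers such as "sensu ..." dropped).
#' * `cassian_metadata()` — age zone, coordinates, specimen totals,
#'   dominance, evenness, mean pairwise proportional dissimilarity (PPD)
#'   and inferred relative water-depth rank (deeper positive) of the eight
#'   Cassian samples.
#' * `safaga_metadata()` — environment, depth (m), coordinates and
#'   diversity of the 13 Bay of Safaga (Red Sea) bulk samples; with
#'   `by_site = TRUE`, samples taken from the same environment, site and
#'   depth are merged to the published 8-site dataset. The mangrove-channel
#'   depth is printed as "<1 m" and stored as 0.5 m.
#' * `cassian_ppd()` / `safaga_ppd()` — the published pairwise PPD
#'   matrices (2 decimal places) of the 8 Cassian samples and the 8
#'   combined Safaga sites.
#' * `safaga_site_grouping()` — the sample-to-site map behind the by-site
#'   dataset.
#'
#' @param by_site for `safaga_metadata()`: merge replicate samples per
#'   site (default `FALSE`).
#' @return an `abundance_table`, a metadata `data.frame`, a `diss_matrix`,
#'   or a named character vector, as described.
#' @name fixtures
NULL

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "reefbeta")
  if (path == "") stop("fixture not found: ", name)
  path
}

#' @rdname fixtures
#' @export
cassian_new4 <- function() {
  read_abundance_table(fixture_path("cassian_new4_counts.csv"), layout = "long")
}

#' @rdname fixtures
#' @export
cassian_metadata <- function() {
  read_sample_metadata(fixture_path("cassian_meta8.csv"))
}

#' @rdname fixtures
#' @export
safaga_metadata <- function(by_site = FALSE) {
  md <- read_sample_metadata(fixture_path("safaga_meta13.csv"))
  if (!by_site) return(md)
  sites <- unique(md$site_id)
  merged <- lapply(sites, function(s) {
    rows <- md[md$site_id == s, , drop = FALSE]
    one <- rows[1, , drop = FALSE]
    one$sample_id <- s
    one$n_specimens <- sum(rows$n_specimens)
    one$berger_parker <- NA_real_
    one$evenness <- NA_real_
    one$mean_ppd <- NA_real_
    one
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' @rdname fixtures
#' @export
safaga_site_grouping <- function() {
  md <- read_sample_metadata(fixture_path("safaga_meta13.csv"))
  stats::setNames(md$site_id, md$sample_id)
}

#' @rdname fixtures
#' @export
cassian_ppd <- function() {
  read_dissimilarity_matrix(fixture_path("cassian_ppd_table4.csv"), "ppd")
}

#' @rdname fixtures
#' @export
safaga_ppd <- function() {
  read_dissimilarity_matrix(fixture_path("safaga_ppd_table5.csv"), "ppd")
}
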