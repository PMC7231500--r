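#' Sample-by-taxon abundance tables
#'
#' An `abundance_table` is an integer matrix of specimen counts with one row
#' per sample and one column per taxon, the universal input of the package.
#' Validation enforces non-negative integral counts, unique sample and taxon
#' ids, a positive total for every sample, and drops taxa whose total count
#' over all samples is zero (so downstream proportion vectors never carry
#' all-zero columns).
#'
#' @param counts numeric matrix (or object coercible to one) of non-negative
#'   integer counts; rows are samples, columns taxa.
#' @param sample_ids,taxon_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return an `abundance_table`: an integer matrix with class attribute and
#'   full dimnames.
#' @examples
#' abundance_table(rbind(s1 = c(a = 3, b = 1), s2 = c(a = 0, b = 5)))
#' @export
abundance_table <- function(counts, sample_ids = rownames(counts),
                            taxon_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("no records: empty abundance table")
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(ncol(counts)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids: ",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon ids: ",
    paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integral (specimen counts)")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, taxon_ids)
  zero_sample <- rowSums(counts) < 1L
  if (any(zero_sample))
    stop("sample(s) with zero total count: ",
         paste(sample_ids[zero_sample], collapse = ", "))
  counts <- counts[, colSums(counts) > 0L, drop = FALSE]
  class(counts) <- c("abundance_table", class(counts))
  counts
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa, %d specimens\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @export
`[.abundance_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("abundance_table", class(out))
  out
}

is_abundance_table <- function(x) inherits(x, "abundance_table")

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("no records: empty file ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    fileEncoding = "UTF-8", comment.char = "")
}

#' Read an abundance table from CSV/TSV
#'
#' Both dialects carry a header row and are UTF-8. `layout = "wide"` expects
#' samples as rows (first column the sample id) and taxa as columns;
#' `layout = "long"` expects the three columns `sample_id`, `taxon_id`,
#' `count`. Order of first appearance of samples and taxa is preserved, and
#' validation (see [abundance_table()]) drops zero-total taxa.
#'
#' @param path file path; comma or tab separated, inferred from content.
#' @param layout `"wide"` or `"long"`.
#' @return an `abundance_table`.
#' @export
read_abundance_table <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  df <- read_delim_auto(path)
  if (nrow(df) == 0L) stop("no records in ", path)
  if (layout == "long") {
    need <- c("sample_id", "taxon_id", "count")
    if (!all(need %in% names(df)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    key <- paste(df$sample_id, df$taxon_id, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (sample, taxon) pair(s): ",
           paste(unique(gsub("\r", " / ", key[duplicated(key)])), collapse = "; "))
    counts <- suppressWarnings(as.numeric(df$count))
    bad <- which(is.na(counts))
    if (length(bad))
      stop(sprintf("malformed numeric cell in row %d, column 'count': '%s'",
                   bad[1], df$count[bad[1]]))
    sids <- unique(df$sample_id)
    tids <- unique(df$taxon_id)
    m <- matrix(0, length(sids), length(tids), dimnames = list(sids, tids))
    m[cbind(match(df$sample_id, sids), match(df$taxon_id, tids))] <- counts
    abundance_table(m)
  } else {
    sids <- as.character(df[[1]])
    num <- df[-1]
    for (j in seq_along(num)) {
      v <- suppressWarnings(as.numeric(num[[j]]))
      bad <- which(is.na(v) & !is.na(num[[j]]))
      if (length(bad))
        stop(sprintf("malformed numeric cell in row %d, column '%s': '%s'",
                     bad[1], names(num)[j], num[[j]][bad[1]]))
      num[[j]] <- v
    }
    m <- as.matrix(num)
    rownames(m) <- sids
    abundance_table(m)
  }
}

#' Write an abundance table to CSV
#'
#' @param table an `abundance_table`.
#' @param path output file path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(is_abundance_table(table))
  if (layout == "wide") {
    df <- data.frame(sample_id = rownames(table), unclass(table),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    idx <- which(unclass(table) > 0, arr.ind = TRUE)
    df <- data.frame(sample_id = rownames(table)[idx[, 1]],
                     taxon_id = colnames(table)[idx[, 2]],
                     count = table[idx])
    df <- df[order(idx[, 1], idx[, 2]), ]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Parse a latitude/longitude coordinate
#'
#' Accepts signed decimal degrees (`-12.5`) and hemisphere-suffixed strings
#' as printed in field tables (`"46.53995N"`, `"12.16390E"`, with optional
#' space before the suffix). South and west are returned negative; WGS84 is
#' assumed.
#'
#' @param x character or numeric vector.
#' @return numeric vector of signed decimal degrees.
#' @export
parse_coordinate <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  suffix <- toupper(substring(x, nchar(x)))
  has_suffix <- suffix %in% c("N", "S", "E", "W")
  num <- suppressWarnings(as.numeric(ifelse(
    has_suffix, trimws(substr(x, 1, nchar(x) - 1)), x)))
  bad <- which(is.na(num) & nzchar(x))
  if (length(bad)) stop("unparseable coordinate: '", x[bad[1]], "'")
  sgn <- ifelse(has_suffix & suffix %in% c("S", "W"), -1, 1)
  num * sgn
}

#' Read a sample metadata table
#'
#' Expects a CSV/TSV with a `sample_id` column; recognised optional columns
#' are `latitude`, `longitude` (signed decimals or hemisphere-suffixed
#' strings), `depth_m`, `depth_rank` (deeper-positive), `age_zone`,
#' `environment` and `n_specimens`; missing values are empty strings. Extra
#' columns are carried through untouched.
#'
#' @param path file path.
#' @return a `data.frame`, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- read_delim_auto(path)
  if (!"sample_id" %in% names(df)) stop("metadata requires a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (col in c("latitude", "longitude"))
    if (col %in% names(df)) df[[col]] <- parse_coordinate(df[[col]])
  for (col in c("depth_m", "depth_rank", "n_specimens"))
    if (col %in% names(df))
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if ("latitude" %in% names(df) &&
      any(abs(df$latitude) > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if ("longitude" %in% names(df) &&
      any(abs(df$longitude) > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]")
  if ("depth_m" %in% names(df) && any(df$depth_m < 0, na.rm = TRUE))
    stop("depth_m must be non-negative")
  df
}
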