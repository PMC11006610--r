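# The long-format community table: the interchange type every module
# consumes and produces. One row is one taxon's count in one sample
# (trap/visit) in one within-year period at one site.

CT_COLS <- c("study_id", "area_id", "site_id", "year", "period",
             "sample_id", "taxon_id", "rank", "count")
CT_RANKS <- c("species", "genus", "family", "higher")

#' Construct and validate a long-format community table
#'
#' A community table holds survey records of individuals per taxon per
#' sample per site per year, with the hierarchy study > area > site and an
#' optional within-year period (e.g. month). It is the input to effort
#' standardization and the output of the simulators.
#'
#' Invariants enforced: counts are non-negative integers; the key
#' (site_id, year, period, sample_id, taxon_id) is unique; every site
#' belongs to exactly one area and one study.
#'
#' @param df data frame with columns `study_id`, `area_id`, `site_id`,
#'   `year`, `period`, `sample_id`, `taxon_id`, `rank`, `count`.
#' @return a `community_table` (a validated data frame).
#' @export
community_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CT_COLS, names(df))
  if (length(missing_cols)) {
    stop("community table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), CT_COLS)
  df <- df[, c(CT_COLS, extra)]
  for (col in c("study_id", "area_id", "site_id", "period", "sample_id",
                "taxon_id", "rank")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$year <- as.integer(df$year)
  df$count <- as.numeric(df$count)
  validate_community_table(df)
  class(df) <- c("community_table", "data.frame")
  df
}

#' @rdname community_table
#' @param x object to validate.
#' @export
validate_community_table <- function(x) {
  if (any(is.na(x$count)) || any(x$count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(x$count != floor(x$count))) {
    stop("counts must be integers", call. = FALSE)
  }
  if (nrow(x)) {
    key <- paste(x$site_id, x$year, x$period, x$sample_id, x$taxon_id, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (site, year, period, sample, taxon) records", call. = FALSE)
    }
    map <- unique(x[, c("site_id", "area_id", "study_id")])
    if (anyDuplicated(map$site_id)) {
      stop("a site_id maps to more than one area_id/study_id", call. = FALSE)
    }
    bad <- setdiff(unique(x$rank), CT_RANKS)
    if (length(bad)) {
      stop("unknown rank values: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf(
    "Community table: %d records | %d stud%s, %d site%s, years %s\n",
    nrow(x), length(unique(x$study_id)),
    if (length(unique(x$study_id)) == 1L) "y" else "ies",
    length(unique(x$site_id)),
    if (length(unique(x$site_id)) == 1L) "" else "s",
    if (nrow(x)) paste(range(x$year), collapse = "-") else "-"))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read / write the community-table CSV dialect
#'
#' UTF-8 CSV with the canonical header
#' `study_id,area_id,site_id,year,period,sample_id,taxon_id,rank,count`.
#'
#' @param path file path.
#' @return `read_community_csv()` returns a `community_table`.
#' @export
read_community_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(year = "integer", count = "numeric"),
                        encoding = "UTF-8")
  community_table(df)
}

#' @rdname read_community_csv
#' @param x a `community_table`.
#' @export
write_community_csv <- function(x, path) {
  stopifnot(inherits(x, "community_table") || is.data.frame(x))
  utils::write.csv(as.data.frame(x)[, intersect(c(CT_COLS, "count_display"), names(x))],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate a community table to per site-year assemblages
#'
#' Sums counts over periods and samples, yielding one species-by-count
#' record per site and year (the `AssemblageYear` layout used by the
#' diversity metrics and the SAD interval analysis).
#'
#' @param table a `community_table` or compatible data frame.
#' @param keep_zero keep taxa with zero total in a year (needed for
#'   population models); dropped by default.
#' @return data frame with columns `site_id`, `year`, `taxon_id`, `count`.
#' @export
assemblage_counts <- function(table, keep_zero = FALSE) {
  df <- as.data.frame(table)
  if (!nrow(df)) {
    return(data.frame(site_id = character(), year = integer(),
                      taxon_id = character(), count = numeric()))
  }
  agg <- stats::aggregate(count ~ site_id + year + taxon_id, data = df, FUN = sum)
  if (!keep_zero) agg <- agg[agg$count > 0, , drop = FALSE]
  agg <- agg[order(agg$site_id, agg$year, agg$taxon_id), c("site_id", "year", "taxon_id", "count")]
  rownames(agg) <- NULL
  agg
}

# Genus prefix convention: taxon identifiers carry their genus before the
# first underscore ("g03_sp12" -> genus "g03"). Genus-level records use the
# bare genus id.
genus_of <- function(taxon_id) sub("_.*$", "", taxon_id)
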