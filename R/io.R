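# CSV schemas. All tables are comma-separated with a header row, "." decimal,
# UTF-8, no thousands separators.

.counts_cols <- c("sample_id", "group", "condition", "time_h",
                  "count_cells_per_ml")

#' Write count series to a counts CSV
#'
#' Long format, one row per (sample, condition, timepoint), columns
#' `sample_id`, `group`, `condition`, `time_h`, `count_cells_per_ml`.
#'
#' @param series a list of [count_series()] or a `synthetic_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(series, path) {
  if (inherits(series, "synthetic_cohort")) series <- series$series
  stopifnot(all(vapply(series, inherits, logical(1), "count_series")))
  rows <- lapply(series, function(s) data.frame(
    sample_id = s$sample_id, group = s$group, condition = s$condition,
    time_h = s$timepoints, count_cells_per_ml = s$counts,
    stringsAsFactors = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a counts CSV into count series
#'
#' Validates the schema (columns present, numeric counts, no negative counts,
#' no duplicate sample/condition/time rows) and returns one [count_series()]
#' per (sample_id, condition), rows sorted by time.
#'
#' @param path CSV file with columns `sample_id`, `group`, `condition`,
#'   `time_h`, `count_cells_per_ml`.
#' @return List of [count_series()].
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop_invalid("counts file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.counts_cols, names(df))
  if (length(missing))
    stop_invalid("counts file %s lacks column(s): %s", path,
                 paste(missing, collapse = ", "))
  if (!is.numeric(df$time_h) || !is.numeric(df$count_cells_per_ml))
    stop_invalid("`time_h` and `count_cells_per_ml` must be numeric in %s", path)
  if (any(is.na(df$count_cells_per_ml)))
    stop_invalid("non-numeric or missing count in %s", path)
  neg <- which(df$count_cells_per_ml < 0)
  if (length(neg))
    stop_invalid("negative count at row %d of %s", neg[1L], path)
  key <- paste(df$sample_id, df$condition, df$time_h, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop_invalid("duplicate (sample, condition, time) at row %d of %s",
                 dup[1L], path)
  split_keys <- interaction(df$sample_id, df$condition, drop = TRUE)
  lapply(unname(split(df, split_keys)), function(d) {
    d <- d[order(d$time_h), ]
    count_series(d$sample_id[1L], d$group[1L], d$condition[1L],
                 d$time_h, d$count_cells_per_ml)
  })
}

#' Write the truth table of a synthetic cohort
#' @param cohort a `synthetic_cohort`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  write.csv(cohort$truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the package version, the command/stage, the RNG seeds used, a
#' config echo and the md5 digests of the files written, so any output can
#' be regenerated from the manifest alone.
#'
#' @param path output JSON file.
#' @param command short label of the producing command.
#' @param config configuration list echoed verbatim (classes dropped).
#' @param seeds named list/vector of RNG seeds used.
#' @param files character vector of output files to digest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seeds = list(),
                           files = character(0)) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  config <- strip(config)
  digests <- vapply(files, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
    character(1))
  manifest <- list(
    tool = "moranfix",
    version = as.character(packageVersion("moranfix")),
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    config = unclass(config),
    files = as.list(digests)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
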