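# Report writers. Formatting follows the presentation conventions used
# throughout: p-values to 4 decimals, rates to one decimal of percent.
# Row order and number formatting are fixed, so repeated runs with the same
# configuration produce byte-identical files.

#' Write the per-N enumeration summary as CSV
#'
#' One row per total sample size with columns \code{n_total,
#' total_significant, fi_attainable, fi_unattainable, ties_excluded,
#' unattainability_rate} (rate as percent, one decimal).
#'
#' @param enum an \code{"fi_enum"} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_summary_csv <- function(enum, path) {
  stopifnot(inherits(enum, "fi_enum"))
  s <- enum$summary
  out <- data.frame(
    n_total = s$n_total,
    total_significant = s$total_significant,
    fi_attainable = s$fi_attainable,
    fi_unattainable = s$fi_unattainable,
    ties_excluded = s$ties_excluded,
    unattainability_rate = ifelse(
      is.na(s$unattainability_rate), "",
      sprintf("%.1f", 100 * s$unattainability_rate)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-table enumeration records as CSV
#'
#' One row per baseline-significant table with columns \code{a, b, c, d,
#' n_total, p_baseline, status, mechanism, fi, min_cell, imbalance_ratio}.
#'
#' @inheritParams write_summary_csv
#' @return \code{path}, invisibly.
#' @export
write_records_csv <- function(enum, path) {
  rec <- .as_records(enum)
  out <- data.frame(
    a = rec$a, b = rec$b, c = rec$c, d = rec$d, n_total = rec$n_total,
    p_baseline = sprintf("%.4f", rec$p_baseline),
    status = rec$status,
    mechanism = ifelse(is.na(rec$mechanism), "", rec$mechanism),
    fi = ifelse(is.na(rec$fi), "", as.character(rec$fi)),
    min_cell = rec$min_cell,
    imbalance_ratio = sprintf("%.6f", rec$imbalance_ratio))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the minimum-cell tally as CSV
#'
#' @inheritParams write_summary_csv
#' @return \code{path}, invisibly.
#' @export
write_min_cell_csv <- function(enum, path) {
  t <- min_cell_tally(enum)
  out <- data.frame(min_cell = t$min_cell, count = t$count,
                    percent = sprintf("%.2f", t$percent))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the mechanism tally as JSON
#'
#' @inheritParams write_summary_csv
#' @return \code{path}, invisibly.
#' @export
write_mechanism_json <- function(enum, path) {
  m <- mechanism_tally(enum)
  jsonlite::write_json(as.list(m), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the full enumeration report to a directory
#'
#' Writes \code{summary.csv}, \code{records.csv}, \code{min_cell.csv},
#' \code{mechanisms.json}, and (when at least one evaluable table is
#' unattainable and one attainable, so the correlation is defined)
#' \code{association.json}.
#'
#' @param enum an \code{"fi_enum"} object.
#' @param dir output directory; created if missing.
#' @return character vector of files written, invisibly.
#' @export
write_enum_report <- function(enum, dir) {
  stopifnot(inherits(enum, "fi_enum"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(summary = file.path(dir, "summary.csv"),
             records = file.path(dir, "records.csv"),
             min_cell = file.path(dir, "min_cell.csv"),
             mechanisms = file.path(dir, "mechanisms.json"))
  write_summary_csv(enum, files[["summary"]])
  write_records_csv(enum, files[["records"]])
  write_min_cell_csv(enum, files[["min_cell"]])
  write_mechanism_json(enum, files[["mechanisms"]])
  assoc <- tryCatch(predictor_correlations(enum), error = function(e) NULL)
  if (!is.null(assoc)) {
    f <- file.path(dir, "association.json")
    write_association_json(assoc, f)
    files <- c(files, association = f)
  } else {
    message("association skipped: nonattainability constant across ",
            "evaluable tables in this range")
  }
  invisible(files)
}
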