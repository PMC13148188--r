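#' Registry of counterexample and published-trial tables
#'
#' The packaged set of 2x2 tables that demonstrate fragility-index
#' nonattainability: three constructed counterexamples (zero nonevents in
#' the selected arm; a single futile toggle; an 8-toggle path that moves the
#' p-value away from the boundary) and three published-trial tables
#' (FINEARTS-HF adverse events, ISCHEMIA angina-free status, FRESCO deaths),
#' each tagged with its expected attainability status.
#'
#' @return a data frame with columns \code{name, a, b, c, d,
#'   expected_status, note}.
#' @examples
#' fi_registry()
#' @export
fi_registry <- function() {
  path <- system.file("extdata", "registry.csv", package = "fragattain",
                      mustWork = TRUE)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(reg$name))
  reg
}

#' Read 2x2 tables from CSV
#'
#' Accepts either cell-name headers \code{a, b, c, d} or the clinical scheme
#' \code{events_A, nonevents_A, events_B, nonevents_B}, with an optional
#' \code{id} (or \code{name}) column. Every cell is validated; malformed
#' rows are reported by row number.
#'
#' @param path CSV file path (comma-separated, UTF-8, header required).
#' @return a data frame with columns \code{id, a, b, c, d}; \code{id}
#'   defaults to the row number when no id column is present.
#' @export
read_tables_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  long <- c("events_A", "nonevents_A", "events_B", "nonevents_B")
  if (all(c("a", "b", "c", "d") %in% names(df))) {
    cells <- df[c("a", "b", "c", "d")]
  } else if (all(long %in% names(df))) {
    cells <- df[long]
    names(cells) <- c("a", "b", "c", "d")
  } else {
    stop("CSV must contain columns a,b,c,d or ",
         "events_A,nonevents_A,events_B,nonevents_B")
  }
  idcol <- intersect(c("id", "name"), names(df))
  id <- if (length(idcol)) as.character(df[[idcol[1L]]])
        else as.character(seq_len(nrow(df)))
  bad <- integer()
  for (i in seq_len(nrow(cells))) {
    v <- suppressWarnings(as.numeric(unlist(cells[i, ])))
    if (anyNA(v) || any(v < 0) || any(v != round(v))) bad <- c(bad, i)
  }
  if (length(bad))
    stop("invalid cells (must be nonnegative integers) in row",
         if (length(bad) > 1L) "s" else "", " ",
         paste(bad, collapse = ", "))
  out <- data.frame(id = id, lapply(cells, function(v) as.integer(round(v))),
                    stringsAsFactors = FALSE)
  names(out) <- c("id", "a", "b", "c", "d")
  out
}

#' Write 2x2 tables to CSV
#'
#' Inverse of [read_tables_csv()]; the round trip preserves all cells
#' exactly.
#'
#' @param tables a data frame with columns \code{a, b, c, d} and optionally
#'   \code{id}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tables_csv <- function(tables, path) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  cols <- intersect(c("id", "a", "b", "c", "d"), names(tables))
  utils::write.csv(tables[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Random nondegenerate 2x2 tables
#'
#' Seeded generator for property testing. For each table a total N is drawn
#' uniformly from \code{2:n_total_max}, then a quadruple \code{{a,b,c,d}}
#' summing to N is drawn uniformly (stars-and-bars sampling) and rejected
#' until nondegenerate, giving a uniform draw over the valid tables at that
#' N. Uses R's Mersenne-Twister stream locally; the caller's RNG state is
#' left untouched.
#'
#' @param n_tables number of tables, >= 1.
#' @param n_total_max largest total sample size, >= 2.
#' @param seed integer seed; identical seeds give identical output.
#' @return a data frame with integer columns \code{a, b, c, d}.
#' @examples
#' random_tables(5, 30, seed = 1)
#' @export
random_tables <- function(n_tables, n_total_max, seed) {
  stopifnot(is.numeric(n_tables), length(n_tables) == 1L, n_tables >= 1,
            is.numeric(n_total_max), length(n_total_max) == 1L,
            n_total_max >= 2,
            is.numeric(seed), length(seed) == 1L)
  n_tables <- as.integer(n_tables)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  out <- matrix(0L, n_tables, 4L)
  for (i in seq_len(n_tables)) {
    n <- sample(2:as.integer(n_total_max), 1L)
    repeat {
      # uniform composition of n into 4 nonnegative parts: 3 bars among
      # n + 3 positions
      bars <- sort(sample.int(n + 3L, 3L))
      q <- c(bars[1L] - 1L, bars[2L] - bars[1L] - 1L,
             bars[3L] - bars[2L] - 1L, n + 3L - bars[3L])
      if ((q[1L] + q[2L] > 0L) && (q[3L] + q[4L] > 0L) &&
          (q[1L] + q[3L] > 0L) && (q[2L] + q[4L] > 0L)) break
    }
    out[i, ] <- q
  }
  out <- as.data.frame(out)
  names(out) <- c("a", "b", "c", "d")
  out
}
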