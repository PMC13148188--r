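#' Enumerate all nondegenerate 2x2 tables with a given total
#'
#' Generates every integer table \code{{a, b, c, d}} with
#' \code{a + b + c + d = n_total} that passes the nondegeneracy filters:
#' each arm contains at least one subject (\code{a + b > 0},
#' \code{c + d > 0}) and each outcome column is present (\code{a + c > 0},
#' \code{b + d > 0}). Tables are returned exactly once, in lexicographic
#' order of \code{(a, b, c)}.
#'
#' @param n_total total sample size, an integer >= 2.
#' @return a data frame with integer columns \code{a, b, c, d}.
#' @examples
#' enumerate_tables(2) # two tables: {1,0,0,1} and {0,1,1,0}
#' nrow(enumerate_tables(4))
#' @export
enumerate_tables <- function(n_total) {
  if (!is.numeric(n_total) || length(n_total) != 1L ||
      n_total != round(n_total) || n_total < 2)
    stop("n_total must be a single integer >= 2")
  n <- as.integer(n_total)
  g <- expand.grid(c = 0:n, b = 0:n, a = 0:n, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$a + g$b + g$c <= n, c("a", "b", "c")]
  g$d <- n - g$a - g$b - g$c
  keep <- (g$a + g$b > 0L) & (g$c + g$d > 0L) &
          (g$a + g$c > 0L) & (g$b + g$d > 0L)
  g <- g[keep, , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Two-sided p lookup array for one N: P[r1, k, a + 1] where r1 = a + b is
# the arm-A size (1..N-1), k = a + c the event-column total (1..N; k = N can
# be reached mid-path when the nonevent column empties, where p = 1), and a
# ranges over the hypergeometric support. Entries outside the support stay
# NA. One .support_p call per margin signature is the whole p-value cost of
# an enumeration at this N.
.p_lookup <- function(n, alpha) {
  P <- array(NA_real_, dim = c(n - 1L, n, n))
  for (r1 in 1:(n - 1L)) {
    r2 <- n - r1
    for (k in 1:n) {
      s <- .support_p(r1, r2, k)
      P[r1, k, s$a + 1L] <- s$p_two
    }
  }
  # snap boundary entries to the exactly arbitrated side of alpha, so every
  # downstream comparison (baseline significance, path crossing) is decided
  # in exact arithmetic rather than by platform rounding
  near <- which(!is.na(P) & abs(P - alpha) < .sig_eps)
  if (length(near)) {
    ind <- arrayInd(near, dim(P))
    for (j in seq_along(near)) {
      r1 <- ind[j, 1L]; k <- ind[j, 2L]; a <- ind[j, 3L] - 1L
      lt <- .exact_p_lt_alpha(r1, n - r1, k, a, alpha)
      if (is.na(lt)) next
      P[near[j]] <- if (lt) alpha * (1 - 1e-6) else alpha
    }
  }
  P
}

# Classify every nondegenerate table at one N. Returns a list with the
# per-N summary counts and a records data frame for baseline-significant
# tables (attainable / not attainable with mechanism / tied-excluded).
.classify_n <- function(n, alpha) {
  P <- .p_lookup(n, alpha)

  # all nondegenerate tables as (r1, k, a) triples, vectorised
  g <- expand.grid(k = 1:(n - 1L), r1 = 1:(n - 1L), KEEP.OUT.ATTRS = FALSE)
  lo <- pmax(0L, g$k - (n - g$r1))
  hi <- pmin(g$k, g$r1)
  len <- hi - lo + 1L
  r1 <- rep.int(g$r1, len)
  k <- rep.int(g$k, len)
  a <- sequence(len, from = lo, by = 1L)
  b <- r1 - a
  cc <- k - a
  d <- n - r1 - cc
  p0 <- P[cbind(r1, k, a + 1L)]

  total_tables <- length(a)
  sig <- p0 < alpha
  tied <- a == cc

  # evaluable = significant and untied; walk the forced toggle path
  ev <- which(sig & !tied)
  status <- character(total_tables)
  status[sig & tied] <- "tied_events"
  mech <- rep(NA_character_, total_tables)
  fi <- rep(NA_integer_, total_tables)

  for (i in ev) {
    if (a[i] < cc[i]) { # arm A selected: a + j, k + j move together
      ne <- b[i]
      if (ne == 0L) { status[i] <- "not_attainable"; mech[i] <- "no_legal_move"; next }
      js <- seq_len(ne)
      pv <- P[cbind(r1[i], k[i] + js, a[i] + js + 1L)]
    } else { # arm B selected: k + j moves, a fixed
      ne <- d[i]
      if (ne == 0L) { status[i] <- "not_attainable"; mech[i] <- "no_legal_move"; next }
      js <- seq_len(ne)
      pv <- P[cbind(r1[i], k[i] + js, a[i] + 1L)]
    }
    hit <- which(pv >= alpha)
    if (length(hit)) {
      status[i] <- "attainable"
      fi[i] <- hit[1L]
    } else {
      status[i] <- "not_attainable"
      mech[i] <- "path_exhausted"
    }
  }

  keep <- which(sig)
  rec <- data.frame(
    a = a[keep], b = b[keep], c = cc[keep], d = d[keep],
    n_total = rep.int(n, length(keep)),
    p_baseline = p0[keep], status = status[keep],
    mechanism = mech[keep], fi = fi[keep],
    min_cell = pmin(a[keep], b[keep], cc[keep], d[keep]),
    imbalance_ratio = pmax(r1[keep], n - r1[keep]) /
                      pmin(r1[keep], n - r1[keep]),
    stringsAsFactors = FALSE)
  rec <- rec[order(rec$a, rec$b, rec$c), , drop = FALSE]
  rownames(rec) <- NULL

  n_att <- sum(rec$status == "attainable")
  n_unatt <- sum(rec$status == "not_attainable")
  n_tied <- sum(rec$status == "tied_events")
  list(
    summary = data.frame(
      n_total = n, total_tables = total_tables,
      total_significant = nrow(rec),
      fi_attainable = n_att, fi_unattainable = n_unatt,
      ties_excluded = n_tied,
      unattainability_rate = if (n_att + n_unatt > 0)
        n_unatt / (n_att + n_unatt) else NA_real_),
    records = rec)
}

#' Complete enumeration study of fragility-index attainability
#'
#' Enumerates all nondegenerate 2x2 tables for every total sample size N in
#' \code{n_min:n_max}, classifies each baseline-significant table with the
#' original fragility-index algorithm ([fragility()]), and aggregates per-N
#' counts: total significant, FI attainable, FI unattainable, tied-event
#' exclusions, and the unattainability rate
#' \code{unattainable / (attainable + unattainable)}.
#'
#' Two-sided Fisher p-values are computed once per margin signature
#' (arm sizes and event-column total) and reused across tables and toggle
#' steps, which keeps the full N = 2-60 run at desk scale.
#'
#' @param n_min,n_max inclusive bounds on the total sample size,
#'   \code{2 <= n_min <= n_max}.
#' @param alpha significance level, default 0.05.
#' @param progress if \code{TRUE}, log one line per N to standard error.
#' @return an object of class \code{"fi_enum"}: a list with
#'   \code{summary} (one row per N) and \code{records} (one row per
#'   baseline-significant table, columns \code{a, b, c, d, n_total,
#'   p_baseline, status, mechanism, fi, min_cell, imbalance_ratio}), plus
#'   \code{alpha}, \code{n_min}, \code{n_max}.
#' @examples
#' e <- fragility_enumeration(2, 18)
#' subset(e$summary, n_total == 18)
#' @export
fragility_enumeration <- function(n_min, n_max, alpha = 0.05,
                                  progress = FALSE) {
  if (!is.numeric(n_min) || !is.numeric(n_max) ||
      length(n_min) != 1L || length(n_max) != 1L ||
      n_min != round(n_min) || n_max != round(n_max) ||
      n_min < 2 || n_min > n_max)
    stop("need integer bounds 2 <= n_min <= n_max")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  ns <- as.integer(n_min):as.integer(n_max)
  res <- vector("list", length(ns))
  for (i in seq_along(ns)) {
    res[[i]] <- .classify_n(ns[i], alpha)
    if (progress)
      message(sprintf("N = %d: %d significant, %d unattainable",
                      ns[i], res[[i]]$summary$total_significant,
                      res[[i]]$summary$fi_unattainable))
  }
  out <- list(
    summary = do.call(rbind, lapply(res, `[[`, "summary")),
    records = do.call(rbind, lapply(res, `[[`, "records")),
    alpha = alpha, n_min = as.integer(n_min), n_max = as.integer(n_max))
  rownames(out$summary) <- NULL
  rownames(out$records) <- NULL
  class(out) <- "fi_enum"
  out
}

# accept an fi_enum object or a bare records data frame
.as_records <- function(records) {
  if (inherits(records, "fi_enum")) records$records
  else if (is.data.frame(records)) records
  else stop("records must be an fi_enum object or a records data frame")
}

#' Minimum-cell tally of unattainable tables
#'
#' Distribution of \code{min(a, b, c, d)} across the unattainable tables of
#' an enumeration run. If nonattainability were purely a zero-cell artifact,
#' every row would have minimum cell 0; path-exhausted tables with all cells
#' positive show it is not.
#'
#' @param records an \code{"fi_enum"} object or its \code{records} data
#'   frame.
#' @return a data frame with columns \code{min_cell}, \code{count},
#'   \code{percent} (percentages of all unattainable tables).
#' @export
min_cell_tally <- function(records) {
  rec <- .as_records(records)
  un <- rec[rec$status == "not_attainable", , drop = FALSE]
  if (nrow(un) == 0L)
    return(data.frame(min_cell = integer(), count = integer(),
                      percent = numeric()))
  tab <- table(un$min_cell)
  data.frame(min_cell = as.integer(names(tab)),
             count = as.integer(tab),
             percent = 100 * as.integer(tab) / nrow(un))
}

#' Mechanism tally of unattainable tables
#'
#' Counts the two mechanisms of nonattainability: \code{no_legal_move} (the
#' selected arm already has zero nonevents at baseline) and
#' \code{path_exhausted} (legal toggles existed but the p-value never
#' reached the nonsignificance boundary before the arm was exhausted). The
#' two counts always sum to the total number of unattainable tables.
#'
#' @inheritParams min_cell_tally
#' @return a named integer vector with elements \code{no_legal_move} and
#'   \code{path_exhausted}.
#' @export
mechanism_tally <- function(records) {
  rec <- .as_records(records)
  un <- rec[rec$status == "not_attainable", , drop = FALSE]
  c(no_legal_move = sum(un$mechanism == "no_legal_move"),
    path_exhausted = sum(un$mechanism == "path_exhausted"))
}

#' @export
print.fi_enum <- function(x, ...) {
  cat(sprintf("Fragility-index enumeration, N = %d..%d, alpha = %s\n",
              x$n_min, x$n_max, format(x$alpha)))
  tot <- colSums(x$summary[c("total_significant", "fi_attainable",
                             "fi_unattainable", "ties_excluded")])
  ev <- tot[["fi_attainable"]] + tot[["fi_unattainable"]]
  cat(sprintf("  %d baseline-significant tables (%d evaluable, %d tied-excluded)\n",
              tot[["total_significant"]], ev, tot[["ties_excluded"]]))
  cat(sprintf("  FI unattainable: %d of %d evaluable (%.1f%%)\n",
              tot[["fi_unattainable"]], ev,
              100 * tot[["fi_unattainable"]] / ev))
  first <- x$summary$n_total[x$summary$fi_unattainable > 0]
  if (length(first))
    cat(sprintf("  first unattainable case at N = %d\n", min(first)))
  invisible(x)
}

#' @export
summary.fi_enum <- function(object, ...) {
  df <- object$summary
  df$unattainability_rate <- sprintf(
    "%.1f%%", 100 * df$unattainability_rate)
  df
}

#' @export
plot.fi_enum <- function(x, ...) {
  s <- x$summary
  plot(s$n_total, 100 * s$unattainability_rate, type = "b", pch = 19,
       xlab = "total sample size N",
       ylab = "unattainability rate (%)",
       main = "FI unattainability by sample size", ...)
  invisible(x)
}
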