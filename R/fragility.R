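#' Evaluability of a table for the fragility-index algorithm
#'
#' The original fragility index is defined only for nondegenerate,
#' baseline-significant tables with untied event counts. This classifies any
#' table into one of four states, checked in order: \code{"degenerate"} (an
#' empty arm or outcome column), \code{"not_significant"} (baseline two-sided
#' Fisher p >= alpha), \code{"tied_events"} (a == c; the definition names
#' "the arm with fewer events" and provides no tie-break), or
#' \code{"evaluable"}.
#'
#' @inheritParams as_ct
#' @param alpha significance level; the baseline table must have two-sided
#'   Fisher p strictly below \code{alpha}. Default 0.05.
#' @return one of \code{"evaluable"}, \code{"degenerate"},
#'   \code{"not_significant"}, \code{"tied_events"}.
#' @examples
#' evaluability(c(3, 0, 4, 11)) # "evaluable"
#' evaluability(c(1, 1, 1, 1)) # "not_significant"
#' evaluability(c(5, 0, 5, 10)) # "tied_events"
#' @export
evaluability <- function(x, b = NULL, c = NULL, d = NULL, alpha = 0.05) {
  ct <- as_ct(x, b, c, d)
  if (!is.null(.degenerate_margin(ct))) return("degenerate")
  if (!.ct_lt_alpha(ct, two_sided_p(ct)$p_two_sided, alpha))
    return("not_significant")
  if (ct[["a"]] == ct[["c"]]) return("tied_events")
  "evaluable"
}

#' Select the toggling arm
#'
#' The arm with fewer events at baseline. Selection is made once and never
#' re-evaluated along the toggle path, so the selected arm keeps being
#' toggled even if its event count overtakes the other arm's.
#'
#' @inheritParams as_ct
#' @return \code{"A"}, \code{"B"}, or \code{"tied"} (when a == c).
#' @examples
#' select_arm(c(3, 0, 4, 11)) # "A"
#' select_arm(c(9, 35, 8, 8)) # "B"
#' @export
select_arm <- function(x, b = NULL, c = NULL, d = NULL) {
  ct <- as_ct(x, b, c, d)
  if (ct[["a"]] < ct[["c"]]) "A" else if (ct[["c"]] < ct[["a"]]) "B" else "tied"
}

#' Apply one fragility toggle
#'
#' Converts one nonevent to an event in the selected arm, preserving the arm
#' total (events + 1, nonevents - 1). The only move the original algorithm
#' permits.
#'
#' @param x a contingency table accepted by [as_ct()].
#' @param arm \code{"A"} or \code{"B"}.
#' @return the toggled table as a named integer vector.
#' @examples
#' toggle(c(9, 35, 8, 8), "B") # {9, 35, 9, 7}
#' @export
toggle <- function(x, arm) {
  ct <- as_ct(x)
  arm <- match.arg(arm, c("A", "B"))
  ev <- if (arm == "A") "a" else "c"
  ne <- if (arm == "A") "b" else "d"
  if (ct[[ne]] < 1L)
    stop("no legal move: arm ", arm, " has zero nonevents")
  ct[ev] <- ct[ev] + 1L
  ct[ne] <- ct[ne] - 1L
  ct
}

#' Fragility index with attainability classification
#'
#' Runs the original fragility-index algorithm on a 2x2 table: require
#' baseline significance (two-sided Fisher exact p < \code{alpha}), select
#' the arm with fewer events, then repeatedly convert one nonevent to an
#' event in that arm (arm size fixed), recomputing the two-sided p after
#' each step. The fragility index (FI) is the minimum number of such changes
#' that makes the result nonsignificant (p >= \code{alpha}).
#'
#' Unlike calculators that fail with a generic error, every input gets a
#' named outcome:
#' \describe{
#'   \item{\code{attainable}}{a finite FI exists; \code{fi} holds it.}
#'   \item{\code{not_attainable}}{no finite FI exists, with the mechanism:
#'     \code{"no_legal_move"} (the selected arm has zero nonevents at
#'     baseline, so the algorithm cannot begin) or \code{"path_exhausted"}
#'     (toggles were legal but the arm ran out of nonevents with every p
#'     still below \code{alpha}).}
#'   \item{\code{not_evaluable}}{the algorithm does not apply, with the
#'     reason: \code{"degenerate"}, \code{"not_significant"}, or
#'     \code{"tied_events"}.}
#' }
#'
#' @inheritParams as_ct
#' @param alpha significance level, default 0.05.
#' @return an object of class \code{"fragility"}: a list with
#'   \code{table}, \code{alpha}, \code{status}, \code{fi}, \code{mechanism},
#'   \code{reason}, \code{arm}, \code{p_baseline}, and \code{trajectory}
#'   (a data frame with one row per visited table: \code{step, a, b, c, d,
#'   p}; the baseline is step 0).
#' @examples
#' fragility(c(3, 0, 4, 11)) # not attainable, no legal move
#' fragility(c(9, 35, 8, 8)) # not attainable, path exhausted after 8 toggles
#' fragility(c(10, 40, 25, 25)) # attainable
#' @export
fragility <- function(x, b = NULL, c = NULL, d = NULL, alpha = 0.05) {
  ct <- as_ct(x, b, c, d)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  degen <- !is.null(.degenerate_margin(ct))
  p0 <- if (degen) NA_real_ else two_sided_p(ct)$p_two_sided

  out <- list(table = ct, alpha = alpha, status = NA_character_,
              fi = NA_integer_, mechanism = NA_character_,
              reason = NA_character_, arm = NA_character_,
              p_baseline = p0, trajectory = NULL)
  class(out) <- "fragility"

  traj <- list(c(step = 0, ct, p = p0))
  reason <- if (degen) "degenerate"
            else if (!.ct_lt_alpha(ct, p0, alpha)) "not_significant"
            else if (ct[["a"]] == ct[["c"]]) "tied_events"
            else NA_character_
  if (!is.na(reason)) {
    out$status <- "not_evaluable"
    out$reason <- reason
    out$trajectory <- .traj_df(traj)
    return(out)
  }

  arm <- select_arm(ct)
  out$arm <- arm
  ne <- if (arm == "A") "b" else "d"
  r1 <- ct[["a"]] + ct[["b"]]
  r2 <- ct[["c"]] + ct[["d"]]
  cur <- ct
  steps <- 0L
  repeat {
    if (cur[[ne]] == 0L) {
      out$status <- "not_attainable"
      out$mechanism <- if (steps == 0L) "no_legal_move" else "path_exhausted"
      break
    }
    cur <- toggle(cur, arm)
    steps <- steps + 1L
    # the path kernel is used directly: a toggled table may legitimately
    # empty the nonevent column (all subjects events), where p = 1
    p <- .two_sided_one(r1, r2, cur[["a"]] + cur[["c"]], cur[["a"]])$p_two
    traj[[steps + 1L]] <- c(step = steps, cur, p = p)
    if (!.lt_alpha(p, r1, r2, cur[["a"]] + cur[["c"]], cur[["a"]], alpha)) {
      out$status <- "attainable"
      out$fi <- steps
      break
    }
  }
  out$trajectory <- .traj_df(traj)
  out
}

.traj_df <- function(traj) {
  m <- do.call(rbind, traj)
  df <- as.data.frame(m)
  df$step <- as.integer(df$step)
  for (nm in c("a", "b", "c", "d")) df[[nm]] <- as.integer(df[[nm]])
  rownames(df) <- NULL
  df
}

#' @export
print.fragility <- function(x, ...) {
  cat(sprintf("Fragility index (original algorithm, alpha = %s)\n",
              format(x$alpha)))
  cat(sprintf("  table {a,b,c,d} = {%s}   N = %d\n",
              paste(x$table, collapse = ", "), sum(x$table)))
  if (!is.na(x$p_baseline))
    cat(sprintf("  baseline two-sided Fisher p = %.4f\n", x$p_baseline))
  switch(x$status,
    attainable = cat(sprintf("  status: ATTAINABLE, FI = %d\n", x$fi)),
    not_attainable = cat(sprintf(
      "  status: NOT ATTAINABLE (%s)\n",
      if (x$mechanism == "no_legal_move")
        sprintf("no legal move: arm %s has zero nonevents at baseline", x$arm)
      else
        sprintf("path exhausted: arm %s ran out of nonevents after %d toggle%s with p still < %s",
                x$arm, nrow(x$trajectory) - 1L,
                if (nrow(x$trajectory) == 2L) "" else "s",
                format(x$alpha)))),
    not_evaluable = cat(sprintf("  status: NOT EVALUABLE (%s)\n", x$reason)))
  invisible(x)
}

#' @export
summary.fragility <- function(object, ...) {
  structure(object, class = c("summary.fragility", "fragility"))
}

#' @export
print.summary.fragility <- function(x, ...) {
  NextMethod()
  n <- nrow(x$trajectory)
  cat("  toggle trajectory (", n - 1L, " toggle",
      if (n == 2L) "" else "s", "):\n", sep = "")
  tr <- x$trajectory
  show <- if (n > 12L) c(1:6, NA, (n - 4L):n) else seq_len(n)
  for (i in show) {
    if (is.na(i)) { cat("    ...\n"); next }
    cat(sprintf("    %s {%d,%d,%d,%d}  p = %.4f\n",
                if (tr$step[i] == 0L) "baseline" else
                  sprintf("toggle %2d", tr$step[i]),
                tr$a[i], tr$b[i], tr$c[i], tr$d[i], tr$p[i]))
  }
  invisible(x)
}

#' @export
plot.fragility <- function(x, ...) {
  tr <- x$trajectory
  if (all(is.na(tr$p))) stop("nothing to plot: degenerate table")
  plot(tr$step, tr$p, type = "b", pch = 19, log = "y",
       xlab = "toggle", ylab = "two-sided Fisher p (log scale)",
       main = sprintf("FI toggle path, arm %s",
                      if (is.na(x$arm)) "-" else x$arm), ...)
  abline(h = x$alpha, lty = 2)
  invisible(x)
}
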