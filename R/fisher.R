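# Cached cumulative log-factorial table. Grown monotonically; growth never
# changes previously returned values, so memoized and unmemoized paths agree
# bit-for-bit.
.lfac_env <- new.env(parent = emptyenv())
.lfac_env$tab <- 0 # log(0!)

.lfac_grow <- function(nmax) {
  have <- length(.lfac_env$tab) - 1L
  if (nmax > have) {
    .lfac_env$tab <- c(.lfac_env$tab,
                       .lfac_env$tab[have + 1L] +
                         cumsum(log(seq.int(have + 1L, nmax))))
  }
  invisible(NULL)
}

# log(n!) for vector n >= 0
.lfac <- function(n) {
  .lfac_grow(max(n))
  .lfac_env$tab[n + 1L]
}

# log choose(n, k), vectorised, via the cached table
.lchoose2 <- function(n, k) {
  .lfac(n) - .lfac(k) - .lfac(n - k)
}

# Relative tolerance used when deciding whether a support table's point
# probability "does not exceed" the observed one. Guards against floating
# ties; the convention shared by mainstream exact-test implementations.
.fisher_rel_tol <- 1e-7

#' Coerce and validate a 2x2 contingency table
#'
#' Accepts a length-4 numeric vector \code{c(a, b, c, d)}, a 2x2 matrix
#' (rows = arms, columns = events/nonevents), or four scalar arguments, and
#' returns a validated named integer vector. The cell layout is the standard
#' \code{{a, b, c, d}} nomenclature: \code{a} = events in arm A, \code{b} =
#' nonevents in arm A, \code{c} = events in arm B, \code{d} = nonevents in
#' arm B.
#'
#' @param x a length-4 vector, a 2x2 matrix, or the \code{a} cell when
#'   \code{b}, \code{c}, \code{d} are given separately.
#' @param b,c,d optional remaining cells when given as scalars.
#' @return named integer vector \code{c(a =, b =, c =, d =)}.
#' @examples
#' as_ct(c(3, 0, 4, 11))
#' as_ct(matrix(c(3, 0, 4, 11), nrow = 2, byrow = TRUE))
#' @export
as_ct <- function(x, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) x <- c(x, b, c, d)
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L)))
      stop("matrix input must be 2x2 (rows = arms, columns = outcome)")
    x <- as.vector(t(x))
  }
  if (length(x) != 4L)
    stop("a contingency table needs exactly 4 cells {a, b, c, d}")
  if (anyNA(x) || !is.numeric(x))
    stop("cells must be non-missing numbers")
  if (any(x < 0) || any(x != round(x)))
    stop("cells must be nonnegative integers")
  if (sum(x) < 1)
    stop("total sample size must be at least 1")
  x <- as.integer(round(x))
  names(x) <- c("a", "b", "c", "d")
  x
}

# Check margins; returns NULL if nondegenerate, otherwise the name of the
# first empty margin.
.degenerate_margin <- function(ct) {
  if (ct[["a"]] + ct[["b"]] == 0L) return("arm A is empty (a + b = 0)")
  if (ct[["c"]] + ct[["d"]] == 0L) return("arm B is empty (c + d = 0)")
  if (ct[["a"]] + ct[["c"]] == 0L) return("event column is empty (a + c = 0)")
  if (ct[["b"]] + ct[["d"]] == 0L) return("nonevent column is empty (b + d = 0)")
  NULL
}

.stop_if_degenerate <- function(ct) {
  m <- .degenerate_margin(ct)
  if (!is.null(m)) stop("degenerate table: ", m)
  invisible(NULL)
}

#' Hypergeometric point probability of a 2x2 table
#'
#' Probability of the observed table under the hypergeometric null with all
#' margins fixed: \code{C(a+b, a) * C(c+d, c) / C(N, a+c)}, computed in log
#' space with cached log-factorials.
#'
#' @inheritParams as_ct
#' @return the point probability, a double in \code{[0, 1]}.
#' @examples
#' point_probability(c(1, 1, 1, 1)) # 4/6
#' point_probability(c(3, 0, 4, 11)) # 1365/31824
#' @seealso [two_sided_p()]
#' @export
point_probability <- function(x, b = NULL, c = NULL, d = NULL) {
  ct <- as_ct(x, b, c, d)
  .stop_if_degenerate(ct)
  r1 <- ct[["a"]] + ct[["b"]]
  k <- ct[["a"]] + ct[["c"]]
  n <- sum(ct)
  exp(.lchoose2(r1, ct[["a"]]) + .lchoose2(n - r1, k - ct[["a"]]) -
        .lchoose2(n, k))
}

# Hypergeometric point masses over the support of one margin set, in the
# numerical convention of the classical two-sided exact test: log point
# masses are shifted by their maximum, exponentiated, and normalized to sum
# to 1. r1 = arm A size, r2 = arm B size, k = total events; the support is
# the range of a (events in arm A). The normalization pins down the
# floating-point behaviour at knife-edge tables whose exact p equals alpha,
# so significance classifications agree bit-for-bit with the reference
# convention.
.dnhyper <- function(r1, r2, k) {
  lo <- max(0L, k - r2)
  hi <- min(k, r1)
  xs <- lo:hi
  logdc <- stats::dhyper(xs, k, r1 + r2 - k, r1, log = TRUE)
  d <- exp(logdc - max(logdc))
  list(a = xs, d = d / sum(d))
}

# Two-sided p for one observed table: sum, in support order, of the point
# masses that do not exceed the observed one (relative tolerance). O(support).
.two_sided_one <- function(r1, r2, k, aobs) {
  s <- .dnhyper(r1, r2, k)
  i <- aobs - s$a[1L] + 1L
  list(p_two = min(1, sum(s$d[s$d <= s$d[i] * (1 + .fisher_rel_tol)])),
       p_point = s$d[i])
}

# Two-sided p-values for every table in the support of one margin set, each
# summed exactly as .two_sided_one would. Used by the enumeration cache:
# one call per margin signature covers all tables and toggle steps that
# share it.
.support_p <- function(r1, r2, k) {
  s <- .dnhyper(r1, r2, k)
  thr <- s$d * (1 + .fisher_rel_tol)
  p2 <- vapply(thr, function(t) sum(s$d[s$d <= t]), 0)
  list(a = s$a, p_point = s$d, p_two = pmin(1, p2))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric point probabilities,
#' over all tables sharing the observed margins, that do not exceed the
#' observed table's point probability (relative tolerance 1e-7). This is the
#' classical two-sided convention; p-values are returned at full double
#' precision and rounded only for display.
#'
#' @inheritParams as_ct
#' @return a list of class \code{"fisher2x2"} with components
#'   \code{p_two_sided} and \code{p_point}.
#' @examples
#' two_sided_p(c(3, 0, 4, 11)) # p = 0.0429
#' two_sided_p(c(9, 35, 8, 8)) # p = 0.0487
#' @export
two_sided_p <- function(x, b = NULL, c = NULL, d = NULL) {
  ct <- as_ct(x, b, c, d)
  .stop_if_degenerate(ct)
  r1 <- ct[["a"]] + ct[["b"]]
  r2 <- ct[["c"]] + ct[["d"]]
  k <- ct[["a"]] + ct[["c"]]
  s <- .two_sided_one(r1, r2, k, ct[["a"]])
  structure(list(p_two_sided = s$p_two, p_point = s$p_point, table = ct),
            class = "fisher2x2")
}

#' @export
print.fisher2x2 <- function(x, ...) {
  cat("Two-sided Fisher exact test\n")
  cat(sprintf("  table {a,b,c,d} = {%s}\n",
              paste(x$table, collapse = ", ")))
  cat(sprintf("  p (two-sided) = %.4f\n", x$p_two_sided))
  cat(sprintf("  point probability = %.4g\n", x$p_point))
  invisible(x)
}
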