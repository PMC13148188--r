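#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Spearman's r with midrank handling of ties (ranks via [base::rank()]
#' averaging, correlation via [stats::cor()]), and a confidence interval
#' from the Fisher z-transform with standard error \code{1/sqrt(n - 3)}.
#'
#' @param x,y numeric vectors of equal length >= 4, neither constant.
#' @param conf confidence level, default 0.95.
#' @return a list of class \code{"fi_assoc"}: \code{r}, \code{ci_low},
#'   \code{ci_high}, \code{n}, \code{conf}.
#' @examples
#' spearman_ci(1:10, (1:10)^3) # r = 1, monotone-invariant
#' @export
spearman_ci <- function(x, y, conf = 0.95) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain missing values")
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (min(x) == max(x)) stop("x is constant; correlation undefined")
  if (min(y) == max(y)) stop("y is constant; correlation undefined")
  stopifnot(is.numeric(conf), length(conf) == 1L, conf > 0, conf < 1)
  r <- stats::cor(x, y, method = "spearman")
  z <- atanh(min(1 - 1e-15, max(-1 + 1e-15, r)))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(r = r, ci_low = tanh(z - q * se),
                 ci_high = tanh(z + q * se), n = n, conf = conf),
            class = "fi_assoc")
}

#' @export
print.fi_assoc <- function(x, ...) {
  cat(sprintf("Spearman r = %.3f, %d%% CI %.3f-%.3f (n = %d)\n",
              x$r, round(100 * x$conf), x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Predictors of fragility-index nonattainability
#'
#' Spearman rank correlations, with the individual table as the unit of
#' analysis, between the binary nonattainability indicator (1 = FI not
#' attainable) and two structural predictors: allocation imbalance (ratio of
#' the larger to the smaller arm size, so the predictor is orientation-free)
#' and total sample size. Only evaluable tables (attainable or unattainable;
#' tied-event exclusions dropped) enter the correlation.
#'
#' @param records an \code{"fi_enum"} object or its \code{records} data
#'   frame, from [fragility_enumeration()].
#' @param conf confidence level for the Fisher-z intervals, default 0.95.
#' @return a list of class \code{"fi_assoc_set"} with components
#'   \code{imbalance} and \code{n_total}, each an \code{"fi_assoc"} result,
#'   plus \code{scope = "evaluable"}.
#' @examples
#' e <- fragility_enumeration(2, 20)
#' predictor_correlations(e)
#' @export
predictor_correlations <- function(records, conf = 0.95) {
  rec <- .as_records(records)
  ev <- rec[rec$status %in% c("attainable", "not_attainable"), , drop = FALSE]
  if (nrow(ev) == 0L) stop("no evaluable records")
  y <- as.integer(ev$status == "not_attainable")
  if (min(y) == max(y))
    stop("nonattainability indicator is constant across evaluable records; ",
         "correlation undefined")
  structure(list(
    imbalance = spearman_ci(ev$imbalance_ratio, y, conf),
    n_total = spearman_ci(ev$n_total, y, conf),
    scope = "evaluable"),
    class = "fi_assoc_set")
}

#' @export
print.fi_assoc_set <- function(x, ...) {
  cat("Predictors of FI nonattainability (evaluable tables only)\n")
  cat("  allocation imbalance: "); print(x$imbalance)
  cat("  total sample size:    "); print(x$n_total)
  invisible(x)
}

#' Write an association report as JSON
#'
#' @param assoc an \code{"fi_assoc_set"} from [predictor_correlations()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_association_json <- function(assoc, path) {
  stopifnot(inherits(assoc, "fi_assoc_set"))
  rows <- lapply(c(imbalance = "imbalance", n_total = "n_total"),
                 function(k) {
    a <- assoc[[k]]
    list(predictor = k, r = a$r, ci_low = a$ci_low, ci_high = a$ci_high,
         n = a$n, scope = assoc$scope)
  })
  jsonlite::write_json(unname(rows), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
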