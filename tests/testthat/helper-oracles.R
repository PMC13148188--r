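# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct binomial-coefficient arithmetic for the
# exact test, and a literal step-by-step replay of the toggle algorithm.

# Naive two-sided Fisher p: enumerate the full hypergeometric support with
# base-R choose() and sum the qualifying point probabilities. Exact-integer
# arithmetic up to N ~ 25, so a trustworthy reference at small N.
oracle_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- a + b + c + d
  xs <- max(0, k - r2):min(k, r1)
  pr <- choose(r1, xs) * choose(r2, k - xs) / choose(n, k)
  po <- pr[xs == a]
  sum(pr[pr <= po * (1 + 1e-7)])
}

# Literal replay of the original FI algorithm, written independently of
# fragility(): arm chosen once at baseline, one nonevent converted per step,
# p recomputed each time. p-values come from the supplied function so the
# replay can be paired with either the package engine or the naive oracle.
oracle_fi <- function(a, b, c, d, alpha = 0.05, pfun = oracle_two_sided) {
  p <- pfun(a, b, c, d)
  if (p >= alpha) return(list(status = "not_evaluable"))
  if (a == c) return(list(status = "not_evaluable"))
  arm_a <- a < c # arm chosen once at baseline, never re-evaluated
  steps <- 0L
  repeat {
    if (arm_a) {
      if (b == 0L)
        return(list(status = "not_attainable",
                    mechanism = if (steps == 0L) "no_legal_move"
                                else "path_exhausted",
                    steps = steps))
      a <- a + 1L; b <- b - 1L
    } else {
      if (d == 0L)
        return(list(status = "not_attainable",
                    mechanism = if (steps == 0L) "no_legal_move"
                                else "path_exhausted",
                    steps = steps))
      c <- c + 1L; d <- d - 1L
    }
    steps <- steps + 1L
    if (pfun(a, b, c, d) >= alpha)
      return(list(status = "attainable", fi = steps))
  }
}

# Midrank assignment by first principles: rank = mean position of the tied
# block in the sorted order.
oracle_midrank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}
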