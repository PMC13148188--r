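# Exact arbitration of boundary significance decisions.
#
# The enumeration space contains tables whose two-sided Fisher p equals the
# significance level exactly as a rational number (e.g. p = 1/20 at
# alpha = 0.05); double-precision kernels land on either side of the
# boundary depending on platform rounding. Whenever a computed p falls
# within .sig_eps of alpha, the comparison p < alpha is re-decided in exact
# integer arithmetic: the two-sided p is the rational
#   S / C(N, k),  S = sum of C(r1, x) C(r2, k - x) over qualifying x,
# and alpha is interpreted as the decimal fraction the user wrote (up to 6
# decimal places), so p < alpha  <=>  S * 10^6 < A * C(N, k) with
# A = alpha * 10^6. Counts then do not depend on the platform's libm.
#
# Big integers are little-endian limb vectors in base 1e7 (doubles hold
# limb products exactly). Only boundary tables ever reach this code.

.sig_eps <- 1e-10
.bg_base <- 1e7

# carry-propagate a limb vector whose entries may exceed the base
.bg_carry <- function(v) {
  repeat {
    carry <- floor(v / .bg_base)
    if (all(carry == 0)) break
    v <- v - carry * .bg_base
    if (length(v) < length(carry) + 1L)
      v <- c(v, numeric(length(carry) + 1L - length(v)))
    idx <- seq_along(carry) + 1L
    v[idx] <- v[idx] + carry
  }
  while (length(v) > 1L && v[length(v)] == 0) v <- v[-length(v)]
  v
}

.bg_add <- function(a, b) {
  n <- max(length(a), length(b))
  .bg_carry(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# a * s for small integer s (s * base must stay exact in doubles: s <= 1e7)
.bg_mul_small <- function(a, s) {
  stopifnot(s >= 0, s <= .bg_base)
  .bg_carry(a * s)
}

# exact short division by small s; errors if not divisible
.bg_div_small <- function(a, s) {
  q <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    cur <- rem * .bg_base + a[i]
    q[i] <- floor(cur / s)
    rem <- cur - q[i] * s
  }
  if (rem != 0) stop("non-exact big-integer division")
  while (length(q) > 1L && q[length(q)] == 0) q <- q[-length(q)]
  q
}

.bg_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(b)) {
    if (b[i] == 0) next
    idx <- seq_along(a) + i - 1L
    res[idx] <- res[idx] + a * b[i]
    # carry each round so partial sums stay well below 2^53
    carry <- floor(res / .bg_base)
    while (any(carry != 0)) {
      res <- res - carry * .bg_base
      res[seq_along(carry)[-1L]] <- res[seq_along(carry)[-1L]] +
        carry[-length(carry)]
      carry <- floor(res / .bg_base)
    }
  }
  while (length(res) > 1L && res[length(res)] == 0) res <- res[-length(res)]
  res
}

# -1, 0, 1 for a < b, a == b, a > b
.bg_cmp <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

# exact C(n, k) as a big integer (multiplicative formula; every
# intermediate quotient is integral)
.bg_choose <- function(n, k) {
  k <- min(k, n - k)
  if (k < 0) return(0)
  res <- 1
  if (k == 0) return(res)
  for (i in seq_len(k)) {
    res <- .bg_mul_small(res, n - k + i)
    res <- .bg_div_small(res, i)
  }
  res
}

# Exact decision of "two-sided p < alpha" for the table with margins
# (r1, r2, k) and observed a. Returns NA when alpha is not a 6-decimal
# fraction (caller falls back to the floating comparison).
.exact_p_lt_alpha <- function(r1, r2, k, a, alpha) {
  A <- round(alpha * 1e6)
  if (abs(alpha * 1e6 - A) > 1e-9) return(NA)
  lo <- max(0L, k - r2)
  hi <- min(k, r1)
  xs <- lo:hi
  W <- lapply(xs, function(x) .bg_mul(.bg_choose(r1, x), .bg_choose(r2, k - x)))
  Wobs <- W[[a - lo + 1L]]
  S <- 0
  for (i in seq_along(xs)) {
    if (.bg_cmp(W[[i]], Wobs) <= 0) S <- .bg_add(S, W[[i]])
  }
  lhs <- .bg_mul_small(S, 1e6)
  rhs <- .bg_mul_small(.bg_choose(r1 + r2, k), A)
  .bg_cmp(lhs, rhs) < 0
}

# "p < alpha" with exact arbitration at the boundary. p is the float
# two-sided p already computed for the table (r1, r2, k, a).
.lt_alpha <- function(p, r1, r2, k, a, alpha) {
  if (abs(p - alpha) > .sig_eps) return(p < alpha)
  ex <- .exact_p_lt_alpha(r1, r2, k, a, alpha)
  if (is.na(ex)) p < alpha else ex
}

# same, taking a validated table
.ct_lt_alpha <- function(ct, p, alpha) {
  .lt_alpha(p, ct[["a"]] + ct[["b"]], ct[["c"]] + ct[["d"]],
            ct[["a"]] + ct[["c"]], ct[["a"]], alpha)
}
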