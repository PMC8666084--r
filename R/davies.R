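# Tail probability of a weighted sum of independent chi-square(1) variables
# by numerical inversion of the characteristic function (Gil-Pelaez / Imhof
# form). With Q = sum_r lambda_r X_r, X_r ~ chi2_1,
#
#   P(Q >= q) = 1/2 + (1/pi) * Int_0^inf sin(theta(u)) / (u * rho(u)) du
#   theta(u) = (1/2) sum_r atan(lambda_r u) - q u / 2
#   rho(u)   = prod_r (1 + lambda_r^2 u^2)^(1/4)
#
# theta is concave on u >= 0 (its derivative is strictly decreasing), so
# the integrand's sign structure is known: theta rises to a single maximum,
# then decreases to -infinity with asymptotic slope -q/2. The integral is
# evaluated lobe-by-lobe between consecutive zeros of sin(theta); the
# eventual alternating lobe series is summed with repeated averaging
# (Euler transformation), which converges to machine precision even for
# the slowly decaying single-weight case.

davies_pvalue <- function(q, lambda, accuracy = 1e-9, max_lobes = 300L) {
  if (!is.finite(q)) stop("non-finite Q statistic", call. = FALSE)
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0L) return(list(p = 1, ifault = 0L))
  if (q <= 0) return(list(p = 1, ifault = 0L))

  theta <- function(u) 0.5 * sum(atan(lambda * u)) - 0.5 * q * u
  dtheta <- function(u) 0.5 * sum(lambda / (1 + (lambda * u)^2)) - 0.5 * q
  f <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(th) / (u * rho)
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  lobe_int <- function(lo, hi) {
    stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = accuracy * 1e-3,
                     subdivisions = 200L, stop.on.error = FALSE)$value
  }
  # next u > lo with theta(u) == lv, searching outward from lo in steps
  cross_down <- function(lo, lv, step) {
    hi <- lo + step
    it <- 0L
    while (theta(hi) > lv) {
      hi <- hi + step
      step <- step * 2
      if ((it <- it + 1L) > 200L) return(NA_real_)
    }
    stats::uniroot(function(u) theta(u) - lv, c(lo, hi),
                   tol = .Machine$double.eps^0.75)$root
  }

  lob <- numeric(0)
  lo <- 0
  nlev <- 0L
  if (dtheta(0) > 0) {
    # phase rises first: lobes on the ascending branch up to the maximum
    hi <- 1 / max(lambda)
    it <- 0L
    while (dtheta(hi) > 0) {
      hi <- hi * 2
      if ((it <- it + 1L) > 200L) return(list(p = NA_real_, ifault = 1L))
    }
    ustar <- stats::uniroot(dtheta, c(0, hi), tol = .Machine$double.eps^0.75)$root
    nlev <- floor(theta(ustar) / pi)
    if (nlev >= 1L) for (nn in seq_len(nlev)) {
      b <- stats::uniroot(function(u) theta(u) - nn * pi, c(lo, ustar),
                          tol = .Machine$double.eps^0.75)$root
      lob <- c(lob, lobe_int(lo, b))
      lo <- b
    }
    # bridge lobe over the maximum down to level nlev*pi on the far side
    b <- cross_down(ustar, nlev * pi, max(ustar, pi / q))
    if (is.na(b)) return(list(p = NA_real_, ifault = 1L))
    lob <- c(lob, lobe_int(lo, b))
    lo <- b
  }
  # descending branch: levels (nlev - 1) pi, (nlev - 2) pi, ...
  step <- pi / q
  small <- 0L
  for (nn in seq_len(max_lobes)) {
    b <- cross_down(lo, (nlev - nn) * pi, step)
    if (is.na(b)) return(list(p = NA_real_, ifault = 1L))
    li <- lobe_int(lo, b)
    lob <- c(lob, li)
    step <- max(b - lo, pi / q)
    lo <- b
    small <- if (abs(li) < accuracy * 1e-4) small + 1L else 0L
    if (nn >= 48L && small >= 3L) break
  }
  if (any(!is.finite(lob)) || length(lob) < 8L)
    return(list(p = NA_real_, ifault = 2L))

  # Euler transformation of the alternating tail of partial sums
  ps <- cumsum(lob)
  n0 <- max(1L, length(ps) - 60L)
  s <- ps[n0:length(ps)]
  while (length(s) > 1L) s <- (s[-1L] + s[-length(s)]) / 2
  p <- 0.5 + s / pi
  if (!is.finite(p)) return(list(p = NA_real_, ifault = 2L))
  list(p = p, ifault = 0L)
}

# Moment-matching (Liu-type) approximation to the same tail probability:
# match mean, variance and skewness (or kurtosis when skewness matching is
# infeasible) of Q to a scaled non-central chi-square.
liu_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0L || q <= 0) return(1)
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  muX <- l + d; sigmaX <- sqrt(2) * a
  tstar <- (q - muQ) / sigmaQ
  stats::pchisq(tstar * sigmaX + muX, df = l, ncp = d, lower.tail = FALSE)
}
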