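#' Tail probability of a positive linear combination of chi-square variables
#'
#' Computes \eqn{P(Q > q)} where \eqn{Q = \sum_j \lambda_j \chi^2_{1,j}} with
#' independent one-degree-of-freedom chi-square components. This is the null
#' distribution of score-based quadratic forms (SKAT-type statistics) when the
#' summary z-scores are multivariate normal with a known LD correlation
#' matrix. The default method numerically inverts the characteristic function
#' (Imhof's formula); if the integral fails to converge the moment-matching
#' approximation of Liu et al. is used instead.
#'
#' @param q observed statistic (scalar, non-negative).
#' @param lambda positive mixture weights (eigenvalues of the weighted LD
#'   kernel). Weights below `tol * max(lambda)` are dropped.
#' @param acc target absolute accuracy of the numerical inversion.
#' @param tol relative eigenvalue cutoff.
#' @return A list with `p` (the upper-tail probability, clamped to
#'   `(1e-320, 1]`) and `method` (`"imhof"` or `"liu"`).
#' @export
qform_pvalue <- function(q, lambda, acc = 1e-9, tol = 1e-10) {
  lambda <- lambda[lambda > tol * max(lambda)]
  if (length(lambda) == 0L) stop("all mixture weights are numerically zero")
  if (q <= 0) return(list(p = 1, method = "exact"))
  if (length(lambda) == 1L) {
    return(list(p = stats::pchisq(q / lambda, df = 1, lower.tail = FALSE),
                method = "exact"))
  }
  # cheap moment-matched bracket first: near p = 1 the inversion adds
  # nothing, and far below the fallback threshold it would be discarded
  p_liu <- liu_tail(q, lambda)
  if (p_liu > 0.9 || p_liu < 1e-10) return(list(p = p_liu, method = "liu"))
  p <- tryCatch(imhof_tail(q, lambda, acc = acc), error = function(e) NA_real_)
  # below ~1e-8 the inversion integral approaches its double-precision
  # cancellation floor; moment matching takes over (as Davies
  # implementations do for their smallest returns)
  if (is.na(p) || p < 1e-8 || p > 1 + acc) {
    return(list(p = liu_tail(q, lambda), method = "liu"))
  }
  list(p = min(p, 1), method = "imhof")
}

# Imhof (1961) inversion integral for P(Q > q). The slowly decaying
# oscillatory integrand defeats generic adaptive quadrature on an infinite
# domain, so the integral is evaluated by composite Simpson quadrature on
# [0, U] (step resolving both the oscillation period 4*pi/q and the
# arctangent scale 1/max(lambda)) plus a one-step integration-by-parts
# correction for the tail beyond U, whose error is O(U^-(k/2+2)/q^2).
imhof_tail <- function(q, lambda, acc = 1e-9) {
  k <- length(lambda)
  theta_fun <- function(u) {
    m <- length(u)
    0.5 * .colSums(atan(lambda %o% u), k, m) - 0.5 * q * u
  }
  g_fun <- function(u) {
    m <- length(u)
    lu <- lambda %o% u
    exp(-(log(u) + 0.25 * .colSums(log1p(lu * lu), k, m)))
  }

  log_pl <- 0.5 * sum(log(lambda))
  # truncation point from the error bound of the tail correction,
  # ~ (m+1) * 4/q^2 * U^-(m+1) / (pi * prod sqrt(lambda)), m = 1 + k/2
  m <- 1 + k / 2
  log_c2 <- log(m + 1) + log(4) - 2 * log(q) - log_pl - log(pi)
  U <- exp((log_c2 - log(acc)) / (m + 1))
  U <- min(max(U, 24 * pi / q, 10), 3000)
  du <- min(4 * pi / q / 120, 0.25 / max(lambda), U / 1000)
  n <- ceiling(U / du)
  n <- min(n + (n %% 2L == 1L), 2e6L)  # even interval count for Simpson
  u <- seq(0, U, length.out = n + 1L)

  vals <- numeric(n + 1L)
  vals[1] <- (sum(lambda) - q) / 2    # limit of the integrand at u = 0
  chunk <- 2e5L
  for (beg in seq(2L, n + 1L, by = chunk)) {
    idx <- beg:min(beg + chunk - 1L, n + 1L)
    uc <- u[idx]
    m <- length(uc)
    lu <- lambda %o% uc
    theta <- 0.5 * .colSums(atan(lu), k, m) - 0.5 * q * uc
    logrho <- 0.25 * .colSums(log1p(lu * lu), k, m)
    vals[idx] <- sin(theta) * exp(-(log(uc) + logrho))
  }
  h <- U / n
  simpson <- h / 3 * (vals[1] + vals[n + 1L] +
                        4 * sum(vals[seq(2L, n, by = 2L)]) +
                        2 * sum(vals[seq(3L, n - 1L, by = 2L)]))

  # integrate by parts once: int_U^Inf g sin(theta) du =
  #   [g/theta * cos(theta)]_at_U + higher order (theta strictly decreasing)
  dtheta_U <- 0.5 * sum(lambda / (1 + lambda^2 * U^2)) - q / 2
  tail_corr <- cos(theta_fun(U)) * g_fun(U) / dtheta_U

  0.5 + (simpson + tail_corr) / pi
}

# Liu, Tang & Zhang (2009) modified moment matching: approximate Q by a
# (possibly noncentral) scaled chi-square matched on skewness or kurtosis.
liu_tail <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / sqrt(s2)
    delta <- 0
    l <- 1 / s2
  }
  t.star <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(t.star * sqrt(2 * (l + 2 * delta)) + l + delta,
                df = l, ncp = delta, lower.tail = FALSE)
}

# Quantile of the lambda-mixture at upper-tail probability p, by inverting the
# Liu approximation. Used when mapping a min-p over the rho grid back to
# per-rho critical values in the SKAT-O omnibus integration.
liu_quantile <- function(p, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / sqrt(s2)
    delta <- 0
    l <- 1 / s2
  }
  qx <- stats::qchisq(p, df = l, ncp = delta, lower.tail = FALSE)
  (qx - l - delta) / sqrt(2 * (l + 2 * delta)) * sqrt(2 * c2) + c1
}
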