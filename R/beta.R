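# Beta-distribution characterization of the resistant-fraction
# distribution rho(p0): moment matching, density, and goodness of fit
# against empirical surviving-replicate fractions.

#' Beta parameters from a mean and variance
#'
#' Moment matching: given a feasible mean \eqn{m \in (0,1)} and variance
#' \eqn{0 < v < m(1-m)}, the Beta exponents are
#' \eqn{a = m\,(m(1-m) - v)/v} and \eqn{b = a(1-m)/m} (the standard
#' moment-matching solution). The returned parameters reproduce the input
#' moments exactly.
#'
#' @param mean mean fraction, strictly inside (0, 1).
#' @param variance variance, strictly inside (0, mean * (1 - mean)).
#' @return An object of class `beta_params` with elements `a` and `b`.
#' @examples
#' beta_from_moments(0.5, 1 / 12)  # uniform: Beta(1, 1)
#' @export
beta_from_moments <- function(mean, variance) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("mean must lie strictly inside (0, 1)")
  vmax <- mean * (1 - mean)
  if (!is.finite(variance) || variance <= 0 || variance >= vmax)
    stop("variance must lie strictly inside (0, mean * (1 - mean))")
  a <- mean * (vmax - variance) / variance
  b <- a * (1 - mean) / mean
  structure(list(a = a, b = b), class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  s <- x$a + x$b
  cat(sprintf("Beta(%g, %g): mean %.4g, variance %.4g\n",
              x$a, x$b, x$a / s, x$a * x$b / (s^2 * (s + 1))))
  invisible(x)
}

#' Beta probability density
#'
#' \eqn{\rho(p) = \Gamma(a+b)/(\Gamma(a)\Gamma(b))\,p^{a-1}(1-p)^{b-1}},
#' computed in log space for numerical stability at large exponents.
#'
#' @param p fractions in (0, 1); endpoints are evaluated by continuity
#'   (0, Inf or the constant as appropriate).
#' @param params a `beta_params` object.
#' @return Numeric density values along `p`.
#' @export
beta_pdf <- function(p, params) {
  stopifnot(inherits(params, "beta_params"))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  a <- params$a; b <- params$b
  lognorm <- lgamma(a + b) - lgamma(a) - lgamma(b)
  out <- numeric(length(p))
  inner <- p > 0 & p < 1
  out[inner] <- exp(lognorm + (a - 1) * log(p[inner]) +
                      (b - 1) * log1p(-p[inner]))
  if (any(!inner)) {
    at0 <- !inner & p == 0
    at1 <- !inner & p == 1
    out[at0] <- if (a > 1) 0 else if (a == 1) exp(lognorm) else Inf
    out[at1] <- if (b > 1) 0 else if (b == 1) exp(lognorm) else Inf
  }
  out
}

# Kolmogorov-Smirnov distance between a sample and the Beta(a, b) CDF,
# handling ties (atoms of the discrete fractions) correctly.
ks_distance_beta <- function(x, a, b) {
  x <- sort(x)
  n <- length(x)
  Fx <- pbeta(x, a, b)
  max(abs(seq_len(n) / n - Fx), abs(Fx - (seq_len(n) - 1) / n))
}

beta_loglik <- function(x, a, b) {
  eps <- 0.5 / length(x)  # guard exact 0/1 in the ML cross-check only
  xx <- pmin(pmax(x, eps), 1 - eps)
  sum(dbeta(xx, a, b, log = TRUE))
}

#' Fit a Beta distribution to empirical resistant fractions
#'
#' Moment matching of a Beta distribution to the surviving-replicate
#' fractions of a [empirical_fraction_distribution()] (the canonical fit:
#' the Beta with the same mean and variance as the empirical
#' distribution), with the Kolmogorov-Smirnov distance between the
#' empirical CDF and the fitted Beta CDF as goodness-of-fit diagnostic.
#' Fractions exactly 0 or 1 are retained in the moments; because the
#' fractions are discrete at small population size N, the diagnostics
#' report the surviving N range, and no p-value is attached to the KS
#' distance. An optional maximum-likelihood cross-check is available.
#'
#' @param dist a `fraction_distribution`, or a numeric vector of
#'   fractions.
#' @param min_n minimum number of surviving fractions required.
#' @param mle also compute a maximum-likelihood fit for comparison?
#' @return A list of class `beta_fit`: `params` (`beta_params`),
#'   `ks_distance`, `mean`, `variance`, `n`, `n_extinct`, `N_range`,
#'   `degenerate` flag, and optionally `mle`.
#' @export
fit_empirical_fractions <- function(dist, min_n = 100, mle = FALSE) {
  if (inherits(dist, "fraction_distribution")) {
    x <- dist$fractions
    n_extinct <- dist$n_extinct
    N_range <- dist$N_range
  } else {
    x <- as.numeric(dist)
    n_extinct <- 0L
    N_range <- c(NA_integer_, NA_integer_)
  }
  if (length(x) < min_n)
    stop("need at least ", min_n, " surviving fractions")
  m <- mean(x)
  v <- var(x)
  if (m <= 0 || m >= 1 || v <= 0 || v >= m * (1 - m)) {
    return(structure(list(params = NULL, ks_distance = NA_real_,
                          mean = m, variance = v, n = length(x),
                          n_extinct = n_extinct, N_range = N_range,
                          degenerate = TRUE),
                     class = "beta_fit"))
  }
  bp <- beta_from_moments(m, v)
  out <- list(params = bp, ks_distance = ks_distance_beta(x, bp$a, bp$b),
              mean = m, variance = v, n = length(x),
              n_extinct = n_extinct, N_range = N_range,
              degenerate = FALSE)
  if (mle) {
    f <- nlminb(log(c(bp$a, bp$b)),
                function(lth) -beta_loglik(x, exp(lth[1]), exp(lth[2])))
    mp <- structure(list(a = exp(f$par[1]), b = exp(f$par[2])),
                    class = "beta_params")
    out$mle <- list(params = mp,
                    ks_distance = ks_distance_beta(x, mp$a, mp$b),
                    convergence = f$convergence)
  }
  structure(out, class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf(
      "Degenerate fraction distribution (mean %.4g, var %.4g): no Beta fit\n",
      x$mean, x$variance))
  } else {
    cat(sprintf("Moment-matched Beta(%.4g, %.4g), KS distance %.4g (n = %d",
                x$params$a, x$params$b, x$ks_distance, x$n))
    cat(sprintf(", %d extinct)\n", x$n_extinct))
  }
  invisible(x)
}

#' Histogram overlay data for a Beta fit
#'
#' Bin counts of the empirical fractions together with the fitted Beta
#' density at bin midpoints, as a plain data frame for plotting or CSV
#' export.
#'
#' @param fit a `beta_fit`.
#' @param fractions the fractions the fit was computed from.
#' @param bins number of histogram bins on \[0, 1\].
#' @return A data frame with `mid`, `density_empirical`, `density_beta`.
#' @export
beta_fit_histogram <- function(fit, fractions, bins = 40) {
  br <- seq(0, 1, length.out = bins + 1)
  h <- hist(fractions, breaks = br, plot = FALSE)
  data.frame(mid = h$mids, density_empirical = h$density,
             density_beta = if (fit$degenerate) NA_real_ else
               beta_pdf(h$mids, fit$params))
}
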