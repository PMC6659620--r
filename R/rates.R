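#' Kinetic rate parameters of the two-phenotype model
#'
#' Bundles the six per-cell rate constants of the switching model: birth
#' rates of the sensitive (E) and tolerant (M) phenotypes, their death
#' rates, and the two switching rates. All rates are non-negative reals in
#' the user's declared time unit; no unit conversion is attempted.
#'
#' @param k_E,k_M birth rates of E and M cells (per cell per unit time).
#' @param mu_E,mu_M death rates of E and M cells.
#' @param k_EM E-to-M switching rate.
#' @param k_ME M-to-E switching rate.
#' @return An object of class `rate_params` (a named list of the six rates).
#' @examples
#' rate_params(k_E = 0.2, k_M = 0.1, mu_E = 0.3, mu_M = 0.15,
#'             k_EM = 0.1, k_ME = 0.1)
#' @export
rate_params <- function(k_E = 0, k_M = 0, mu_E = 0, mu_M = 0,
                        k_EM = 0, k_ME = 0) {
  p <- list(k_E = k_E, k_M = k_M, mu_E = mu_E, mu_M = mu_M,
            k_EM = k_EM, k_ME = k_ME)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("rate '%s' must be a finite non-negative scalar", nm))
  }
  structure(p, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Two-phenotype switching rates (per unit time):\n")
  cat(sprintf("  birth     k_E  = %-8g k_M  = %g\n", x$k_E, x$k_M))
  cat(sprintf("  death     mu_E = %-8g mu_M = %g\n", x$mu_E, x$mu_M))
  cat(sprintf("  switching k_EM = %-8g k_ME = %g\n", x$k_EM, x$k_ME))
  invisible(x)
}

as_rate_params <- function(p) {
  if (inherits(p, "rate_params")) return(p)
  do.call(rate_params, as.list(p)[c("k_E", "k_M", "mu_E", "mu_M",
                                    "k_EM", "k_ME")])
}

# Shared composite-rate kernel. The single-cell mean dynamics in either
# phase are governed by the 2x2 matrix
#   B = [[kEf - k_EM, k_ME], [k_EM, kMf - k_ME]]
# with effective birth rates kEf, kMf (equal to -mu_E, -mu_M in the drug
# phase). Its eigenvalues are (-gamma +/- alpha)/2 with
#   gamma = k_EM + k_ME - kEf - kMf
#   alpha = sqrt(gamma^2 + 4*(k_ME*(kEf - kMf) + (gamma + kMf)*kMf)).
# The discriminant is mathematically >= 0 (real spectrum of a matrix with
# non-negative off-diagonals); tiny negatives from round-off are clamped.
composite_rates <- function(kEf, kMf, k_EM, k_ME) {
  g <- k_EM + k_ME - kEf - kMf
  disc <- g^2 + 4 * (k_ME * (kEf - kMf) + (g + kMf) * kMf)
  tol <- 1e-12 * max(1, g^2)
  if (disc < 0) {
    if (disc < -tol)
      stop("negative discriminant in composite rates: invalid inputs")
    disc <- 0
  }
  list(gamma = g, alpha = sqrt(disc))
}

#' Composite rates of the drug phase
#'
#' Under drug exposure births are suppressed and the mean number of
#' surviving cells decays bi-exponentially with exponents
#' \eqn{-(\gamma_0 \pm \alpha_0)/2}, where
#' \eqn{\gamma_0 = k_{EM} + k_{ME} + \mu_E + \mu_M} and
#' \eqn{\alpha_0 = \sqrt{\gamma_0^2 - 4(k_{ME}(\mu_E-\mu_M) +
#' (\gamma_0-\mu_M)\mu_M)}}. The pair \eqn{(-(\gamma_0+\alpha_0)/2,
#' -(\gamma_0-\alpha_0)/2)} equals the eigenvalues of the single-cell rate
#' matrix, so \eqn{0 \le \alpha_0 \le \gamma_0}.
#'
#' @param params a [rate_params()] object; birth rates are ignored.
#' @return A list with components `gamma0` and `alpha0`.
#' @examples
#' drug_phase_rates(rate_params(mu_E = 0.3, mu_M = 0.15,
#'                              k_EM = 0.1, k_ME = 0.1))
#' @export
drug_phase_rates <- function(params) {
  p <- as_rate_params(params)
  cr <- composite_rates(-p$mu_E, -p$mu_M, p$k_EM, p$k_ME)
  list(gamma0 = cr$gamma, alpha0 = cr$alpha)
}

#' Composite rates of the growth phase
#'
#' With births active the mean dynamics are governed by the effective birth
#' rates \eqn{k_E^f = k_E - \mu_E}, \eqn{k_M^f = k_M - \mu_M} and the
#' composites \eqn{\gamma = k_{EM} + k_{ME} - k_E^f - k_M^f},
#' \eqn{\alpha = \sqrt{\gamma^2 + 4(k_{ME}(k_E^f - k_M^f) +
#' (\gamma + k_M^f)k_M^f)}}. The growth-phase composites are named
#' `gammaG`/`alphaG` to avoid colliding with the exponents of the Beta
#' distribution used elsewhere.
#'
#' @inheritParams drug_phase_rates
#' @return A list with components `gammaG`, `alphaG`, `kEf`, `kMf`.
#' @export
growth_phase_rates <- function(params) {
  p <- as_rate_params(params)
  kEf <- p$k_E - p$mu_E
  kMf <- p$k_M - p$mu_M
  cr <- composite_rates(kEf, kMf, p$k_EM, p$k_ME)
  list(gammaG = cr$gamma, alphaG = cr$alpha, kEf = kEf, kMf = kMf)
}

#' Initial composition of a sample of cells
#'
#' Describes a sample of `N0` cells whose resistant (M) fraction `p0` is
#' either fixed, drawn from a Beta distribution, or drawn from an empirical
#' sample of fractions. In `"binomial"` mode each cell is independently
#' M-type with probability `p0` (the i.i.d.-cell structure under which the
#' population generating function factorizes); in `"deterministic"` mode
#' exactly `round(N0 * p0)` cells are M-type.
#'
#' @param N0 total number of cells (integer >= 1).
#' @param p0 one of: a scalar in \[0,1\]; `list(beta = c(a, b))`;
#'   `list(empirical = fractions)`.
#' @param mode `"binomial"` or `"deterministic"`.
#' @return An object of class `initial_composition` carrying `N0`, the
#'   specification, its mean `p0_mean` and variance `p0_var`.
#' @examples
#' initial_composition(200, 0)                     # all sensitive
#' initial_composition(200, list(beta = c(2, 5)))  # heterogeneous samples
#' @export
initial_composition <- function(N0, p0 = 0,
                                mode = c("binomial", "deterministic")) {
  mode <- match.arg(mode)
  if (!is.numeric(N0) || length(N0) != 1L || !is.finite(N0) || N0 < 1 ||
      N0 != round(N0))
    stop("N0 must be an integer >= 1")
  N0 <- as.integer(N0)
  if (is.numeric(p0) && length(p0) == 1L) {
    if (p0 < 0 || p0 > 1) stop("fixed p0 must lie in [0, 1]")
    spec <- list(kind = "fixed", value = p0)
    m <- p0; v <- 0
  } else if (is.list(p0) && !is.null(p0$beta)) {
    ab <- as.numeric(p0$beta)
    if (length(ab) != 2L || any(!is.finite(ab)) || any(ab <= 0))
      stop("beta specification needs two positive shape parameters")
    spec <- list(kind = "beta", a = ab[1], b = ab[2])
    m <- ab[1] / sum(ab)
    v <- ab[1] * ab[2] / (sum(ab)^2 * (sum(ab) + 1))
  } else if (is.list(p0) && !is.null(p0$empirical)) {
    x <- as.numeric(p0$empirical)
    if (length(x) < 1L || any(!is.finite(x)) || any(x < 0 | x > 1))
      stop("empirical fractions must lie in [0, 1]")
    spec <- list(kind = "empirical", values = x)
    m <- mean(x)
    v <- if (length(x) > 1) mean((x - m)^2) else 0
  } else {
    stop("p0 must be a scalar, list(beta = c(a, b)) or list(empirical = x)")
  }
  structure(list(N0 = N0, p0_spec = spec, composition_mode = mode,
                 p0_mean = m, p0_var = v),
            class = "initial_composition")
}

#' @export
print.initial_composition <- function(x, ...) {
  desc <- switch(x$p0_spec$kind,
    fixed = sprintf("fixed p0 = %g", x$p0_spec$value),
    beta = sprintf("p0 ~ Beta(%g, %g)", x$p0_spec$a, x$p0_spec$b),
    empirical = sprintf("empirical p0 sample (n = %d)",
                        length(x$p0_spec$values)))
  cat(sprintf("Initial composition: N0 = %d, %s, mode = %s\n",
              x$N0, desc, x$composition_mode))
  cat(sprintf("  <p0> = %g, var(p0) = %g\n", x$p0_mean, x$p0_var))
  invisible(x)
}
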