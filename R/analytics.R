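# Closed-form and semi-closed-form moments for the two-phenotype model.
#
# Drug phase (k_E = k_M = 0): every cell evolves independently, so the
# population generating function is the N0-fold product of the single-cell
# one, mixed over the initial resistant-fraction distribution rho(p0).
# Growth phase: means and second moments obey closed linear ODE systems.

# exp(A t) %*% v for a 2x2 matrix A, vectorized over t. Uses the identity
# exp(At) = e^{tau t} [cosh(q t) I + t sinhc(q t) (A - tau I)] with
# tau = tr(A)/2 and q^2 = tau^2 - det(A); exact for all q including q = 0.
expm2_action <- function(A, v, t) {
  tau <- (A[1, 1] + A[2, 2]) / 2
  q2 <- tau^2 - (A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
  q <- sqrt(max(q2, 0))
  Bv <- c((A[1, 1] - tau) * v[1] + A[1, 2] * v[2],
          A[2, 1] * v[1] + (A[2, 2] - tau) * v[2])
  e <- exp(tau * t)
  ch <- cosh(q * t)
  sc <- t * sinhc(q * t)
  rbind(e * (ch * v[1] + sc * Bv[1]),
        e * (ch * v[2] + sc * Bv[2]))
}

# Single-cell drug-phase rate matrix for (P_E, P_M).
drug_rate_matrix <- function(p) {
  matrix(c(-(p$k_EM + p$mu_E), p$k_ME,
           p$k_EM, -(p$k_ME + p$mu_M)),
         nrow = 2, byrow = TRUE)
}

# Growth-phase mean-field matrix for (<E>, <M>).
growth_rate_matrix <- function(p) {
  kEf <- p$k_E - p$mu_E
  kMf <- p$k_M - p$mu_M
  matrix(c(kEf - p$k_EM, p$k_ME,
           p$k_EM, kMf - p$k_ME),
         nrow = 2, byrow = TRUE)
}

#' Single-cell phenotype occupancy under drug exposure
#'
#' Probability that a cell initially M-type with probability `p0` is
#' E-type / M-type / dead at time `t`, with births suppressed. Solves
#' \eqn{d(P_E,P_M)/dt = A (P_E,P_M)} with
#' \eqn{A = [[-(k_{EM}+\mu_E), k_{ME}], [k_{EM}, -(k_{ME}+\mu_M)]]}
#' in closed form.
#'
#' @inheritParams drug_phase_rates
#' @param p0 probability the cell is initially M-type, in \[0,1\].
#' @param t vector of non-negative times.
#' @return A data frame with columns `t`, `P_E`, `P_M`, `P_dead`.
#' @export
single_cell_occupancy <- function(params, p0, t) {
  p <- as_rate_params(params)
  if (!is.numeric(p0) || length(p0) != 1L || p0 < 0 || p0 > 1)
    stop("p0 must lie in [0, 1]")
  if (any(t < 0)) stop("t must be non-negative")
  P <- expm2_action(drug_rate_matrix(p), c(1 - p0, p0), t)
  data.frame(t = t, P_E = P[1, ], P_M = P[2, ],
             P_dead = pmax(0, 1 - P[1, ] - P[2, ]))
}

#' Single-cell probability generating function (drug phase)
#'
#' \eqn{g(z_1, z_2, t \mid p_0) = 1 - (P_E + P_M) + P_E z_1 + P_M z_2},
#' the generating function of a single cell's state (dead carries no z).
#'
#' @inheritParams single_cell_occupancy
#' @param z1,z2 generating-function arguments for E and M counts.
#' @return Numeric vector along `t`.
#' @export
single_cell_gf <- function(z1, z2, params, p0, t) {
  occ <- single_cell_occupancy(params, p0, t)
  1 - (occ$P_E + occ$P_M) + occ$P_E * z1 + occ$P_M * z2
}

#' Population probability generating function (drug phase)
#'
#' \eqn{G(z_1,z_2,t) = \int_0^1 \rho(p_0)\, g(z_1,z_2,t\mid p_0)^{N_0}
#' dp_0}: cells evolve independently, so the population generating function
#' is the `N0`-th power of the single-cell one, averaged over the initial
#' resistant-fraction distribution. Fixed `p0` is evaluated exactly;
#' Beta-distributed `p0` by adaptive quadrature; empirical samples by
#' averaging.
#'
#' @inheritParams single_cell_gf
#' @param init an [initial_composition()].
#' @param rel_tol relative tolerance passed to [stats::integrate()].
#' @return Numeric vector along `t`.
#' @export
population_gf <- function(z1, z2, params, init, t, rel_tol = 1e-9) {
  stopifnot(inherits(init, "initial_composition"))
  p <- as_rate_params(params)
  gN <- function(p0, tt) single_cell_gf(z1, z2, p, p0, tt)^init$N0
  spec <- init$p0_spec
  vapply(t, function(tt) {
    switch(spec$kind,
      fixed = gN(spec$value, tt),
      empirical = mean(vapply(spec$values, gN, numeric(1), tt = tt)),
      beta = {
        f <- function(x) dbeta(x, spec$a, spec$b) *
          vapply(x, gN, numeric(1), tt = tt)
        q <- integrate(f, 0, 1, rel.tol = rel_tol, stop.on.error = FALSE)
        if (q$message != "OK")
          stop("quadrature failed in population_gf: ", q$message)
        q$value
      })
  }, numeric(1))
}

# Per-cell survival probability at mean initial fraction p0:
# s(t) = <N>/N0 from the bi-exponential mean law. mbar is the composition-
# averaged initial death rate (1-p0)*mu_E + p0*mu_M; writing the law as
# e^{-gamma0 t/2} [cosh(alpha0 t/2) - (2*mbar - gamma0)/alpha0 *
# sinh(alpha0 t/2)] is an exact rearrangement of the two-exponential form
# that stays finite as alpha0 -> 0.
drug_survival_fraction <- function(p, p0, t) {
  dr <- drug_phase_rates(p)
  mbar <- (1 - p0) * p$mu_E + p0 * p$mu_M
  u <- 2 * mbar - dr$gamma0
  pmax(biexp_kernel(dr$gamma0, dr$alpha0, 1, -u, t), 0)
}

# Difference in per-cell survival between p0 = 1 and p0 = 0; the slope of
# s(t) in p0. Appears squared in the heterogeneity term of the Fano factor.
drug_survival_contrast <- function(p, t) {
  dr <- drug_phase_rates(p)
  (p$mu_E - p$mu_M) * biexp_kernel(dr$gamma0, dr$alpha0, 0, 2, t)
}

#' Mean number of surviving cells under drug exposure
#'
#' The bi-exponential mean law for the drug phase, with decay exponents
#' \eqn{-(\gamma_0 \pm \alpha_0)/2}. The mean is linear in the initial
#' resistant fraction, so for a distributed \eqn{p_0} pass its mean.
#'
#' @inheritParams single_cell_occupancy
#' @param N0 initial number of cells.
#' @return Numeric vector of mean surviving counts along `t`.
#' @export
mean_surviving_drug <- function(params, N0, p0, t) {
  p <- as_rate_params(params)
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (any(t < 0)) stop("t must be non-negative")
  N0 * drug_survival_fraction(p, p0, t)
}

#' Fano factor of the surviving population under drug exposure
#'
#' \deqn{F = 1 - \langle N\rangle/N_0 + \frac{N_0(N_0-1)}{\langle N\rangle}
#'   \left[\frac{\mu_E-\mu_M}{\alpha_0}\left(e^{-t(\gamma_0-\alpha_0)/2} -
#'   e^{-t(\gamma_0+\alpha_0)/2}\right)\right]^2 \sigma^2_{p_0}.}
#' Without initial heterogeneity (\eqn{\sigma^2_{p_0}=0}) the surviving
#' count is a binomial thinning of \eqn{N_0} cells and \eqn{F < 1} for all
#' \eqn{t>0}; variability in \eqn{p_0} adds the positive heterogeneity term
#' which can push \eqn{F} above 1 (super-Poissonian counts).
#'
#' @inheritParams mean_surviving_drug
#' @param p0_mean,p0_var mean and variance of the initial resistant
#'   fraction across samples.
#' @return Numeric vector of Fano factors along `t`.
#' @export
fano_drug <- function(params, N0, p0_mean, p0_var, t) {
  p <- as_rate_params(params)
  if (p0_mean < 0 || p0_mean > 1) stop("p0_mean must lie in [0, 1]")
  if (p0_var < 0 || p0_var > p0_mean * (1 - p0_mean) + 1e-12)
    stop("p0_var must lie in [0, p0_mean * (1 - p0_mean)]")
  if (p0_var > 0 && N0 < 2) stop("N0 >= 2 required for heterogeneity term")
  s <- drug_survival_fraction(p, p0_mean, t)
  if (any(s <= 0 & t > 0) || any(N0 * s == 0 & t > 0))
    stop("mean surviving population is numerically zero; Fano undefined")
  X <- drug_survival_contrast(p, t)
  het <- if (p0_var > 0) (N0 - 1) / s * X^2 * p0_var else 0
  out <- 1 - s + het
  out[t == 0] <- 0
  out
}

#' Heterogeneity signal from Fano factor and mean (drug phase)
#'
#' The square-root of the heterogeneity term of the drug-phase Fano factor,
#' a quantity estimable purely from measured \eqn{F} and \eqn{\langle
#' N\rangle}: `heterogeneity_signal_empirical` returns
#' \eqn{\sqrt{(F - 1 + \langle N\rangle/N_0)\,\langle N\rangle /
#' (N_0(N_0-1))}} while `heterogeneity_signal_theory` evaluates its model
#' value \eqn{\sigma_{p_0}\,|\mu_E-\mu_M|/\alpha_0\,
#' |e^{-t(\gamma_0-\alpha_0)/2} - e^{-t(\gamma_0+\alpha_0)/2}|}.
#'
#' The decaying (negative) exponents are used throughout, consistent with
#' the Fano-factor expression; a published variant of this regrouped form
#' carries growing exponents, which is inconsistent with the Fano factor it
#' was regrouped from and divergent in `t`, and is not implemented.
#'
#' @inheritParams fano_drug
#' @return Numeric vector along `t` (theory) / along `F` (empirical).
#' @export
heterogeneity_signal_theory <- function(params, p0_var, t) {
  p <- as_rate_params(params)
  if (p0_var < 0) stop("p0_var must be non-negative")
  sqrt(p0_var) * abs(drug_survival_contrast(p, t))
}

#' @rdname heterogeneity_signal_theory
#' @param F measured Fano factor(s) of the surviving population.
#' @param mean_N measured mean surviving count(s).
#' @export
heterogeneity_signal_empirical <- function(F, mean_N, N0) {
  arg <- (F - 1 + mean_N / N0) * mean_N / (N0 * (N0 - 1))
  neg <- arg < 0
  if (any(neg)) {
    warning("negative argument: data sub-Poissonian beyond the ",
            "zero-heterogeneity floor; returning NA there")
    arg[neg] <- NA_real_
  }
  sqrt(arg)
}

#' Mean population size in the growth phase
#'
#' Bi-exponential mean law with exponents \eqn{-(\gamma \pm \alpha)/2}
#' built from the effective birth rates (see [growth_phase_rates()]),
#' given a deterministic initial state (`E0`, `M0`).
#'
#' @inheritParams drug_phase_rates
#' @param E0,M0 initial counts of E and M cells.
#' @param t vector of non-negative times.
#' @return Numeric vector of mean total counts along `t`.
#' @export
mean_growth <- function(params, E0, M0, t) {
  p <- as_rate_params(params)
  if (E0 < 0 || M0 < 0) stop("initial counts must be non-negative")
  if (any(t < 0)) stop("t must be non-negative")
  gr <- growth_phase_rates(p)
  S <- E0 + M0
  D <- gr$gammaG * S + 2 * gr$kEf * E0 + 2 * gr$kMf * M0
  biexp_kernel(gr$gammaG, gr$alphaG, S, D, t)
}

# 5x5 generator of the closed first+second moment system for the state
# x = (<E>, <M>, <E^2>, <M^2>, <EM>).
moment_ode_matrix <- function(p) {
  kEf <- p$k_E - p$mu_E
  kMf <- p$k_M - p$mu_M
  rbind(
    c(kEf - p$k_EM, p$k_ME, 0, 0, 0),
    c(p$k_EM, kMf - p$k_ME, 0, 0, 0),
    c(p$k_E + p$mu_E + p$k_EM, p$k_ME, 2 * (kEf - p$k_EM), 0, 2 * p$k_ME),
    c(p$k_EM, p$k_M + p$mu_M + p$k_ME, 0, 2 * (kMf - p$k_ME), 2 * p$k_EM),
    c(-p$k_EM, -p$k_ME, p$k_EM, p$k_ME,
      kEf + kMf - p$k_EM - p$k_ME))
}

# x(t) = exp(A t) x0 for a small dense A over a grid of times.
# Eigendecomposition fast path; falls back to Matrix::expm when the
# eigenvector basis is ill-conditioned (near-defective A).
solve_linear_ode <- function(A, x0, t) {
  n <- length(x0)
  ev <- tryCatch(eigen(A), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(ev)) {
    rc <- tryCatch(rcond(ev$vectors), error = function(e) 0)
    use_eigen <- is.finite(rc) && rc > 1e-8
  }
  if (use_eigen) {
    c0 <- solve(ev$vectors, x0)
    out <- Re(ev$vectors %*% (c0 * exp(outer(ev$values, t))))
  } else {
    out <- vapply(t, function(tt) {
      as.numeric(Matrix::expm(A * tt) %*% x0)
    }, numeric(n))
  }
  matrix(out, nrow = n)
}

# Lean mean/variance evaluator used inside fitting loops: th is the
# numeric rate vector (k_E, k_M, mu_E, mu_M, k_EM, k_ME).
growth_mean_var <- function(th, E0, M0, t) {
  p <- list(k_E = th[1], k_M = th[2], mu_E = th[3], mu_M = th[4],
            k_EM = th[5], k_ME = th[6])
  A <- moment_ode_matrix(p)
  x0 <- c(E0, M0, E0^2, M0^2, E0 * M0)
  X <- solve_linear_ode(A, x0, t)
  mN <- X[1, ] + X[2, ]
  vN <- (X[3, ] - X[1, ]^2) + (X[4, ] - X[2, ]^2) +
    2 * (X[5, ] - X[1, ] * X[2, ])
  list(mean = mN, var = vN)
}

#' Moment trajectories in the growth phase
#'
#' Solves the closed linear ODE system for the first and second moments
#' \eqn{(\langle E\rangle, \langle M\rangle, \langle E^2\rangle,
#' \langle M^2\rangle, \langle EM\rangle)} from a deterministic initial
#' state, and returns means, variances, the E-M covariance, the total
#' variance \eqn{\sigma_N^2 = \sigma_E^2 + \sigma_M^2 + 2 C_{EM}} and the
#' Fano factor of the total count. Drug-phase trajectories are the special
#' case `k_E = k_M = 0`.
#'
#' @inheritParams mean_growth
#' @param t_grid increasing vector of times (need not start at 0).
#' @return A data frame with columns `t`, `mean_E`, `mean_M`, `mean_N`,
#'   `var_E`, `var_M`, `cov_EM`, `var_N`, `fano_N`; the raw second moments
#'   are attached as attribute `"second_moments"`.
#' @export
moments_growth <- function(params, E0, M0, t_grid) {
  p <- as_rate_params(params)
  if (E0 < 0 || M0 < 0) stop("initial counts must be non-negative")
  if (any(t_grid < 0)) stop("times must be non-negative")
  A <- moment_ode_matrix(p)
  x0 <- c(E0, M0, E0^2, M0^2, E0 * M0)
  X <- solve_linear_ode(A, x0, t_grid)
  mE <- X[1, ]; mM <- X[2, ]
  EE <- X[3, ]; MM <- X[4, ]; EM <- X[5, ]
  vE <- EE - mE^2
  vM <- MM - mM^2
  cEM <- EM - mE * mM
  vN <- vE + vM + 2 * cEM
  mN <- mE + mM
  out <- data.frame(t = t_grid, mean_E = mE, mean_M = mM, mean_N = mN,
                    var_E = vE, var_M = vM, cov_EM = cEM, var_N = vN,
                    fano_N = ifelse(mN > 0, vN / mN, NA_real_))
  attr(out, "second_moments") <-
    data.frame(t = t_grid, EE = EE, MM = MM, EM = EM)
  out
}
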