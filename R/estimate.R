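# Parameter estimation from designed initial conditions.
#
# Drug-phase protocol: (1) a p0 = 0 series identifies (mu_E, gamma0,
# alpha0) from the bi-exponential mean law; (2) a p0 = 1 series then
# identifies mu_M; (3) the composite-rate definitions are inverted for the
# switching rates; (4) a mixed series' mean and Fano factor give the
# initial heterogeneity (<p0>, var(p0)) per time point.
# Growth phase: mean curves from M0 = 0 / E0 = 0 conditions identify the
# effective birth rates and switching rates; adding variance trajectories
# separates birth from death rates.

#' Moment time series of a designed experiment
#'
#' Container for cross-replicate per-time summaries of the surviving
#' population under one initial condition.
#'
#' @param times increasing vector of observation times.
#' @param mean_N mean total count per time.
#' @param var_N optional cross-replicate variance per time.
#' @param n optional replicates per time (scalar or vector).
#' @param N0 initial sample size (drug phase) or `E0 + M0`.
#' @param label initial-condition label, e.g. `"p0=0"`, `"E0-only"`.
#' @param E0,M0 optional deterministic initial counts (growth phase).
#' @return An object of class `moment_series`.
#' @export
moment_time_series <- function(times, mean_N, var_N = NULL, n = NULL,
                               N0, label = "", E0 = NULL, M0 = NULL) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (length(mean_N) != length(times)) stop("mean_N length mismatch")
  if (any(mean_N < 0)) stop("mean_N must be non-negative")
  if (!is.null(var_N) && length(var_N) != length(times))
    stop("var_N length mismatch")
  if (!is.null(n)) n <- rep_len(n, length(times))
  structure(list(times = times, mean_N = mean_N, var_N = var_N, n = n,
                 N0 = N0, label = label, E0 = E0, M0 = M0),
            class = "moment_series")
}

# Drug-phase mean survival fraction in composite parameters:
# s(t) = e^{-g t/2} [cosh(a t/2) - (2 mbar - g) (t/2) sinhc(a t/2)]
# where mbar is the composition-averaged initial death rate.
drug_mean_fraction_comp <- function(gamma0, alpha0, mbar, t) {
  pmax(biexp_kernel(gamma0, alpha0, 1, gamma0 - 2 * mbar, t), 0)
}

# Growth-phase mean in effective-rate parameters.
growth_mean_eff <- function(kEf, kMf, k_EM, k_ME, E0, M0, t) {
  cr <- composite_rates(kEf, kMf, k_EM, k_ME)
  S <- E0 + M0
  D <- cr$gamma * S + 2 * kEf * E0 + 2 * kMf * M0
  biexp_kernel(cr$gamma, cr$alpha, S, D, t)
}

series_weights <- function(series) {
  if (!is.null(series$var_N) && !is.null(series$n)) {
    se <- sqrt(pmax(series$var_N, 0) / series$n) / series$N0
    1 / pmax(se, 1e-6)
  } else {
    rep(1, length(series$times))
  }
}

fit_flags <- function(est, lower, upper, tol = 1e-6) {
  flags <- character(0)
  pin <- abs(est - lower) < tol | abs(est - upper) < tol
  if (any(pin)) flags <- c(flags, "boundary-pinned")
  flags
}

#' Fit the drug-phase mean curve from an all-sensitive start
#'
#' Constrained nonlinear least squares of the bi-exponential drug-phase
#' mean law (with \eqn{p_0 = 0}) to `mean_N / N0`, estimating
#' \eqn{(\mu_E, \gamma_0, \alpha_0)}. Multi-start over a latin-hypercube
#' of initial values plus a slope-based start; the constraint
#' \eqn{0 \le \alpha_0 \le \gamma_0} is enforced by fitting
#' \eqn{\alpha_0/\gamma_0 \in [0,1]}.
#'
#' @param series a [moment_time_series()] with the `p0 = 0` condition.
#' @param n_starts number of multi-start initial values.
#' @param seed seed for the start draws.
#' @param rate_upper optional upper box bound for rates; default is scaled
#'   from the observed decay.
#' @return A list of class `switch_fit` with elements `mu_E`, `gamma0`,
#'   `alpha0`, `objective`, `convergence`, `flags`.
#' @export
fit_drug_mean_curve <- function(series, n_starts = 8, seed = 1,
                                rate_upper = NULL) {
  stopifnot(inherits(series, "moment_series"))
  t <- series$times
  if (length(t) < 4) stop("need at least 4 time points")
  y <- series$mean_N / series$N0
  w <- series_weights(series)
  tl <- t[length(t)]
  r_hat <- max(1e-3, -log(max(y[length(y)], 1e-10)) / tl)
  U <- rate_upper %||% (20 * r_hat)
  obj <- function(th) {
    m <- drug_mean_fraction_comp(th[2], th[3] * th[2], th[1], t)
    sum((w * (y - m))^2)
  }
  lower <- c(0, 1e-8, 0)
  upper <- c(U, U, 1)
  slope0 <- if (y[1] > 0 && length(t) >= 2) {
    max((y[1] - y[2]) / ((t[2] - t[1]) * y[1]), 1e-3)
  } else r_hat
  starts <- rbind(c(min(slope0, U), min(2 * r_hat, U), 0.5),
                  lhs_starts(n_starts - 1, lower, upper, seed))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(nlminb(starts[i, ], obj, lower = lower, upper = upper,
                         control = list(iter.max = 500, eval.max = 1000)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$objective < best$objective))
      best <- f
  }
  if (is.null(best)) stop("all starts failed in fit_drug_mean_curve")
  est <- best$par
  flags <- fit_flags(est, lower, upper)
  gamma0 <- est[2]
  alpha0 <- est[3] * gamma0
  r1 <- (gamma0 - alpha0) / 2
  r2 <- (gamma0 + alpha0) / 2
  if (r2 > 0 && (r2 - r1) / r2 < 0.05)
    flags <- c(flags, "near-single-exponential")
  structure(list(mu_E = est[1], gamma0 = gamma0, alpha0 = alpha0,
                 objective = best$objective,
                 convergence = best$convergence, flags = flags),
            class = "switch_fit")
}

#' Fit the M-cell death rate from an all-resistant start
#'
#' One-parameter weighted least squares of the drug-phase mean law with
#' \eqn{p_0 = 1} and known composites \eqn{(\gamma_0, \alpha_0)}. The
#' small-time slope of `mean_N / N0` equals \eqn{-\mu_M}, which brackets
#' the search.
#'
#' @inheritParams fit_drug_mean_curve
#' @param series a [moment_time_series()] with the `p0 = 1` condition.
#' @param gamma0,alpha0 composite drug-phase rates from
#'   [fit_drug_mean_curve()].
#' @return A list of class `switch_fit` with element `mu_M`.
#' @export
fit_drug_mu_M <- function(series, gamma0, alpha0) {
  stopifnot(inherits(series, "moment_series"))
  t <- series$times
  y <- series$mean_N / series$N0
  w <- series_weights(series)
  obj <- function(m) {
    sum((w * (y - drug_mean_fraction_comp(gamma0, alpha0, m, t)))^2)
  }
  o <- optimize(obj, c(0, gamma0), tol = 1e-12)
  flags <- fit_flags(o$minimum, 0, gamma0, tol = 1e-8 * max(1, gamma0))
  structure(list(mu_M = o$minimum, objective = o$objective,
                 convergence = 0L, flags = flags),
            class = "switch_fit")
}

#' Invert drug-phase composite rates for the switching rates
#'
#' Solves the composite definitions \eqn{\gamma_0 = k_{EM} + k_{ME} +
#' \mu_E + \mu_M} and the \eqn{\alpha_0} discriminant for
#' \eqn{(k_{EM}, k_{ME})} given the death rates:
#' \eqn{k_{ME} = (\gamma_0^2 - \alpha_0^2 - 4(\gamma_0 - \mu_M)\mu_M) /
#' (4(\mu_E - \mu_M))}.
#'
#' @param gamma0,alpha0 drug-phase composites.
#' @param mu_E,mu_M death rates.
#' @param tol negative results larger than `-tol` are clamped to zero;
#'   beyond that the inputs are inconsistent and an error is raised.
#' @return A list with `k_EM` and `k_ME`.
#' @export
invert_drug_rates <- function(gamma0, alpha0, mu_E, mu_M, tol = 1e-8) {
  scale <- max(1, gamma0)
  if (abs(mu_E - mu_M) < 1e-12 * scale)
    stop("mu_E = mu_M: switching rates are structurally non-identifiable ",
         "from drug-phase composites")
  k_ME <- (gamma0^2 - alpha0^2 - 4 * (gamma0 - mu_M) * mu_M) /
    (4 * (mu_E - mu_M))
  k_EM <- gamma0 - k_ME - mu_E - mu_M
  for (v in c(k_EM, k_ME)) {
    if (v < -tol * scale)
      stop("inconsistent inputs: negative switching rate ", signif(v, 4))
  }
  list(k_EM = max(k_EM, 0), k_ME = max(k_ME, 0))
}

#' Invert growth-phase composite rates for the switching rates
#'
#' Same algebraic pattern as [invert_drug_rates()] with the effective
#' birth rates in place of the negated death rates.
#'
#' @param gammaG,alphaG growth-phase composites.
#' @param kEf,kMf effective birth rates \eqn{k - \mu} of E and M.
#' @inheritParams invert_drug_rates
#' @return A list with `k_EM` and `k_ME`.
#' @export
invert_growth_rates <- function(gammaG, alphaG, kEf, kMf, tol = 1e-8) {
  scale <- max(1, abs(gammaG))
  if (abs(kEf - kMf) < 1e-12 * scale)
    stop("kEf = kMf: switching-rate inversion is degenerate")
  k_ME <- (alphaG^2 - gammaG^2 - 4 * gammaG * kMf - 4 * kMf^2) /
    (4 * (kEf - kMf))
  k_EM <- gammaG + kEf + kMf - k_ME
  for (v in c(k_EM, k_ME)) {
    if (v < -tol * scale)
      stop("inconsistent inputs: negative switching rate ", signif(v, 4))
  }
  list(k_EM = max(k_EM, 0), k_ME = max(k_ME, 0))
}

#' Estimate initial heterogeneity from measured moments
#'
#' Per-time moment estimators of the initial resistant fraction:
#' \deqn{p_0 = \frac{\langle N\rangle - \langle N\rangle_0}
#'   {\langle N\rangle_1 - \langle N\rangle_0}, \qquad
#'   \sigma^2_{p_0} = \frac{N_0 \langle N\rangle}
#'   {(\langle N\rangle_1 - \langle N\rangle_0)^2 (N_0 - 1)}
#'   \left[F - 1 + \frac{\langle N\rangle}{N_0}\right],}
#' where \eqn{\langle N\rangle_0, \langle N\rangle_1} are the mean
#' surviving counts of companion experiments started from \eqn{p_0 = 0}
#' and \eqn{p_0 = 1}. Estimates are computed at every supplied time and
#' combined by the given weights (inverse bootstrap variances in the full
#' protocol); out-of-range values are clipped with a flag.
#'
#' @param mean_N,fano_N mixed-condition mean and Fano factor per time.
#' @param mean_N0,mean_N1 companion means per time for `p0 = 0` / `p0 = 1`.
#' @param N0 sample size.
#' @param weights optional per-time combination weights; equal by default.
#' @return A list with `p0_mean`, `p0_var`, per-time estimates
#'   (`per_time`), and `flags`.
#' @export
estimate_initial_heterogeneity <- function(mean_N, fano_N, mean_N0,
                                           mean_N1, N0, weights = NULL) {
  den <- mean_N1 - mean_N0
  if (any(abs(den) < .Machine$double.eps * N0))
    stop("<N>_0 = <N>_1: heterogeneity is non-identifiable (mu_E = mu_M)")
  p0_t <- (mean_N - mean_N0) / den
  var_t <- N0 * mean_N / (den^2 * (N0 - 1)) * (fano_N - 1 + mean_N / N0)
  flags <- character(0)
  if (any(p0_t < 0 | p0_t > 1, na.rm = TRUE)) flags <- c(flags, "p0-clipped")
  if (any(var_t < 0, na.rm = TRUE)) flags <- c(flags, "variance-clipped")
  p0c <- pmin(pmax(p0_t, 0), 1)
  w <- weights %||% rep(1, length(p0_t))
  w[!is.finite(w) | !is.finite(p0_t) | !is.finite(var_t)] <- 0
  if (sum(w) <= 0) stop("no usable time points")
  p0_hat <- sum(w * p0c) / sum(w)
  var_hat <- max(sum(w * pmax(var_t, 0)) / sum(w), 0)
  vmax <- p0_hat * (1 - p0_hat)
  if (var_hat > vmax) {
    flags <- c(flags, "variance-clipped")
    var_hat <- vmax
  }
  list(p0_mean = p0_hat, p0_var = var_hat,
       per_time = data.frame(p0 = p0_t, p0_var = var_t, weight = w),
       flags = unique(flags))
}

#' Fit growth-phase mean curves from two pure initial conditions
#'
#' Joint constrained least squares of the growth-phase mean law to a
#' `M0 = 0` curve and an `E0 = 0` curve, in the natural parameters
#' \eqn{(k_E^f, k_M^f, k_{EM}, k_{ME})}; composites are reported via the
#' forward definitions. Only the differences \eqn{k - \mu} are
#' identifiable from mean curves, which is made explicit by the
#' parameterization.
#'
#' @param series_E0only [moment_time_series()] with `M0 = 0`.
#' @param series_M0only [moment_time_series()] with `E0 = 0`.
#' @inheritParams fit_drug_mean_curve
#' @return A list of class `switch_fit` with `kEf`, `kMf`, `k_EM`,
#'   `k_ME`, `gammaG`, `alphaG`.
#' @export
fit_growth_mean_curves <- function(series_E0only, series_M0only,
                                   n_starts = 8, seed = 1,
                                   rate_upper = NULL) {
  sE <- series_E0only; sM <- series_M0only
  stopifnot(inherits(sE, "moment_series"), inherits(sM, "moment_series"))
  if (is.null(sE$E0) || (sE$M0 %||% 0) != 0)
    stop("series_E0only must have M0 = 0 and E0 set")
  if (is.null(sM$M0) || (sM$E0 %||% 0) != 0)
    stop("series_M0only must have E0 = 0 and M0 set")
  yE <- sE$mean_N / sE$E0
  yM <- sM$mean_N / sM$M0
  wE <- series_weights(sE) ; wM <- series_weights(sM)
  tspan <- max(sE$times, sM$times)
  r_hat <- max(1e-3, max(abs(log(pmax(c(yE, yM), 1e-10)))) / tspan)
  U <- rate_upper %||% (20 * r_hat)
  obj <- function(th) {
    mE <- growth_mean_eff(th[1], th[2], th[3], th[4], sE$E0, 0, sE$times)
    mM <- growth_mean_eff(th[1], th[2], th[3], th[4], 0, sM$M0, sM$times)
    sum((wE * (yE - mE / sE$E0))^2) + sum((wM * (yM - mM / sM$M0))^2)
  }
  lower <- c(-U, -U, 0, 0)
  upper <- c(U, U, U, U)
  slopeE <- (yE[1] - yE[2]) / (sE$times[2] - sE$times[1])
  slopeM <- (yM[1] - yM[2]) / (sM$times[2] - sM$times[1])
  starts <- rbind(c(-slopeE, -slopeM, r_hat / 2, r_hat / 2),
                  lhs_starts(n_starts - 1, lower, upper, seed))
  starts <- pmin(pmax(starts, rep(lower, each = nrow(starts))),
                 rep(upper, each = nrow(starts)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(nlminb(starts[i, ], obj, lower = lower, upper = upper,
                         control = list(iter.max = 500, eval.max = 1000)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$objective < best$objective))
      best <- f
  }
  if (is.null(best)) stop("all starts failed in fit_growth_mean_curves")
  th <- best$par
  cr <- composite_rates(th[1], th[2], th[3], th[4])
  flags <- fit_flags(th, lower, upper)
  if (abs(th[1] - th[2]) < 1e-6 * max(1, abs(th[1])))
    flags <- c(flags, "kEf=kMf-degenerate")
  structure(list(kEf = th[1], kMf = th[2], k_EM = th[3], k_ME = th[4],
                 gammaG = cr$gamma, alphaG = cr$alpha,
                 objective = best$objective,
                 convergence = best$convergence, flags = flags),
            class = "switch_fit")
}

# Weighted least-squares objective over one or more growth-phase moment
# series; precomputes the weights once. th = (k_E, k_M, mu_E, mu_M,
# k_EM, k_ME).
growth_full_objective <- function(series) {
  pre <- lapply(series, function(s) {
    se_m <- if (!is.null(s$n)) {
      sqrt(pmax(s$var_N, 1e-8) / s$n)
    } else pmax(abs(s$mean_N), 1) * 1e-3
    se_v <- if (!is.null(s$n)) {
      pmax(s$var_N, 1e-8) * sqrt(2 / (pmax(s$n, 2) - 1))
    } else pmax(abs(s$var_N), 1) * 1e-3
    list(t = s$times, E0 = s$E0, M0 = s$M0, m = s$mean_N, v = s$var_N,
         wm = 1 / se_m, wv = 1 / se_v)
  })
  function(th) {
    if (any(th < 0) || any(!is.finite(th))) return(1e12)
    tot <- 0
    for (q in pre) {
      mv <- tryCatch(growth_mean_var(th, q$E0, q$M0, q$t),
                     error = function(e) NULL)
      if (is.null(mv) || any(!is.finite(mv$mean)) ||
          any(!is.finite(mv$var)))
        return(1e12)
      tot <- tot + sum(((q$m - mv$mean) * q$wm)^2) +
        sum(((q$v - mv$var) * q$wv)^2)
    }
    tot
  }
}

#' Fit all six rates from growth-phase mean and variance trajectories
#'
#' Weighted least squares jointly on the mean and variance trajectories of
#' one or more growth-phase conditions with known deterministic
#' \eqn{(E_0, M_0)}. The mean depends only on \eqn{k - \mu} while the
#' variance depends on \eqn{k + \mu}, which separates birth from death
#' rates. Model trajectories come from the closed second-moment ODE system
#' ([moments_growth()]).
#'
#' @param series a [moment_time_series()] with `var_N`, or a list of them.
#' @inheritParams fit_drug_mean_curve
#' @param init_rates optional list with `kEf`, `kMf`, `k_EM`, `k_ME` used
#'   to build structured starts (e.g. from [fit_growth_mean_curves()]).
#' @return A list of class `switch_fit` with a [rate_params()] in
#'   `$params` and the six estimates as fields.
#' @export
fit_growth_full <- function(series, n_starts = 8, seed = 1,
                            rate_upper = NULL, init_rates = NULL) {
  if (inherits(series, "moment_series")) series <- list(series)
  for (s in series) {
    stopifnot(inherits(s, "moment_series"))
    if (is.null(s$var_N)) stop("fit_growth_full needs variance trajectories")
    if (is.null(s$E0) || is.null(s$M0))
      stop("each series needs known deterministic E0 and M0")
  }
  U <- rate_upper %||% 5
  obj <- growth_full_objective(series)
  lower <- rep(0, 6)
  upper <- rep(U, 6)
  starts <- NULL
  if (!is.null(init_rates)) {
    for (d in c(0.05, 0.2, 0.5, 1)) {
      kE <- max(init_rates$kEf, 0) + d
      kM <- max(init_rates$kMf, 0) + d
      starts <- rbind(starts,
                      c(kE, kM, kE - init_rates$kEf, kM - init_rates$kMf,
                        max(init_rates$k_EM, 1e-3),
                        max(init_rates$k_ME, 1e-3)))
    }
  }
  n_lhs <- max(n_starts - NROW(starts), 2)
  starts <- rbind(starts, lhs_starts(n_lhs, lower, upper, seed))
  starts <- pmin(pmax(starts, 0), U)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(nlminb(starts[i, ], obj, lower = lower, upper = upper,
                         control = list(iter.max = 1000, eval.max = 2000)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$objective < best$objective))
      best <- f
  }
  if (is.null(best)) stop("all starts failed in fit_growth_full")
  th <- best$par
  p <- rate_params(th[1], th[2], th[3], th[4], th[5], th[6])
  gr <- growth_phase_rates(p)
  flags <- fit_flags(th, lower, upper)
  structure(list(params = p, k_E = th[1], k_M = th[2], mu_E = th[3],
                 mu_M = th[4], k_EM = th[5], k_ME = th[6],
                 kEf = gr$kEf, kMf = gr$kMf,
                 gammaG = gr$gammaG, alphaG = gr$alphaG,
                 objective = best$objective,
                 convergence = best$convergence, flags = flags),
            class = "switch_fit")
}

#' @export
print.switch_fit <- function(x, ...) {
  est <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1,
                  logical(1))]
  est <- est[setdiff(names(est), c("objective", "convergence"))]
  cat("Fit estimates:\n")
  for (nm in names(est)) cat(sprintf("  %-8s %.6g\n", nm, est[[nm]]))
  cat(sprintf("  objective %.4g, convergence %d\n",
              x$objective, x$convergence))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
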