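# Exact stochastic simulation (direct-method Gillespie) of the
# two-phenotype birth-death-switching process, plus ensemble summaries and
# empirical resistant-fraction distributions.

#' Draw initial (E0, M0) compositions
#'
#' Draws the per-sample resistant fraction from the composition's `p0`
#' specification (using R's RNG, so wrap in `set.seed()` for
#' reproducibility), then allocates cells: `M0 ~ Binomial(N0, p0)` in
#' binomial mode or `M0 = round(N0 * p0)` in deterministic mode.
#'
#' @param init an [initial_composition()].
#' @param n number of samples to draw.
#' @return Integer matrix with columns `E0`, `M0` and `n` rows.
#' @export
draw_initial_composition <- function(init, n = 1) {
  stopifnot(inherits(init, "initial_composition"))
  spec <- init$p0_spec
  p0 <- switch(spec$kind,
    fixed = rep(spec$value, n),
    beta = rbeta(n, spec$a, spec$b),
    empirical = spec$values[sample.int(length(spec$values), n,
                                       replace = TRUE)])
  M0 <- if (init$composition_mode == "binomial") {
    rbinom(n, init$N0, p0)
  } else {
    as.integer(round(init$N0 * p0))
  }
  cbind(E0 = init$N0 - M0, M0 = M0)
}

#' Simulate a replicate ensemble of the switching process
#'
#' Runs `n_replicates` exact stochastic simulations of the six-channel
#' process (births, deaths and switching of E and M cells) and records the
#' state at each grid time (right-continuous sampling of the jump
#' process). Each replicate runs on its own counter-derived RNG stream
#' (`seed * 2^20 + replicate`), so ensembles are bit-reproducible from
#' `(params, init, seed, t_grid)` and replicates are independent of
#' ordering.
#'
#' @inheritParams drug_phase_rates
#' @param init an [initial_composition()], or a length-2 numeric
#'   `c(E0, M0)` for a fixed deterministic initial state.
#' @param t_grid increasing vector of sampling times starting at 0.
#' @param n_replicates number of replicates (>= 1).
#' @param seed master seed (non-negative integer < 2^31).
#' @param max_events per-replicate event cap guarding super-critical
#'   parameter sets.
#' @return An object of class `switch_ensemble`: list with `params`,
#'   `init`, `t_grid`, `seeds`, integer matrices `E` and `M`
#'   (`n_replicates` x `length(t_grid)`), and `n_replicates`.
#' @examples
#' p <- rate_params(mu_E = 0.3, mu_M = 0.15, k_EM = 0.1, k_ME = 0.1)
#' ens <- simulate_ensemble(p, initial_composition(50, 0.2),
#'                          t_grid = seq(0, 4, 0.5),
#'                          n_replicates = 100, seed = 1)
#' ensemble_summary(ens)[1:3, 1:5]
#' @export
simulate_ensemble <- function(params, init, t_grid, n_replicates, seed,
                              max_events = 1e8) {
  p <- as_rate_params(params)
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1] != 0)
    stop("t_grid must be strictly increasing and start at 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (inherits(init, "initial_composition")) {
    comps <- with_seed(seed, draw_initial_composition(init, n_replicates))
  } else if (is.numeric(init) && length(init) == 2L) {
    comps <- cbind(E0 = rep(as.integer(init[1]), n_replicates),
                   M0 = rep(as.integer(init[2]), n_replicates))
  } else {
    stop("init must be an initial_composition or c(E0, M0)")
  }
  seeds <- spawn_path_seeds(seed, n_replicates)
  sim <- ssa_ensemble_cpp(p$k_E, p$k_M, p$mu_E, p$mu_M, p$k_EM, p$k_ME,
                          as.integer(comps[, "E0"]),
                          as.integer(comps[, "M0"]),
                          as.numeric(t_grid), seeds, max_events)
  structure(list(params = p, init = init, t_grid = t_grid, seeds = seeds,
                 E = sim$E, M = sim$M, n_replicates = n_replicates),
            class = "switch_ensemble")
}

#' @export
print.switch_ensemble <- function(x, ...) {
  cat(sprintf(
    "SSA ensemble: %d replicates, %d grid times on [0, %g]\n",
    x$n_replicates, length(x$t_grid), max(x$t_grid)))
  invisible(x)
}

#' Single stochastic trajectory
#'
#' @inheritParams simulate_ensemble
#' @param E0,M0 initial counts.
#' @return A data frame with columns `t`, `E`, `M`.
#' @export
ssa_trajectory <- function(params, E0, M0, t_grid, seed,
                           max_events = 1e8) {
  ens <- simulate_ensemble(params, c(E0, M0), t_grid,
                           n_replicates = 1, seed = seed,
                           max_events = max_events)
  data.frame(t = t_grid, E = ens$E[1, ], M = ens$M[1, ])
}

#' Cross-replicate moment summary of an ensemble
#'
#' Unbiased sample moments of E, M and N = E + M across replicates at each
#' grid time, with the Fano factor of N and (optionally) bootstrap
#' standard errors of the mean, variance and Fano factor. Replicates are
#' the resampling unit: one set of `B` bootstrap index draws is shared
#' across grid times.
#'
#' @param ensemble a `switch_ensemble`.
#' @param bootstrap logical; compute bootstrap standard errors?
#' @param B number of bootstrap resamples.
#' @param boot_seed seed for the bootstrap index draws.
#' @return A data frame with columns `t`, `mean_E`, `mean_M`, `mean_N`,
#'   `var_E`, `var_M`, `cov_EM`, `var_N`, `fano_N`, `n` and, when
#'   `bootstrap`, `se_mean_N`, `se_var_N`, `se_fano_N`.
#' @export
ensemble_summary <- function(ensemble, bootstrap = TRUE, B = 1000,
                             boot_seed = 1) {
  stopifnot(inherits(ensemble, "switch_ensemble"))
  n <- ensemble$n_replicates
  if (n < 2) stop("ensemble_summary needs at least 2 replicates")
  E <- ensemble$E
  M <- ensemble$M
  N <- E + M
  mE <- colMeans(E); mM <- colMeans(M); mN <- mE + mM
  vE <- apply(E, 2, var); vM <- apply(M, 2, var)
  cEM <- vapply(seq_along(mE), function(j) cov(E[, j], M[, j]), numeric(1))
  vN <- apply(N, 2, var)
  out <- data.frame(t = ensemble$t_grid, mean_E = mE, mean_M = mM,
                    mean_N = mN, var_E = vE, var_M = vM, cov_EM = cEM,
                    var_N = vN,
                    fano_N = ifelse(mN > 0, vN / mN, NA_real_), n = n)
  if (bootstrap) {
    idx <- with_seed(boot_seed,
                     matrix(sample.int(n, n * B, replace = TRUE), B, n))
    bs <- bootstrap_count_moments(N, idx)
    out$se_mean_N <- bs$se_mean
    out$se_var_N <- bs$se_var
    out$se_fano_N <- bs$se_fano
  }
  out
}

# Bootstrap SEs of mean, variance and Fano of a replicate-by-time count
# matrix given a B x n index matrix. Vectorized per time column.
bootstrap_count_moments <- function(N, idx) {
  n <- ncol(idx)
  B <- nrow(idx)
  nt <- ncol(N)
  se_mean <- se_var <- se_fano <- numeric(nt)
  for (j in seq_len(nt)) {
    x <- N[, j]
    xb <- matrix(x[idx], B, n)
    m1 <- rowMeans(xb)
    m2 <- rowMeans(xb^2)
    vb <- (m2 - m1^2) * n / (n - 1)
    fb <- ifelse(m1 > 0, vb / m1, NA_real_)
    se_mean[j] <- sd(m1)
    se_var[j] <- sd(vb)
    se_fano[j] <- sd(fb[is.finite(fb)])
  }
  list(se_mean = se_mean, se_var = se_var, se_fano = se_fano)
}

#' Empirical distribution of the resistant fraction
#'
#' The fractions `p = M / (E + M)` across surviving replicates at grid
#' time `t`; extinct replicates (N = 0) are counted separately and
#' excluded from the moments.
#'
#' @param ensemble a `switch_ensemble`.
#' @param t a time contained in the ensemble's grid.
#' @return An object of class `fraction_distribution`: list with `t`,
#'   `fractions`, `n_extinct`, `mean`, `variance`, `n_replicates` and the
#'   surviving-population size range `N_range`.
#' @export
empirical_fraction_distribution <- function(ensemble, t) {
  stopifnot(inherits(ensemble, "switch_ensemble"))
  j <- match(TRUE, abs(ensemble$t_grid - t) < 1e-12)
  if (is.na(j)) stop("t is not on the ensemble grid")
  E <- ensemble$E[, j]
  M <- ensemble$M[, j]
  N <- E + M
  alive <- N > 0
  if (!any(alive)) stop("all replicates extinct at t = ", t)
  fr <- M[alive] / N[alive]
  structure(list(t = t, fractions = fr, n_extinct = sum(!alive),
                 mean = mean(fr),
                 variance = if (sum(alive) > 1) var(fr) else 0,
                 n_replicates = length(N),
                 N_range = range(N[alive])),
            class = "fraction_distribution")
}

#' @export
print.fraction_distribution <- function(x, ...) {
  cat(sprintf(
    "Resistant-fraction distribution at t = %g: %d surviving, %d extinct\n",
    x$t, length(x$fractions), x$n_extinct))
  cat(sprintf("  mean = %.4g, variance = %.4g, N range [%d, %d]\n",
              x$mean, x$variance, x$N_range[1], x$N_range[2]))
  invisible(x)
}
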