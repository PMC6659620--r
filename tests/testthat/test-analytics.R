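# Closed-form moments versus independent matrix-exponential oracles.

test_that("single-cell occupancy matches initial condition and expm oracle", {
  p <- drug_params()
  occ0 <- single_cell_occupancy(p, 0.2, 0)
  expect_equal(c(occ0$P_E, occ0$P_M), c(0.8, 0.2))
  # decoupled deaths
  p2 <- rate_params(mu_E = 0.3, mu_M = 0.15)
  occ <- single_cell_occupancy(p2, 0.25, c(1, 3))
  expect_equal(occ$P_E, exp(-0.3 * c(1, 3)) * 0.75, tolerance = 1e-12)
  expect_equal(occ$P_M, exp(-0.15 * c(1, 3)) * 0.25, tolerance = 1e-12)
  # expm oracle at the reference rates
  A <- matrix(c(-0.4, 0.1, 0.1, -0.25), 2, byrow = TRUE)
  o <- as.numeric(as.matrix(Matrix::expm(A * 2)) %*% c(0.8, 0.2))
  occ2 <- single_cell_occupancy(p, 0.2, 2)
  expect_equal(c(occ2$P_E, occ2$P_M), o, tolerance = 1e-10)
  expect_error(single_cell_occupancy(p, 1.5, 1), "p0")
})

test_that("single-cell generating function normalizes and matches occupancy", {
  p <- drug_params()
  expect_equal(single_cell_gf(1, 1, p, 0.4, c(0, 1, 5)), rep(1, 3))
  expect_equal(single_cell_gf(0, 0, p, 0.4, 0), 0)
  occ <- single_cell_occupancy(p, 0.2, 2)
  expect_equal(single_cell_gf(0, 1, p, 0.2, 2), 1 - occ$P_E,
               tolerance = 1e-12)
})

test_that("population generating function: normalization, N0 = 1 reduction, MC oracle", {
  ps <- random_params(20, seed = 31, drug = TRUE)
  set.seed(99)
  for (p in ps) {
    N0 <- sample(1:30, 1)
    tt <- runif(1, 0, 5)
    init <- initial_composition(N0, list(beta = c(runif(1, 0.5, 4),
                                                  runif(1, 0.5, 4))))
    expect_equal(population_gf(1, 1, p, init, tt), 1, tolerance = 1e-7)
  }
  p <- drug_params()
  init1 <- initial_composition(1, 0.3)
  expect_equal(population_gf(0.4, 0.7, p, init1, 2),
               single_cell_gf(0.4, 0.7, p, 0.3, 2), tolerance = 1e-12)
  # Monte-Carlo quadrature oracle: g is linear in p0, so draw Beta(2,2)
  # p0 values and average g(p0)^N0 directly
  init <- initial_composition(10, list(beta = c(2, 2)))
  g0 <- single_cell_gf(0.3, 0.8, p, 0, 1)
  g1 <- single_cell_gf(0.3, 0.8, p, 1, 1)
  set.seed(42)
  draws <- (g0 + rbeta(1e6, 2, 2) * (g1 - g0))^10
  mc <- mean(draws)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(population_gf(0.3, 0.8, p, init, 1) - mc), 3 * se)
})

test_that("population gf derivatives at z = 1 reproduce the mean law", {
  p <- drug_params()
  init <- initial_composition(20, list(beta = c(2, 5)))
  h <- 1e-5
  # central difference with one Richardson step in each of z1, z2
  d_at <- function(hh) {
    (population_gf(1 + hh, 1, p, init, 1.5) -
       population_gf(1 - hh, 1, p, init, 1.5)) / (2 * hh) +
      (population_gf(1, 1 + hh, p, init, 1.5) -
         population_gf(1, 1 - hh, p, init, 1.5)) / (2 * hh)
  }
  d <- (4 * d_at(h) - d_at(2 * h)) / 3
  expect_equal(d, mean_surviving_drug(p, 20, init$p0_mean, 1.5),
               tolerance = 1e-6)
})

test_that("drug-phase mean law: special cases and expm oracle", {
  p <- drug_params()
  expect_equal(mean_surviving_drug(p, 200, 0.3, 0), 200)
  # equal death rates: uniform exponential decay regardless of switching
  p2 <- rate_params(mu_E = 0.25, mu_M = 0.25, k_EM = 0.8, k_ME = 0.02)
  expect_equal(mean_surviving_drug(p2, 100, 0.7, c(1, 2, 5)),
               100 * exp(-0.25 * c(1, 2, 5)), tolerance = 1e-12)
  expect_equal(mean_surviving_drug(p, 200, 0.2, 2),
               expm_mean_drug(p, 200, 0.2, 2), tolerance = 1e-10)
  # random grid incl. degenerate alpha0 = 0 (no switching, equal deaths)
  for (pp in c(random_params(25, seed = 55, drug = TRUE),
               list(rate_params(mu_E = 0.3, mu_M = 0.3)))) {
    t <- c(0.2, 1, 4)
    expect_lt(max(rel_err(mean_surviving_drug(pp, 150, 0.4, t),
                          expm_mean_drug(pp, 150, 0.4, t))), 1e-10)
  }
  # monotone non-increasing when deaths positive
  tgrid <- seq(0, 20, 0.25)
  for (pp in random_params(20, seed = 56, drug = TRUE)) {
    m <- mean_surviving_drug(pp, 100, 0.5, tgrid)
    expect_true(all(diff(m) <= 1e-12))
  }
})

test_that("drug-phase Fano factor: bounds, vanishing heterogeneity, t = 0", {
  p <- drug_params()
  t <- seq(0.25, 15, 0.25)
  # no initial heterogeneity: strictly sub-Poissonian
  f <- fano_drug(p, 200, 0.3, 0, t)
  expect_true(all(f < 1))
  expect_true(all(f > 0))
  expect_equal(fano_drug(p, 200, 0.3, 0, 0), 0)
  expect_equal(f, 1 - mean_surviving_drug(p, 200, 0.3, t) / 200,
               tolerance = 1e-12)
  # equal death rates kill the heterogeneity term identically
  p2 <- rate_params(mu_E = 0.2, mu_M = 0.2, k_EM = 0.3, k_ME = 0.1)
  expect_equal(fano_drug(p2, 200, 0.4, 0.05, t),
               1 - mean_surviving_drug(p2, 200, 0.4, t) / 200,
               tolerance = 1e-12)
  expect_error(fano_drug(p, 200, 0.3, 0.5, 1), "p0_var")
})

test_that("heterogeneity signal: theory/empirical round trip through mean and Fano", {
  p <- drug_params()
  N0 <- 200
  t <- seq(0.5, 8, 0.5)
  p0m <- 0.3; p0v <- 0.02
  mN <- mean_surviving_drug(p, N0, p0m, t)
  f <- fano_drug(p, N0, p0m, p0v, t)
  emp <- heterogeneity_signal_empirical(f, mN, N0)
  th <- heterogeneity_signal_theory(p, p0v, t)
  expect_equal(emp, th, tolerance = 1e-10)
  expect_equal(heterogeneity_signal_theory(p, 0, t), rep(0, length(t)))
  expect_equal(heterogeneity_signal_theory(p, 0.02, 0), 0)
  # zero-heterogeneity floor maps to (numerically) zero signal
  f0 <- 1 - mN / N0
  out0 <- suppressWarnings(heterogeneity_signal_empirical(f0, mN, N0))
  expect_true(all(is.na(out0) | out0 < 1e-7))
  expect_warning(
    out <- heterogeneity_signal_empirical(f0[1] - 1e-3, mN[1], N0),
    "sub-Poissonian")
  expect_true(is.na(out))
})

test_that("growth-phase mean law: special cases and expm oracle", {
  p <- reference_growth_params()
  expect_equal(mean_growth(p, 120, 80, 0), 200)
  # pure birth-death of E only
  p2 <- rate_params(k_E = 0.4, mu_E = 0.1)
  expect_equal(mean_growth(p2, 50, 0, c(1, 2)), 50 * exp(0.3 * c(1, 2)),
               tolerance = 1e-12)
  expect_equal(mean_growth(p, 200, 0, 10),
               expm_mean_growth(p, 200, 0, 10), tolerance = 1e-10)
  for (pp in random_params(25, seed = 77, max_rate = 1)) {
    t <- c(0.5, 2, 6)
    expect_lt(max(rel_err(mean_growth(pp, 100, 40, t),
                          expm_mean_growth(pp, 100, 40, t))), 1e-10)
  }
})

test_that("second-moment ODE solution: t = 0, variance identity, expm oracle", {
  p <- reference_growth_params()
  m0 <- moments_growth(p, 200, 50, 0)
  expect_equal(m0$var_E, 0, tolerance = 1e-8)
  expect_equal(m0$var_M, 0, tolerance = 1e-8)
  expect_equal(attr(m0, "second_moments")$EM, 200 * 50)
  tg <- c(0.5, 1, 5, 10)
  for (pp in c(list(p), random_params(25, seed = 91, max_rate = 0.8))) {
    mom <- moments_growth(pp, 150, 30, tg)
    # Eq-6 identity holds by construction of var_N; check against oracle
    oracle <- expm_moments_growth(pp, 150, 30, tg)
    expect_lt(max(rel_err(mom$mean_N, oracle["mean_N", ])), 1e-9)
    expect_lt(max(rel_err(mom$var_N, oracle["var_N", ])), 1e-9)
    expect_equal(mom$var_N, mom$var_E + mom$var_M + 2 * mom$cov_EM,
                 tolerance = 1e-9)
  }
})

test_that("pure birth-death variance matches the classical closed form and SSA", {
  # classical linear birth-death: Var(t) = E0 (k+mu)/(k-mu) e^{(k-mu)t}
  #   (e^{(k-mu)t} - 1). Verify the formula itself against SSA before
  # using it as the oracle for the ODE solution.
  k <- 0.3; mu <- 0.1; E0 <- 60
  tg <- c(0, 1, 2)
  classical <- E0 * (k + mu) / (k - mu) * exp((k - mu) * tg) *
    (exp((k - mu) * tg) - 1)
  ens <- simulate_ensemble(rate_params(k_E = k, mu_E = mu), c(E0, 0), tg,
                           20000, seed = 404)
  s <- ensemble_summary(ens, B = 400, boot_seed = 2)
  expect_true(all(abs(s$var_N - classical) <= 3 * s$se_var_N + 1e-9))
  mom <- moments_growth(rate_params(k_E = k, mu_E = mu), E0, 0, tg)
  expect_equal(mom$var_N, classical, tolerance = 1e-9)
})

test_that("growth moments with births off reproduce the drug-phase laws", {
  p <- drug_params()
  pd <- rate_params(0, 0, p$mu_E, p$mu_M, p$k_EM, p$k_ME)
  tg <- c(0.5, 2, 5)
  mom <- moments_growth(pd, 160, 40, tg)
  expect_equal(mom$mean_N, mean_surviving_drug(p, 200, 0.2, tg),
               tolerance = 1e-10)
  # binomially mixed initial state: law of total variance over
  # M0 ~ Binomial(N0, p0) reproduces the sigma^2_{p0} = 0 Fano factor
  N0 <- 40; p0 <- 0.3
  probs <- dbinom(0:N0, N0, p0)
  mix <- vapply(0:N0, function(m0) {
    mm <- moments_growth(pd, N0 - m0, m0, tg)
    rbind(mm$mean_N, mm$var_N)
  }, matrix(0, 2, length(tg)))
  mmix <- apply(mix, c(1, 2), function(x) sum(x * probs))
  m2 <- vapply(seq_along(tg), function(j) {
    sum((mix[1, j, ]^2 + mix[2, j, ]) * probs)
  }, numeric(1))
  vmix <- m2 - mmix[1, ]^2
  expect_equal(vmix / mmix[1, ], fano_drug(p, N0, p0, 0, tg),
               tolerance = 1e-9)
})
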