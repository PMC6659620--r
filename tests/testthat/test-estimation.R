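# Estimation: round trips on noiseless analytic curves, inversion
# identities, heterogeneity estimators, and small-scale SSA sanity runs
# (the full-scale recovery studies live in test-acceptance.R).

noiseless_drug_series <- function(p, N0, p0, t) {
  moment_time_series(t, mean_surviving_drug(p, N0, p0, t), N0 = N0,
                     label = sprintf("p0=%g", p0))
}

test_that("drug mean-curve fit recovers composites from noiseless data", {
  p <- drug_params()  # mu_E 0.3, gamma0 0.65, alpha0 0.25
  t <- seq(0.5, 10, 0.5)
  f <- fit_drug_mean_curve(noiseless_drug_series(p, 200, 0, t), seed = 2)
  expect_lt(rel_err(f$mu_E, 0.3), 1e-6)
  expect_lt(rel_err(f$gamma0, 0.65), 1e-6)
  expect_lt(rel_err(f$alpha0, 0.25), 1e-6)
  expect_length(f$flags, 0)
})

test_that("drug mean-curve fit flags near-single-exponential data", {
  # k_EM = 0 from p0 = 0: N decays as a single exponential at mu_E + k_EM
  p <- rate_params(mu_E = 0.3, mu_M = 0.15, k_EM = 0, k_ME = 0.2)
  t <- seq(0.5, 10, 0.5)
  s <- noiseless_drug_series(p, 200, 0, t)
  f <- fit_drug_mean_curve(s, seed = 3)
  expect_lt(abs(f$mu_E - 0.3), 1e-3)
  m <- phenoswitch:::drug_mean_fraction_comp(f$gamma0, f$alpha0, f$mu_E, t)
  expect_lt(max(abs(m - s$mean_N / 200)), 1e-8)
})

test_that("mu_M fit recovers from noiseless all-resistant data", {
  p <- drug_params()
  dr <- drug_phase_rates(p)
  t <- seq(0.5, 10, 0.5)
  f <- fit_drug_mu_M(noiseless_drug_series(p, 200, 1, t),
                     dr$gamma0, dr$alpha0)
  expect_lt(rel_err(f$mu_M, 0.15), 1e-6)
})

test_that("switching-rate inversions are exact identities", {
  sw <- invert_drug_rates(0.65, 0.25, 0.3, 0.15)
  expect_equal(sw$k_EM, 0.1, tolerance = 1e-12)
  expect_equal(sw$k_ME, 0.1, tolerance = 1e-12)
  # no switching
  sw0 <- invert_drug_rates(0.42, 0.18, 0.3, 0.12)
  expect_equal(c(sw0$k_EM, sw0$k_ME), c(0, 0), tolerance = 1e-10)
  # round trip over a random grid (drug and growth patterns)
  set.seed(11)
  for (i in 1:200) {
    r <- runif(4, 0.01, 2)          # mu_E, mu_M, k_EM, k_ME
    if (abs(r[1] - r[2]) < 0.05) next
    p <- rate_params(mu_E = r[1], mu_M = r[2], k_EM = r[3], k_ME = r[4])
    dr <- drug_phase_rates(p)
    sw <- invert_drug_rates(dr$gamma0, dr$alpha0, r[1], r[2])
    expect_lt(max(abs(c(sw$k_EM - r[3], sw$k_ME - r[4]))), 1e-10)
    g <- runif(2, -1, 1)            # kEf, kMf
    if (abs(g[1] - g[2]) < 0.05) next
    cr <- phenoswitch:::composite_rates(g[1], g[2], r[3], r[4])
    swg <- invert_growth_rates(cr$gamma, cr$alpha, g[1], g[2])
    expect_lt(max(abs(c(swg$k_EM - r[3], swg$k_ME - r[4]))), 1e-10)
  }
  expect_error(invert_drug_rates(0.6, 0.2, 0.2, 0.2), "non-identifiable")
  expect_error(invert_growth_rates(0.4, 0.2, 0.1, 0.1), "degenerate")
})

test_that("heterogeneity estimators: boundary cases and exact analytic round trip", {
  p <- drug_params()
  N0 <- 200
  t <- seq(0.5, 8, 0.5)
  m0 <- mean_surviving_drug(p, N0, 0, t)
  m1 <- mean_surviving_drug(p, N0, 1, t)
  # <N> equal to a pure-condition mean pins p0 to the boundary
  h0 <- estimate_initial_heterogeneity(m0, 1 - m0 / N0, m0, m1, N0)
  expect_equal(h0$p0_mean, 0, tolerance = 1e-12)
  expect_equal(h0$p0_var, 0, tolerance = 1e-12)
  h1 <- estimate_initial_heterogeneity(m1, 1 - m1 / N0, m0, m1, N0)
  expect_equal(h1$p0_mean, 1, tolerance = 1e-12)
  # exact recovery from the closed-form mean and Fano factor
  p0 <- 0.3; v0 <- 0.02
  mm <- mean_surviving_drug(p, N0, p0, t)
  ff <- fano_drug(p, N0, p0, v0, t)
  h <- estimate_initial_heterogeneity(mm, ff, m0, m1, N0)
  expect_equal(h$p0_mean, p0, tolerance = 1e-10)
  expect_equal(h$p0_var, v0, tolerance = 1e-10)
  expect_lt(max(abs(h$per_time$p0 - p0)), 1e-10)
  expect_lt(max(abs(h$per_time$p0_var - v0)), 1e-10)
  # non-identifiable when the companion means coincide
  expect_error(estimate_initial_heterogeneity(mm, ff, m0, m0, N0),
               "non-identifiable")
})

test_that("heterogeneity estimates are invariant under time rescaling", {
  p <- drug_params()
  c_ <- 3.7
  pc <- rate_params(mu_E = c_ * p$mu_E, mu_M = c_ * p$mu_M,
                    k_EM = c_ * p$k_EM, k_ME = c_ * p$k_ME)
  N0 <- 150; p0 <- 0.4; v0 <- 0.03
  t <- seq(0.5, 6, 0.5)
  run <- function(pp, tt) {
    estimate_initial_heterogeneity(
      mean_surviving_drug(pp, N0, p0, tt),
      fano_drug(pp, N0, p0, v0, tt),
      mean_surviving_drug(pp, N0, 0, tt),
      mean_surviving_drug(pp, N0, 1, tt), N0)
  }
  a <- run(p, t); b <- run(pc, t / c_)
  expect_equal(a$p0_mean, b$p0_mean, tolerance = 1e-10)
  expect_equal(a$p0_var, b$p0_var, tolerance = 1e-10)
})

test_that("growth mean-curve fit recovers effective and switching rates", {
  p <- reference_growth_params()
  t <- seq(0.5, 20, 0.5)
  sE <- moment_time_series(t, mean_growth(p, 200, 0, t), N0 = 200,
                           E0 = 200, M0 = 0)
  sM <- moment_time_series(t, mean_growth(p, 0, 200, t), N0 = 200,
                           E0 = 0, M0 = 200)
  f <- fit_growth_mean_curves(sE, sM, seed = 4)
  expect_lt(max(abs(c(f$kEf + 0.1, f$kMf + 0.05,
                      f$k_EM - 0.1, f$k_ME - 0.1))), 1e-6)
  # no switching: two independent exponentials
  p0 <- rate_params(k_E = 0.2, k_M = 0.1, mu_E = 0.3, mu_M = 0.15)
  sE0 <- moment_time_series(t, mean_growth(p0, 200, 0, t), N0 = 200,
                            E0 = 200, M0 = 0)
  sM0 <- moment_time_series(t, mean_growth(p0, 0, 200, t), N0 = 200,
                            E0 = 0, M0 = 200)
  f0 <- fit_growth_mean_curves(sE0, sM0, seed = 5)
  expect_lt(max(abs(c(f0$k_EM, f0$k_ME))), 1e-5)
})

test_that("full growth fit separates birth from death on a short noiseless grid", {
  p <- reference_growth_params()
  t <- seq(1, 10, 1)
  mk <- function(E0, M0) {
    mom <- moments_growth(p, E0, M0, t)
    moment_time_series(t, mom$mean_N, mom$var_N, NULL, E0 + M0,
                       E0 = E0, M0 = M0)
  }
  sE <- mk(200, 0); sM <- mk(0, 200)
  pre <- fit_growth_mean_curves(sE, sM, seed = 6)
  f <- fit_growth_full(list(sE, sM), n_starts = 4, seed = 7,
                       init_rates = pre)
  est <- unlist(f[c("k_E", "k_M", "mu_E", "mu_M", "k_EM", "k_ME")])
  truth <- c(0.2, 0.1, 0.3, 0.15, 0.1, 0.1)
  expect_lt(max(rel_err(est, truth)), 1e-3)
})

test_that("small-scale SSA drug protocol lands near the truth", {
  p <- drug_params()
  tg <- c(0, seq(0.5, 10, 0.5))
  e0 <- simulate_ensemble(p, initial_composition(200, 0), tg, 2000,
                          seed = 71)
  e1 <- simulate_ensemble(p, initial_composition(200, 1), tg, 2000,
                          seed = 72)
  em <- simulate_ensemble(p, initial_composition(200, list(beta = c(2, 5))),
                          tg, 2000, seed = 73)
  rep_ <- estimate_drug_protocol(em, e0, e1, N0 = 200, B = 100, seed = 74)
  est <- rep_$estimates
  expect_lt(abs(est["mu_E"] - 0.3), 0.02)
  expect_lt(abs(est["mu_M"] - 0.15), 0.03)
  expect_lt(abs(est["k_EM"] - 0.1), 0.03)
  expect_lt(abs(est["k_ME"] - 0.1), 0.05)
  expect_lt(abs(est["p0_mean"] - 2 / 7), 0.02)
  expect_lt(abs(est["p0_var"] - 10 / (49 * 8)), 0.006)
  expect_true(all(rep_$ci[, "lower"] <= rep_$ci[, "upper"]))
})

test_that("phase comparison labels selection, adaptation and inconclusive cases", {
  mk_report <- function(est, half) {
    ci <- cbind(lower = est - half, upper = est + half)
    rownames(ci) <- names(est)
    structure(list(estimates = est, ci = ci, level = 0.95, B = 1,
                   phase = "x"), class = "estimation_report")
  }
  pre <- mk_report(c(k_EM = 0.1, k_ME = 0.1, mu_E = 0.05, mu_M = 0.05),
                   0.02)
  post_sel <- mk_report(c(k_EM = 0.1, k_ME = 0.1, mu_E = 0.4, mu_M = 0.3),
                        0.02)
  expect_equal(compare_phases(pre, post_sel)$label, "selection-dominant")
  post_ad <- mk_report(c(k_EM = 0.2, k_ME = 0.1, mu_E = 0.05,
                         mu_M = 0.05), 0.02)
  expect_equal(compare_phases(pre, post_ad)$label, "adaptation-indicated")
  post_null <- mk_report(c(k_EM = 0.1, k_ME = 0.1, mu_E = 0.05,
                           mu_M = 0.05), 0.02)
  expect_equal(compare_phases(pre, post_null)$label, "inconclusive")
})
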