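# Shared fixtures and independent oracles.
# Matrix::expm is the matrix-exponential oracle throughout; the package's
# own closed forms / eigen solver are the implementation under test.

reference_growth_params <- function(k_EM = 0.1, k_ME = 0.1) {
  rate_params(k_E = 0.2, k_M = 0.1, mu_E = 0.3, mu_M = 0.15,
              k_EM = k_EM, k_ME = k_ME)
}

drug_params <- function() {
  rate_params(mu_E = 0.3, mu_M = 0.15, k_EM = 0.1, k_ME = 0.1)
}

random_params <- function(n, seed, max_rate = 2, drug = FALSE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    r <- runif(6, 0, max_rate)
    if (drug) r[1:2] <- 0
    rate_params(r[1], r[2], r[3], r[4], r[5], r[6])
  })
}

# Oracle: mean surviving count via Matrix::expm of the 2x2 system.
expm_mean_drug <- function(p, N0, p0, t) {
  A <- matrix(c(-(p$k_EM + p$mu_E), p$k_ME,
                p$k_EM, -(p$k_ME + p$mu_M)), 2, byrow = TRUE)
  vapply(t, function(tt) {
    N0 * sum(as.matrix(Matrix::expm(A * tt)) %*% c(1 - p0, p0))
  }, numeric(1))
}

expm_mean_growth <- function(p, E0, M0, t) {
  B <- matrix(c(p$k_E - p$mu_E - p$k_EM, p$k_ME,
                p$k_EM, p$k_M - p$mu_M - p$k_ME), 2, byrow = TRUE)
  vapply(t, function(tt) {
    sum(as.matrix(Matrix::expm(B * tt)) %*% c(E0, M0))
  }, numeric(1))
}

# Oracle: first+second moment system solved by Matrix::expm (5x5),
# independent of the package's eigendecomposition path.
expm_moments_growth <- function(p, E0, M0, t) {
  A <- phenoswitch:::moment_ode_matrix(p)
  x0 <- c(E0, M0, E0^2, M0^2, E0 * M0)
  vapply(t, function(tt) {
    x <- as.numeric(Matrix::expm(A * tt) %*% x0)
    mN <- x[1] + x[2]
    vN <- (x[3] - x[1]^2) + (x[4] - x[2]^2) + 2 * (x[5] - x[1] * x[2])
    c(mean_N = mN, var_N = vN)
  }, numeric(2))
}

# As above but also exposing the raw second moments.
expm_second_moments <- function(p, E0, M0, t) {
  A <- phenoswitch:::moment_ode_matrix(p)
  x0 <- c(E0, M0, E0^2, M0^2, E0 * M0)
  vapply(t, function(tt) {
    x <- as.numeric(Matrix::expm(A * tt) %*% x0)
    mN <- x[1] + x[2]
    vN <- (x[3] - x[1]^2) + (x[4] - x[2]^2) + 2 * (x[5] - x[1] * x[2])
    c(mean_N = mN, var_N = vN, EE = x[3], MM = x[4], EM = x[5])
  }, numeric(5))
}

rel_err <- function(a, b) {
  abs(a - b) / pmax(abs(b), 1e-8)
}
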