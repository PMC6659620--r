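# Internal numerical helpers.

# sinh(x)/x with a series branch so composite-rate limits (alpha -> 0) are
# evaluated smoothly instead of 0/0.
sinhc <- function(x) {
  out <- rep(1, length(x))
  big <- abs(x) >= 1e-4
  out[big] <- sinh(x[big]) / x[big]
  small <- !big
  xs <- x[small]
  out[small] <- 1 + xs^2 / 6 + xs^4 / 120
  out
}

# Run code with a given R RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Per-replicate path seeds from a master seed: a plain counter scheme.
# master < 2^31 and n < 2^20 keep every seed exact in a double and the
# seed ranges of distinct masters disjoint.
spawn_path_seeds <- function(master, n) {
  master <- as.double(master)
  stopifnot(is.finite(master), master >= 0, master < 2^31, n < 2^20)
  master * 2^20 + seq_len(n)
}

# Latin-hypercube starting points for multi-start fits (n x d), in [0,1]^d
# then scaled to [lower, upper].
lhs_starts <- function(n, lower, upper, seed) {
  d <- length(lower)
  with_seed(seed, {
    u <- vapply(seq_len(d), function(j) {
      (sample.int(n) - runif(n)) / n
    }, numeric(n))
  })
  u <- matrix(u, nrow = n)
  sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable evaluation of the bi-exponential kernel
#   e^{-g t/2} [A cosh(a t/2) + B sinh(a t/2)/a]
# For small a*t/2 the cosh/sinhc form is exact as a -> 0; for large a*t/2
# that form cancels catastrophically (cosh and sinh both grow like
# e^{a t/2} while the result decays), so the two-mode form
#   (A + B/a)/2 e^{-(g-a)t/2} + (A - B/a)/2 e^{-(g+a)t/2}
# is used instead, whose terms never exceed the coefficients.
biexp_kernel <- function(g, a, A, B, t) {
  x <- a * t / 2
  small <- x < 1
  out <- numeric(length(t))
  if (any(small)) {
    ts <- t[small]
    out[small] <- exp(-g * ts / 2) *
      (A * cosh(a * ts / 2) + B * (ts / 2) * sinhc(a * ts / 2))
  }
  if (any(!small)) {
    tl <- t[!small]
    out[!small] <- (A + B / a) / 2 * exp(-(g - a) * tl / 2) +
      (A - B / a) / 2 * exp(-(g + a) * tl / 2)
  }
  out
}
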