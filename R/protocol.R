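# Full estimation protocols with nonparametric bootstrap uncertainty.
# Replicates are the resampling unit; every bootstrap resample re-runs the
# whole estimation chain (single-start at the point estimates, for speed).

counts_from <- function(x) {
  if (inherits(x, "switch_ensemble")) {
    list(N = x$E + x$M, t = x$t_grid)
  } else if (is.matrix(x)) {
    list(N = x, t = NULL)
  } else {
    stop("expected a switch_ensemble or a replicate-by-time count matrix")
  }
}

summarize_counts <- function(N) {
  m <- colMeans(N)
  v <- apply(N, 2, var)
  list(mean = m, var = v, fano = ifelse(m > 0, v / m, NA_real_))
}

# One pass of the drug-phase chain from per-time summaries.
# When `start` is given, the p0 = 0 fit is single-start from it.
drug_chain <- function(t, N0, sum0, sum1, summ, n,
                       start = NULL, n_starts = 8, seed = 1) {
  s0 <- moment_time_series(t, sum0$mean, sum0$var, n, N0, "p0=0")
  if (is.null(start)) {
    f0 <- fit_drug_mean_curve(s0, n_starts = n_starts, seed = seed)
  } else {
    w <- series_weights(s0)
    y <- s0$mean_N / N0
    obj <- function(th) {
      m <- drug_mean_fraction_comp(th[2], th[3] * th[2], th[1], t)
      sum((w * (y - m))^2)
    }
    g0 <- max(start$gamma0, 1e-6)
    f <- nlminb(c(start$mu_E, g0, min(start$alpha0 / g0, 1)), obj,
                lower = c(0, 1e-8, 0),
                upper = c(10 * g0 + 1, 10 * g0 + 1, 1))
    f0 <- list(mu_E = f$par[1], gamma0 = f$par[2],
               alpha0 = f$par[3] * f$par[2])
  }
  s1 <- moment_time_series(t, sum1$mean, sum1$var, n, N0, "p0=1")
  f1 <- fit_drug_mu_M(s1, f0$gamma0, f0$alpha0)
  sw <- invert_drug_rates(f0$gamma0, f0$alpha0, f0$mu_E, f1$mu_M)
  den <- summ$mean - sum0$mean
  den1 <- sum1$mean - sum0$mean
  p0_t <- den / den1
  var_t <- N0 * summ$mean / (den1^2 * (N0 - 1)) *
    (summ$fano - 1 + summ$mean / N0)
  list(mu_E = f0$mu_E, mu_M = f1$mu_M, gamma0 = f0$gamma0,
       alpha0 = f0$alpha0, k_EM = sw$k_EM, k_ME = sw$k_ME,
       p0_t = p0_t, var_t = var_t)
}

#' Drug-phase estimation protocol with bootstrap confidence intervals
#'
#' Runs the full designed-initial-condition protocol on replicate count
#' data from three drug-phase experiments (all-sensitive `p0 = 0`,
#' all-resistant `p0 = 1`, and the heterogeneous condition of interest):
#' fits \eqn{(\mu_E, \gamma_0, \alpha_0)} and \eqn{\mu_M}, inverts for the
#' switching rates, and estimates \eqn{(\langle p_0\rangle,
#' \sigma^2_{p_0})} per time point, combining times by inverse
#' bootstrap-variance weights. Percentile confidence intervals come from
#' resampling replicates and re-running the whole chain.
#'
#' @param mixed,p0_cond,p1_cond `switch_ensemble` objects or
#'   replicate-by-time total-count matrices on a common `t_grid` for the
#'   mixed, `p0 = 0` and `p0 = 1` conditions.
#' @param t_grid observation times (taken from the ensembles when given).
#' @param N0 initial sample size.
#' @param B bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap resampling.
#' @param n_starts multi-start count for the point-estimate fit.
#' @param level confidence level.
#' @return An object of class `estimation_report` with `estimates`,
#'   percentile `ci`, per-time heterogeneity estimates and diagnostics.
#' @export
estimate_drug_protocol <- function(mixed, p0_cond, p1_cond, t_grid = NULL,
                                   N0, B = 1000, seed = 1, n_starts = 8,
                                   level = 0.95) {
  cm <- counts_from(mixed); c0 <- counts_from(p0_cond)
  c1 <- counts_from(p1_cond)
  t_grid <- t_grid %||% cm$t
  if (is.null(t_grid)) stop("t_grid required with matrix inputs")
  keep <- t_grid > 0
  t <- t_grid[keep]
  Nm <- cm$N[, keep, drop = FALSE]
  N0m <- c0$N[, keep, drop = FALSE]
  N1m <- c1$N[, keep, drop = FALSE]
  n <- nrow(Nm)
  point <- drug_chain(t, N0, summarize_counts(N0m), summarize_counts(N1m),
                      summarize_counts(Nm), n, n_starts = n_starts,
                      seed = seed)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  nms <- c("mu_E", "mu_M", "k_EM", "k_ME", "gamma0", "alpha0")
  boot <- matrix(NA_real_, B, length(nms), dimnames = list(NULL, nms))
  boot_p0 <- boot_var <- matrix(NA_real_, B, length(t))
  n_fail <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      ib <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(
        drug_chain(t, N0, summarize_counts(N0m[ib, , drop = FALSE]),
                   summarize_counts(N1m[ib, , drop = FALSE]),
                   summarize_counts(Nm[ib, , drop = FALSE]), n,
                   start = point),
        error = function(e) NULL)
      if (is.null(res)) { n_fail <- n_fail + 1L; next }
      boot[b, ] <- unlist(res[nms])
      boot_p0[b, ] <- pmin(pmax(res$p0_t, 0), 1)
      boot_var[b, ] <- pmax(res$var_t, 0)
    }
  })
  # inverse-bootstrap-variance weights for the per-time combination
  w_p0 <- 1 / pmax(apply(boot_p0, 2, var, na.rm = TRUE), 1e-12)
  w_var <- 1 / pmax(apply(boot_var, 2, var, na.rm = TRUE), 1e-12)
  het <- estimate_initial_heterogeneity(
    summarize_counts(Nm)$mean, summarize_counts(Nm)$fano,
    summarize_counts(N0m)$mean, summarize_counts(N1m)$mean, N0,
    weights = w_p0)
  var_comb <- estimate_initial_heterogeneity(
    summarize_counts(Nm)$mean, summarize_counts(Nm)$fano,
    summarize_counts(N0m)$mean, summarize_counts(N1m)$mean, N0,
    weights = w_var)
  estimates <- c(unlist(point[nms]), p0_mean = het$p0_mean,
                 p0_var = var_comb$p0_var)
  comb_boot <- cbind(
    boot,
    p0_mean = as.numeric(boot_p0 %*% w_p0 / sum(w_p0)),
    p0_var = as.numeric(boot_var %*% w_var / sum(w_var)))
  ci <- t(apply(comb_boot, 2, quantile, probs = qs, na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  structure(list(estimates = estimates, ci = ci, level = level, B = B,
                 n_boot_failures = n_fail,
                 per_time = data.frame(t = t, p0 = point$p0_t,
                                       p0_var = point$var_t,
                                       w_p0 = w_p0, w_var = w_var),
                 flags = unique(c(het$flags, var_comb$flags)),
                 phase = "drug"),
            class = "estimation_report")
}

#' Growth-phase estimation protocol with bootstrap confidence intervals
#'
#' Point estimates via [fit_growth_full()] on cross-replicate mean and
#' variance trajectories (optionally initialized through
#' [fit_growth_mean_curves()] when both pure conditions are supplied),
#' with percentile bootstrap confidence intervals from resampling
#' replicates and refitting (single-start at the point estimate).
#'
#' @param conditions a named list of conditions; each element a list with
#'   `counts` (`switch_ensemble` or replicate-by-time total-count matrix),
#'   `E0`, `M0` and optionally `t_grid`.
#' @inheritParams estimate_drug_protocol
#' @return An object of class `estimation_report`.
#' @export
estimate_growth_protocol <- function(conditions, t_grid = NULL, B = 200,
                                     seed = 1, n_starts = 8,
                                     level = 0.95) {
  built <- lapply(conditions, function(cond) {
    cc <- counts_from(cond$counts)
    tg <- cond$t_grid %||% cc$t %||% t_grid
    if (is.null(tg)) stop("each condition needs a t_grid")
    keep <- tg > 0
    list(N = cc$N[, keep, drop = FALSE], t = tg[keep],
         E0 = cond$E0, M0 = cond$M0)
  })
  mk_series <- function(bc, N) {
    s <- summarize_counts(N)
    moment_time_series(bc$t, s$mean, s$var, nrow(N), bc$E0 + bc$M0,
                       E0 = bc$E0, M0 = bc$M0)
  }
  series <- lapply(built, function(bc) mk_series(bc, bc$N))
  # initialize from the two pure mean curves when both are present
  iE <- Position(function(s) (s$M0 %||% 1) == 0 && (s$E0 %||% 0) > 0,
                 series)
  iM <- Position(function(s) (s$E0 %||% 1) == 0 && (s$M0 %||% 0) > 0,
                 series)
  init_rates <- if (!is.na(iE) && !is.na(iM)) {
    tryCatch(fit_growth_mean_curves(series[[iE]], series[[iM]],
                                    seed = seed),
             error = function(e) NULL)
  } else NULL
  fit <- fit_growth_full(series, n_starts = n_starts, seed = seed,
                         init_rates = init_rates)
  nms <- c("k_E", "k_M", "mu_E", "mu_M", "k_EM", "k_ME")
  point <- unlist(fit[nms])
  boot <- matrix(NA_real_, B, length(nms), dimnames = list(NULL, nms))
  n_fail <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      sb <- lapply(built, function(bc) {
        ib <- sample.int(nrow(bc$N), nrow(bc$N), replace = TRUE)
        mk_series(bc, bc$N[ib, , drop = FALSE])
      })
      res <- tryCatch({
        f <- nlminb(point, growth_full_objective(sb),
                    lower = rep(0, 6), upper = rep(5, 6),
                    control = list(iter.max = 200, eval.max = 500))
        f$par
      }, error = function(e) NULL)
      if (is.null(res)) { n_fail <- n_fail + 1L; next }
      boot[b, ] <- res
    }
  })
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(boot, 2, quantile, probs = qs, na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  structure(list(estimates = point, ci = ci, level = level, B = B,
                 n_boot_failures = n_fail, fit = fit,
                 flags = fit$flags, phase = "growth"),
            class = "estimation_report")
}

#' @export
print.estimation_report <- function(x, ...) {
  cat(sprintf("%s-phase estimation report (%.0f%% percentile bootstrap, B = %d)\n",
              x$phase, 100 * x$level, x$B))
  tab <- cbind(estimate = x$estimates,
               x$ci[names(x$estimates), , drop = FALSE])
  print(round(tab, 5))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

ci_overlap <- function(ci_a, ci_b) {
  ci_a["lower"] <= ci_b["upper"] && ci_b["lower"] <= ci_a["upper"]
}

#' Compare pre- and post-drug estimates: adaptation vs selection
#'
#' Compares switching-rate and death-rate estimates between a growth-phase
#' (pre-drug) and a drug-phase (post-drug) [estimation_report]. Unchanged
#' switching rates with increased death rates favor selection of
#' pre-existing phenotypes as the driver of resistance; a clear shift in
#' the switching rates indicates a role for drug-induced adaptation. The
#' output is a labelled summary of confidence-interval overlaps, not a
#' hypothesis test.
#'
#' @param report_pre,report_post `estimation_report`s for the growth
#'   (pre-drug) and drug (post-drug) phases.
#' @return A list with the `label` (`"selection-dominant"`,
#'   `"adaptation-indicated"` or `"inconclusive"`) and the per-parameter
#'   comparison table.
#' @export
compare_phases <- function(report_pre, report_post) {
  stopifnot(inherits(report_pre, "estimation_report"),
            inherits(report_post, "estimation_report"))
  cmp_one <- function(nm) {
    a <- report_pre$ci[nm, ]; b <- report_post$ci[nm, ]
    data.frame(parameter = nm,
               pre = unname(report_pre$estimates[nm]),
               post = unname(report_post$estimates[nm]),
               overlap = ci_overlap(a, b),
               post_higher = b["lower"] > a["upper"])
  }
  common <- intersect(c("k_EM", "k_ME", "mu_E", "mu_M"),
                      intersect(names(report_pre$estimates),
                                names(report_post$estimates)))
  tab <- do.call(rbind, lapply(common, cmp_one))
  rownames(tab) <- NULL
  sw <- tab[tab$parameter %in% c("k_EM", "k_ME"), ]
  mu <- tab[tab$parameter %in% c("mu_E", "mu_M"), ]
  label <- if (nrow(sw) && any(!sw$overlap)) {
    "adaptation-indicated"
  } else if (nrow(sw) && all(sw$overlap) && nrow(mu) && any(mu$post_higher)) {
    "selection-dominant"
  } else {
    "inconclusive"
  }
  list(label = label, comparison = tab)
}
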