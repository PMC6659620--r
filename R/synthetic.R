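# Seeded generator of complete in-silico experiments with known ground
# truth, producing the CSV/JSON dialects consumed by the estimation
# functions. Demographic (birth-death-switching) noise is the only noise
# layer by default; an optional binomial subsampling layer emulates
# counting a fraction of each well.

#' Design of a synthetic switching experiment
#'
#' @param phase `"drug"` (births forced to zero) or `"growth"`.
#' @param params ground-truth [rate_params()].
#' @param conditions named list of initial conditions; each element either
#'   an [initial_composition()] or a numeric `c(E0, M0)`.
#' @param times increasing sampling times (0 is prepended if absent).
#' @param n_replicates replicates per condition (>= 2).
#' @param seed master seed; condition `i` uses path seeds derived from
#'   `seed + i` (see [simulate_ensemble()]).
#' @param subsample optional detection probability in (0, 1\]; counts are
#'   binomially thinned at observation when < 1.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(phase = c("drug", "growth"), params,
                              conditions, times, n_replicates, seed,
                              subsample = 1) {
  phase <- match.arg(phase)
  p <- as_rate_params(params)
  if (phase == "drug") {
    p <- rate_params(0, 0, p$mu_E, p$mu_M, p$k_EM, p$k_ME)
  }
  if (is.null(names(conditions)) || any(names(conditions) == "") ||
      anyDuplicated(names(conditions)))
    stop("conditions must have unique non-empty names")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (times[1] > 0) times <- c(0, times)
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (subsample <= 0 || subsample > 1) stop("subsample must be in (0, 1]")
  structure(list(phase = phase, params = p, conditions = conditions,
                 times = times, n_replicates = n_replicates, seed = seed,
                 subsample = subsample),
            class = "experiment_design")
}

#' Default reference experiment designs
#'
#' The package's reference in-silico experiment: birth rates 0.2 (E) and
#' 0.1 (M), death rates 0.3 (E) and 0.15 (M), switching ratio
#' `k_EM / k_ME` selectable among 0.1, 1 and 10 with `k_ME = 0.1` held
#' fixed (the package's convention; only the ratio is canonical), sampled
#' at t = 0.1, 1, 10, 20 from 200 sensitive cells. The drug-phase
#' companion design keeps the same death and switching rates, suppresses
#' births, and runs three conditions (`p0 = 0`, `p0 = 1`, and a
#' Beta(2, 5)-heterogeneous condition) on a finer grid.
#'
#' @param phase `"growth"` or `"drug"`.
#' @param switch_ratio `k_EM / k_ME`, one of 0.1, 1, 10 (growth phase).
#' @param n_replicates replicates per condition.
#' @param seed master seed.
#' @return An [experiment_design()].
#' @export
default_experiment_design <- function(phase = c("growth", "drug"),
                                      switch_ratio = 1,
                                      n_replicates = 10000, seed = 1) {
  phase <- match.arg(phase)
  k_ME <- 0.1
  if (phase == "growth") {
    params <- rate_params(k_E = 0.2, k_M = 0.1, mu_E = 0.3, mu_M = 0.15,
                          k_EM = switch_ratio * k_ME, k_ME = k_ME)
    experiment_design("growth", params,
                      conditions = list(`E0-only` = c(200, 0)),
                      times = c(0.1, 1, 10, 20),
                      n_replicates = n_replicates, seed = seed)
  } else {
    params <- rate_params(mu_E = 0.3, mu_M = 0.15,
                          k_EM = switch_ratio * k_ME, k_ME = k_ME)
    experiment_design("drug", params,
                      conditions = list(
                        `p0=0` = initial_composition(200, 0),
                        `p0=1` = initial_composition(200, 1),
                        mixed = initial_composition(200,
                                                    list(beta = c(2, 5)))),
                      times = seq(0.5, 10, by = 0.5),
                      n_replicates = n_replicates, seed = seed)
  }
}

#' Generate a synthetic experiment
#'
#' Simulates every condition of a design with the exact SSA, returning
#' per-condition ensembles, [moment_time_series()] summaries, a tidy raw
#' count table, and the ground truth (kept in a separate element so
#' estimation code cannot silently read it). Bit-reproducible from the
#' design's master seed.
#'
#' @param design an [experiment_design()].
#' @param bootstrap compute bootstrap standard errors in the summaries?
#' @return A list of class `synthetic_experiment` with `ensembles`,
#'   `series`, `counts` (data frame `condition`, `sample_id`, `time`,
#'   `E`, `M`, `N`) and `ground_truth`.
#' @export
generate_experiment <- function(design, bootstrap = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  ensembles <- list()
  series <- list()
  counts <- list()
  for (i in seq_along(design$conditions)) {
    nm <- names(design$conditions)[i]
    cond <- design$conditions[[i]]
    ens <- simulate_ensemble(design$params, cond, design$times,
                             design$n_replicates, seed = design$seed + i)
    if (design$subsample < 1) {
      ens$E[] <- with_seed(design$seed + i + 500000L,
                           rbinom(length(ens$E), ens$E, design$subsample))
      ens$M[] <- with_seed(design$seed + i + 900000L,
                           rbinom(length(ens$M), ens$M, design$subsample))
    }
    ensembles[[nm]] <- ens
    sm <- ensemble_summary(ens, bootstrap = bootstrap,
                           boot_seed = design$seed + i)
    N0 <- if (inherits(cond, "initial_composition")) cond$N0 else sum(cond)
    E0 <- if (inherits(cond, "initial_composition")) NULL else cond[1]
    M0 <- if (inherits(cond, "initial_composition")) NULL else cond[2]
    series[[nm]] <- moment_time_series(sm$t[-1], sm$mean_N[-1],
                                       sm$var_N[-1], sm$n[-1], N0,
                                       label = nm, E0 = E0, M0 = M0)
    nt <- length(design$times)
    counts[[nm]] <- data.frame(
      condition = nm,
      sample_id = rep(seq_len(design$n_replicates), nt),
      time = rep(design$times, each = design$n_replicates),
      E = as.vector(ens$E), M = as.vector(ens$M),
      N = as.vector(ens$E + ens$M))
  }
  structure(list(ensembles = ensembles, series = series,
                 counts = do.call(rbind, counts),
                 ground_truth = list(params = design$params,
                                     phase = design$phase,
                                     seed = design$seed)),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "Synthetic %s-phase experiment: %d conditions x %d replicates\n",
    x$ground_truth$phase, length(x$ensembles),
    x$ensembles[[1]]$n_replicates))
  invisible(x)
}
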