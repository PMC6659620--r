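# Plain-text interchange: JSON parameter/composition files, CSV count and
# moment tables, and JSON provenance sidecars.

#' Read and write rate-parameter JSON files
#'
#' The JSON schema is a flat object with the six rate fields:
#' `{"k_E": ..., "k_M": ..., "mu_E": ..., "mu_M": ..., "k_EM": ...,
#' "k_ME": ...}`. Missing fields default to zero.
#'
#' @param path file path.
#' @return `read_rate_params` returns a [rate_params()].
#' @export
read_rate_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(rate_params, x[intersect(names(x),
                                   c("k_E", "k_M", "mu_E", "mu_M",
                                     "k_EM", "k_ME"))])
}

#' @rdname read_rate_params
#' @param params a [rate_params()].
#' @export
write_rate_params <- function(params, path) {
  p <- as_rate_params(params)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an initial-composition JSON file
#'
#' Schema: `{"N0": n, "p0": scalar | {"beta": [a, b]} |
#' {"empirical": [...]}, "mode": "binomial" | "deterministic"}`.
#'
#' @param path file path.
#' @return An [initial_composition()].
#' @export
read_initial_composition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p0 <- x$p0
  if (is.list(p0) || is.numeric(p0) && length(p0) == 1) {
    # scalar stays scalar; {"beta": [...]} parses to a list
  } else stop("unrecognized p0 specification")
  initial_composition(x$N0, p0, mode = x$mode %||% "binomial")
}

#' Write/read tidy count tables
#'
#' Columns `sample_id`, `time`, and either `N` or both `E` and `M` (an
#' optional `condition` column groups designed experiments).
#'
#' @param counts a data frame of counts.
#' @param path file path.
#' @export
write_counts_csv <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- read.csv(path)
  need <- c("sample_id", "time")
  if (!all(need %in% names(df)))
    stop("counts CSV needs columns sample_id and time")
  if (!("N" %in% names(df))) {
    if (!all(c("E", "M") %in% names(df)))
      stop("counts CSV needs either N or both E and M")
    df$N <- df$E + df$M
  }
  df
}

# Pivot a tidy count table (one condition) into a replicate-by-time matrix.
counts_to_matrix <- function(df) {
  times <- sort(unique(df$time))
  ids <- sort(unique(df$sample_id))
  m <- matrix(NA_real_, length(ids), length(times))
  m[cbind(match(df$sample_id, ids), match(df$time, times))] <- df$N
  if (anyNA(m)) stop("count table is not a complete replicate-by-time grid")
  list(N = m, t = times)
}

#' Write a moment-trajectory CSV
#'
#' Columns `t`, `mean_E`, `mean_M`, `mean_N`, `var_E`, `var_M`, `cov_EM`,
#' `var_N`, `fano_N`.
#'
#' @param moments a data frame from [moments_growth()] or
#'   [ensemble_summary()].
#' @param path file path.
#' @export
write_moments_csv <- function(moments, path) {
  cols <- c("t", "mean_E", "mean_M", "mean_N", "var_E", "var_M",
            "cov_EM", "var_N", "fano_N")
  write.csv(moments[, intersect(cols, names(moments))], path,
            row.names = FALSE)
  invisible(path)
}

# JSON provenance sidecar written next to every CLI artifact.
write_provenance <- function(path, command, config, seed) {
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         package = "phenoswitch",
         version = as.character(packageVersion("phenoswitch"))),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}
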