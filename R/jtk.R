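#' JTK_CYCLE-style nonparametric rhythmicity test
#'
#' For every combination of candidate period and phase lag, a cosine
#' reference ordering is built at the sampling times and the tie-corrected
#' Kendall tau between the measurements and the reference is computed.
#' Each combination's one-sided p-value comes from the exact permutation
#' null of the Kendall statistic when the sample is small (`n <=
#' exact_n_max`, multiset-aware enumeration) and from a seeded random
#' permutation null otherwise.  The reported p-value is the minimum over
#' the grid, Bonferroni-multiplied by the number of distinct
#' (period, lag) combinations and capped at 1.
#'
#' @param values Measurements (replicates allowed; supply one value per
#'   observation).
#' @param times_zt Sampling time of each observation, in ZT hours
#'   (repeated for replicates).  At least 4 distinct times.
#' @param period_grid_h Candidate periods in hours (default 24, matching
#'   a one-day sampling design).
#' @param lag_step_h Phase-lag grid step; defaults to the sampling
#'   interval.
#' @param n_permutations Random permutations when the exact null is not
#'   used.
#' @param seed Integer seed for the permutation null.
#' @param exact_n_max Largest sample size for which the exact null is
#'   enumerated.
#' @return A `jtk_result` one-row tibble: `p_value`, `best_period_h`,
#'   `best_lag_h`, `tau_statistic`, `n`, `n_combos`, `method`.
#' @export
jtk_cycle <- function(values, times_zt, period_grid_h = 24,
                      lag_step_h = NULL, n_permutations = 10000, seed = 1,
                      exact_n_max = 10) {
  stopifnot(length(values) == length(times_zt))
  ok <- is.finite(values) & is.finite(times_zt)
  values <- values[ok]; times_zt <- times_zt[ok]
  n <- length(values)
  tdist <- sort(unique(times_zt))
  if (length(tdist) < 4) abort("JTK needs at least 4 distinct time points.")
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(p_value = 1, best_period_h = NA_real_,
                          best_lag_h = NA_real_, tau_statistic = 0,
                          n = n, n_combos = 0L, method = "degenerate"))
  }
  lag_step_h <- lag_step_h %||% min(diff(tdist))
  use_exact <- n <= exact_n_max
  method <- if (use_exact) "exact" else "permutation"

  grid <- purrr::map_dfr(period_grid_h, function(P) {
    tibble::tibble(period = P, lag = seq(0, P - lag_step_h, by = lag_step_h))
  })
  null_cache <- new.env(parent = emptyenv())
  res <- purrr::pmap_dfr(grid, function(period, lag) {
    ref <- cos(2 * pi * (times_zt - lag) / period)
    kt <- cpp_kendall(ref, values)
    if (use_exact) {
      ex <- cpp_kendall_exact_null(ref, values, kt$S)
      p <- ex$n_ge / ex$n_total
    } else {
      # the null of S depends on the reference only through its value
      # multiset; cache one permutation null per distinct multiset
      key <- paste(signif(sort(ref), 10), collapse = ",")
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- withr::with_seed(
          seed, cpp_kendall_perm_null(ref, values, n_permutations))
      }
      null <- null_cache[[key]]
      p <- (1 + sum(null >= kt$S - 1e-12)) / (n_permutations + 1)
    }
    tibble::tibble(period = period, lag = lag, tau = kt$tau_b, p = p)
  })
  best <- res |>
    dplyr::arrange(.data$p, dplyr::desc(.data$tau)) |>
    dplyr::slice(1)
  tibble::tibble(
    p_value = min(1, best$p * nrow(res)),
    best_period_h = best$period,
    best_lag_h = best$lag,
    tau_statistic = best$tau,
    n = n, n_combos = nrow(res), method = method
  )
}

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' Exposed mainly so the pairwise-counting definition can be checked
#' directly; the heavy lifting is compiled.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `S` (Kendall sum over pairs) and `tau_b`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  cpp_kendall(as.numeric(x), as.numeric(y))
}
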