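#' Tidy a CDL fit
#'
#' One row per fitted parameter of the photoperiodic logistic.
#'
#' @param x A [fit_cdl()] object.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.cdl_fit <- function(x, ...) {
  if (x$degenerate)
    return(tibble::tibble(term = character(), estimate = double()))
  tibble::tibble(term = names(x$params), estimate = unlist(x$params))
}

#' One-row summary of a CDL fit
#'
#' @param x A [fit_cdl()] object.
#' @param ... Unused.
#' @return Tibble: `cdl_h`, `cdl_sd_h`, `ci_lo`, `ci_hi`,
#'   `cdl_sd_delta_h`, `mode`, `extrapolated`, `degenerate`.
#' @export
glance.cdl_fit <- function(x, ...) {
  tibble::tibble(cdl_h = x$cdl_h, cdl_sd_h = x$cdl_sd_h,
                 ci_lo = x$cdl_ci[1], ci_hi = x$cdl_ci[2],
                 cdl_sd_delta_h = x$cdl_sd_delta_h, mode = x$mode,
                 extrapolated = x$extrapolated, degenerate = x$degenerate)
}

#' Tidy a periodogram
#'
#' @param x A [lomb_scargle()] result.
#' @param ... Unused.
#' @return The periodogram as a plain tibble (`period_h`, `freq`,
#'   `power`).
#' @export
tidy.periodogram <- function(x, ...) {
  tibble::tibble(period_h = x$period_h, freq = x$freq, power = x$power)
}

#' One-row summary of a periodogram
#'
#' @param x A [lomb_scargle()] result.
#' @param ... Unused.
#' @return Tibble: `peak_period_h`, `peak_power`, `n_effective`.
#' @export
glance.periodogram <- function(x, ...) {
  i <- which.max(x$power)
  tibble::tibble(peak_period_h = x$period_h[i], peak_power = x$power[i],
                 n_effective = attr(x, "n_effective"))
}
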