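#' Call reproductive diapause from a female's record
#'
#' A female is diapausing when she laid no eggs within the scoring window
#' and dissection found neither mature eggs nor vitellogenic oocytes; a
#' layer, or a non-layer with developing ovaries, is reproductive.
#'
#' @param records Tibble with logical columns `laid_eggs`,
#'   `mature_eggs_present`, `vitellogenic_oocytes_present`.
#' @return Logical vector: `TRUE` = diapause.
#' @export
call_diapause <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("laid_eggs", "mature_eggs_present", "vitellogenic_oocytes_present")
  if (!all(need %in% names(records)))
    abort(paste0("Records need columns: ", paste(need, collapse = ", ")))
  nonlayer <- !records$laid_eggs
  ovary <- records$mature_eggs_present | records$vitellogenic_oocytes_present
  if (any(nonlayer & is.na(ovary)))
    abort("Non-laying female without ovary dissection fields: dissection required.")
  ifelse(records$laid_eggs, FALSE, !ovary)
}

#' Photoperiodic response curve from diapause records
#'
#' Binomial proportion of diapausing females per photoperiod (and
#' genotype, when present), with the binomial SEM.
#'
#' @param records Tibble of diapause records (see
#'   [simulate_photoperiodic_cohort()] for the columns).
#' @return Tibble: grouping columns plus `n`, `k_diapause`, `proportion`,
#'   `sem`.
#' @export
response_curve <- function(records) {
  records <- tibble::as_tibble(records)
  records$diapause <- call_diapause(records)
  grp <- intersect(c("genotype", "photoperiod_light_h"), names(records))
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n = dplyr::n(), k_diapause = sum(.data$diapause),
                     .groups = "drop") |>
    dplyr::mutate(proportion = .data$k_diapause / .data$n,
                  sem = sqrt(.data$proportion * (1 - .data$proportion) / .data$n))
  class(out) <- c("ppr_curve", class(out))
  out
}

ppr_logistic <- function(L, p) {
  p[1] + (p[2] - p[1]) / (1 + exp(p[3] * (L - p[4])))
}

cdl_from_params <- function(p, mode) {
  p <- unname(p)
  if (mode == "midpoint") return(p[4])
  # absolute 50% crossing of the fitted curve
  if (p[2] <= 0.5 || p[1] >= 0.5) return(NA_real_)
  p[4] + log((p[2] - 0.5) / (0.5 - p[1])) / p[3]
}

fit_ppr_once <- function(L, k, n, method, pin) {
  prop <- k / n
  nll <- function(par) {
    pr <- pmin(pmax(ppr_logistic(L, par), 1e-9), 1 - 1e-9)
    -sum(k * log(pr) + (n - k) * log(1 - pr))
  }
  lsq <- function(par) sum((prop - ppr_logistic(L, par))^2)
  obj <- if (method == "binomial") nll else lsq
  # start: asymptotes from the data, inflection near the 50% crossing
  l50 <- tryCatch(stats::approx(prop, L, xout = mean(range(prop)),
                                ties = mean)$y,
                  error = function(e) mean(range(L)))
  start <- c(max(0, min(min(prop), 0.49)), min(1, max(max(prop), 0.51)),
             2, if (is.finite(l50)) l50 else mean(range(L)))
  lower <- c(0, 0.5, 0.05, min(L) - 6)
  upper <- c(0.5, 1, 50, max(L) + 6)
  if (pin) { lower[1:2] <- c(0, 1); upper[1:2] <- c(0, 1); start[1:2] <- c(0, 1) }
  fit <- tryCatch(
    optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 500)),
    error = function(e) list(convergence = 99L))
  if (fit$convergence != 0) {
    # box-constrained line searches can stall on flat likelihoods; retry
    # derivative-free with the bounds enforced by clamping
    clamped <- function(par) obj(pmin(pmax(par, lower), upper))
    fit <- optim(start, clamped, method = "Nelder-Mead",
                 control = list(maxit = 2000))
    fit$par <- pmin(pmax(fit$par, lower), upper)
  }
  if (method == "binomial")
    fit$hessian <- tryCatch(stats::optimHess(fit$par, obj),
                            error = function(e) NULL)
  fit
}

#' Fit a photoperiodic response curve and estimate the critical day length
#'
#' Maximum binomial likelihood fit of the decreasing logistic
#' \eqn{p(L) = p_{min} + (p_{max}-p_{min})/(1+e^{s(L-L_{50})})}
#' to per-photoperiod diapause counts.  The critical day length (CDL) is
#' the photoperiod where the fitted curve crosses 50% diapause
#' (`mode = "absolute_50"`, default) or the asymptote midpoint `L50`
#' (`mode = "midpoint"`); the two diverge for lines that never reach
#' complete diapause.  The CDL's SD and CI come from a seeded
#' nonparametric bootstrap over individual females (binomial resampling
#' within each photoperiod); a delta-method SD from the likelihood
#' Hessian is reported for comparison.
#'
#' @param curve A [response_curve()] tibble (single genotype) with
#'   columns `photoperiod_light_h`, `n`, `k_diapause`.
#' @param mode CDL definition, `"absolute_50"` or `"midpoint"`.
#' @param bootstrap_b Bootstrap replicates (0 skips the bootstrap).
#' @param seed Integer seed.
#' @param method `"binomial"` likelihood (default) or `"least_squares"`
#'   on the proportions (cross-check mode).
#' @param pin_asymptotes Pin `p_min = 0`, `p_max = 1`.
#' @return A `cdl_fit` object (list): `params`, `cdl_h`, `cdl_sd_h`,
#'   `cdl_ci`, `cdl_sd_delta_h`, `extrapolated`, `degenerate`, `mode`,
#'   `convergence`, `curve`, `boot`.
#' @export
fit_cdl <- function(curve, mode = c("absolute_50", "midpoint"),
                    bootstrap_b = 1000, seed = 1,
                    method = c("binomial", "least_squares"),
                    pin_asymptotes = FALSE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  curve <- tibble::as_tibble(curve)
  if (dplyr::n_distinct(curve$photoperiod_light_h) < 4)
    abort("CDL fitting needs data at >= 4 photoperiods.")
  L <- curve$photoperiod_light_h; k <- curve$k_diapause; n <- curve$n
  prop <- k / n
  if (diff(range(prop)) < 1e-12) {
    return(structure(list(params = NULL, cdl_h = NA_real_,
                          cdl_sd_h = NA_real_, cdl_ci = c(NA_real_, NA_real_),
                          cdl_sd_delta_h = NA_real_, extrapolated = FALSE,
                          degenerate = TRUE, mode = mode, convergence = NA,
                          curve = curve, boot = numeric()),
                     class = "cdl_fit"))
  }
  fit <- fit_ppr_once(L, k, n, method, pin_asymptotes)
  if (fit$convergence != 0)
    abort(sprintf("CDL fit did not converge (optim code %d: %s).",
                  fit$convergence, fit$message %||% ""))
  par <- fit$par
  names(par) <- c("p_min", "p_max", "slope", "l50")
  cdl <- cdl_from_params(par, mode)
  extrapolated <- !is.na(cdl) && (cdl < min(L) || cdl > max(L))

  # delta-method SD from the inverse Hessian (binomial fits only)
  sd_delta <- NA_real_
  if (method == "binomial" && !is.na(cdl)) {
    V <- tryCatch(solve(fit$hessian), error = function(e) NULL)
    if (!is.null(V)) {
      g <- numeric(4); eps <- 1e-5
      for (j in 1:4) {
        ph <- par; ph[j] <- ph[j] + eps
        pl <- par; pl[j] <- pl[j] - eps
        g[j] <- (cdl_from_params(ph, mode) - cdl_from_params(pl, mode)) / (2 * eps)
      }
      q <- drop(t(g) %*% V %*% g)
      if (is.finite(q) && q >= 0) sd_delta <- sqrt(q)
    }
  }

  boot <- numeric()
  if (bootstrap_b > 0) {
    boot <- withr::with_seed(seed, vapply(seq_len(bootstrap_b), function(b) {
      kb <- rbinom(length(n), n, prop)   # resampling individuals within condition
      fb <- tryCatch(fit_ppr_once(L, kb, n, method, pin_asymptotes),
                     error = function(e) NULL)
      if (is.null(fb) || fb$convergence != 0) return(NA_real_)
      cdl_from_params(fb$par, mode)
    }, numeric(1)))
    boot <- boot[is.finite(boot)]
  }
  structure(list(
    params = tibble::as_tibble(as.list(par)),
    cdl_h = cdl,
    cdl_sd_h = if (length(boot) > 1) sd(boot) else NA_real_,
    cdl_ci = if (length(boot) > 1) {
      # basic (reverse-percentile) interval: better calibrated than the
      # raw percentile interval for this mildly skewed functional
      q <- unname(quantile(boot, c(0.025, 0.975), type = 8))
      c(2 * cdl - q[2], 2 * cdl - q[1])
    } else c(NA_real_, NA_real_),
    cdl_sd_delta_h = sd_delta,
    extrapolated = extrapolated,
    degenerate = FALSE, mode = mode, convergence = fit$convergence,
    curve = curve, boot = boot
  ), class = "cdl_fit")
}

#' @export
print.cdl_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<cdl_fit> degenerate (all-diapause or all-reproductive data)\n")
    return(invisible(x))
  }
  cat(sprintf("<cdl_fit> CDL = %.2f h (bootstrap SD %.3f, mode %s%s)\n",
              x$cdl_h, x$cdl_sd_h, x$mode,
              if (x$extrapolated) ", extrapolated" else ""))
  invisible(x)
}

#' Compare two critical-day-length fits
#'
#' @param fit_a,fit_b [fit_cdl()] objects with the same CDL definition
#'   mode and non-degenerate fits.
#' @return One-row tibble: `delta_h` (a - b), `sd_h` (combined bootstrap
#'   SDs), `ci_lo`, `ci_hi` (bootstrap difference CI).
#' @export
compare_cdl <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "cdl_fit"), inherits(fit_b, "cdl_fit"))
  if (fit_a$mode != fit_b$mode) abort("CDL definition modes differ.")
  if (fit_a$degenerate || fit_b$degenerate || is.na(fit_a$cdl_h) ||
        is.na(fit_b$cdl_h))
    abort("Cannot compare: at least one fit is degenerate.")
  delta <- fit_a$cdl_h - fit_b$cdl_h
  sd_h <- sqrt(sum(c(fit_a$cdl_sd_h, fit_b$cdl_sd_h)^2))
  nb <- min(length(fit_a$boot), length(fit_b$boot))
  ci <- if (nb > 1) {
    unname(quantile(fit_a$boot[seq_len(nb)] - fit_b$boot[seq_len(nb)],
                    c(0.025, 0.975), type = 8))
  } else c(NA_real_, NA_real_)
  tibble::tibble(delta_h = delta, sd_h = sd_h, ci_lo = ci[1], ci_hi = ci[2])
}
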