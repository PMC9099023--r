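#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Least-squares line of Cq on log10(relative concentration) over a
#' dilution series (conventionally five points); the amplification
#' efficiency is `E = 10^(-1/slope)` (E = 2 for perfect doubling).
#'
#' @param log10_dilutions log10 relative concentrations (e.g. `0:-4`),
#'   at least 3 points.
#' @param cq Mean Cq at each dilution.
#' @param gene Gene label carried on the result.
#' @return A `standard_curve` one-row tibble: `gene`, `slope`,
#'   `intercept`, `r_squared`, `efficiency`.
#' @export
fit_standard_curve <- function(log10_dilutions, cq, gene = "gene") {
  if (length(log10_dilutions) < 3)
    abort("A standard curve needs at least 3 dilution points.")
  stopifnot(length(log10_dilutions) == length(cq))
  fit <- lm(cq ~ log10_dilutions)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("Amplification curve inverted: slope must be negative.")
  E <- 10^(-1 / slope)
  if (E > 2.2)
    warn(sprintf("Implausible efficiency %.3f for %s (slope %.3f).", E, gene, slope))
  sst <- sum((cq - mean(cq))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  if (r2 < 0.9)
    warn(sprintf("Standard curve for %s has r^2 = %.3f (< 0.9).", gene, r2))
  out <- tibble::tibble(gene = gene, slope = slope,
                        intercept = unname(coef(fit)[1]),
                        r_squared = r2, efficiency = E)
  class(out) <- c("standard_curve", class(out))
  out
}

#' Efficiency-corrected relative expression (Pfaffl form)
#'
#' Target expression relative to the reference gene and a calibrator
#' sample:
#' \deqn{ratio = \frac{E_t^{\,Cq_{t,cal} - Cq_t}}{E_r^{\,Cq_{r,cal} - Cq_r}}}
#' With both efficiencies equal to 2 this reduces to the familiar
#' `2^-ddCq`; `mode = "ddCq"` forces that form regardless of the fitted
#' efficiencies.
#'
#' @param target_cq,ref_cq Sample Cq for target and reference gene.
#' @param calibrator_target_cq,calibrator_ref_cq Calibrator Cq values.
#' @param e_target,e_ref Amplification efficiencies from
#'   [fit_standard_curve()].
#' @param mode `"pfaffl"` (default) or `"ddCq"`.
#' @return Ratio (vectorized over samples).
#' @export
relative_expression <- function(target_cq, ref_cq, calibrator_target_cq,
                                calibrator_ref_cq, e_target = 2, e_ref = 2,
                                mode = c("pfaffl", "ddCq")) {
  mode <- match.arg(mode)
  if (anyNA(ref_cq) || anyNA(target_cq))
    abort("Missing Cq measurement (reference gene required for every sample).")
  if (mode == "ddCq") { e_target <- 2; e_ref <- 2 }
  e_target^(calibrator_target_cq - target_cq) /
    e_ref^(calibrator_ref_cq - ref_cq)
}

#' Relative-expression table from a long Cq data frame
#'
#' Averages technical replicates, then forms efficiency-corrected ratios
#' of every sample against the calibrator sample.
#'
#' @param cq_data Long tibble with columns `sample_id`, `gene`,
#'   `replicate`, `cq`.
#' @param target_gene,ref_gene Gene names in `cq_data` (reference
#'   defaults to `"rp49"`).
#' @param calibrator Sample id used as calibrator (default: first sample).
#' @param e_target,e_ref Amplification efficiencies.
#' @param mode Passed to [relative_expression()].
#' @return Tibble: `sample_id`, `dcq_target`, `dcq_ref`, `ratio`.
#' @export
expression_ratios <- function(cq_data, target_gene = "target",
                              ref_gene = "rp49", calibrator = NULL,
                              e_target = 2, e_ref = 2,
                              mode = c("pfaffl", "ddCq")) {
  mode <- match.arg(mode)
  agg <- cq_data |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(cq = mean(.data$cq), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "cq")
  for (g in c(target_gene, ref_gene))
    if (!g %in% names(agg)) abort(sprintf("Gene '%s' missing from Cq data.", g))
  calibrator <- calibrator %||% agg$sample_id[1]
  cal <- agg[agg$sample_id == calibrator, ]
  if (nrow(cal) != 1) abort(sprintf("Calibrator sample '%s' not found.", calibrator))
  tibble::tibble(
    sample_id = agg$sample_id,
    dcq_target = cal[[target_gene]] - agg[[target_gene]],
    dcq_ref = cal[[ref_gene]] - agg[[ref_gene]],
    ratio = relative_expression(agg[[target_gene]], agg[[ref_gene]],
                                cal[[target_gene]], cal[[ref_gene]],
                                e_target, e_ref, mode = mode)
  )
}

#' Group a relative-expression table into a timecourse summary
#'
#' Mean, SEM and n per cell of a grouping (typically ZT by genotype),
#' ready for rhythmicity testing.
#'
#' @param expr Tibble with a `ratio` column and the grouping columns.
#' @param ... Grouping columns (tidy-select), e.g. `zt, genotype`.
#' @return Tibble with the grouping columns plus `mean`, `sem`, `n`.
#'   Cells with a single replicate get `sem = NA` (flagged undefined).
#' @export
timecourse_summary <- function(expr, ...) {
  expr |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      mean = mean(.data$ratio),
      sem = if (dplyr::n() > 1) sd(.data$ratio) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(), .groups = "drop")
}
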