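#' Photoperiodic-response generating model
#'
#' Diapause incidence follows a decreasing logistic in day length:
#' \deqn{p(L) = p_{min} + \frac{p_{max} - p_{min}}{1 + e^{s\,(L - CDL)}}}
#' so short days induce diapause and the curve crosses its midpoint at
#' `cdl_true` (the generating critical day length when `p_min`/`p_max`
#' are 0/1).
#'
#' @param p_min,p_max Asymptotic diapause probabilities, `p_min <= p_max`.
#' @param cdl_true Inflection photoperiod (hours of light).
#' @param slope Logistic steepness per hour (> 0).
#' @param n_per_condition Females per photoperiod.
#' @param photoperiods Hours of light for each tested condition.
#' @return A `photoperiodic_model` list.
#' @export
photoperiodic_model <- function(p_min = 0, p_max = 1, cdl_true = 16.4,
                                slope = 3, n_per_condition = 30,
                                photoperiods = seq(8, 18, by = 1)) {
  if (p_min < 0 || p_max > 1 || p_min > p_max)
    abort("Need 0 <= p_min <= p_max <= 1.")
  if (slope <= 0) abort("`slope` must be > 0.")
  if (length(photoperiods) == 0) abort("`photoperiods` must be non-empty.")
  structure(list(p_min = p_min, p_max = p_max, cdl_true = cdl_true,
                 slope = slope, n_per_condition = n_per_condition,
                 photoperiods = sort(photoperiods)),
            class = "photoperiodic_model")
}

#' Simulate per-female diapause records under a photoperiodic model
#'
#' Each female's diapause state is a Bernoulli draw from the logistic
#' response; the reproductive-record fields (egg laying, mature eggs,
#' vitellogenic oocytes) are filled in consistently with the state, so
#' [call_diapause()] recovers it exactly.
#'
#' @param model A [photoperiodic_model()].
#' @param seed Integer seed.
#' @param genotype Label carried on every record.
#' @return Tibble of diapause records: `female_id`, `genotype`,
#'   `photoperiod_light_h`, `laid_eggs`, `mature_eggs_present`,
#'   `vitellogenic_oocytes_present`.
#' @export
simulate_photoperiodic_cohort <- function(model, seed = 1, genotype = "WT") {
  stopifnot(inherits(model, "photoperiodic_model"))
  p_of <- function(L) model$p_min +
    (model$p_max - model$p_min) / (1 + exp(model$slope * (L - model$cdl_true)))
  withr::with_seed(seed, {
    purrr::map_dfr(model$photoperiods, function(L) {
      p <- p_of(L)
      if (p < 0 || p > 1) abort("Diapause probability outside [0, 1].")
      dia <- rbinom(model$n_per_condition, 1, p) == 1
      # reproductive females mostly lay; some non-layers carry developing ovaries
      lays <- !dia & (runif(model$n_per_condition) < 0.8)
      tibble::tibble(
        female_id = sprintf("%s_L%04.1f_%02d", genotype, L,
                            seq_len(model$n_per_condition)),
        genotype = genotype,
        photoperiod_light_h = L,
        laid_eggs = lays,
        mature_eggs_present = !dia & !lays & (runif(model$n_per_condition) < 0.5),
        vitellogenic_oocytes_present = !dia & !lays
      )
    })
  })
}

#' Simulate a qPCR experiment with known relative expression
#'
#' Generates a Cq table for a target gene against the `rp49` reference
#' under stated amplification efficiencies, plus five-point dilution
#' series for both genes whose slopes encode those efficiencies
#' (slope = -1/log10(E)).  With zero noise the efficiency-corrected
#' ratio pipeline returns `true_ratios` exactly.
#'
#' @param true_ratios Named numeric vector of per-sample relative
#'   expression (vs the calibrator sample, which has ratio 1).
#' @param efficiency_target,efficiency_ref Amplification efficiencies in
#'   (1, 2].
#' @param noise_sd_cq Gaussian SD added to every Cq.
#' @param n_replicates Technical replicates per sample and gene.
#' @param seed Integer seed.
#' @param cq_cal_target,cq_cal_ref Calibrator Cq values.
#' @return List with `cq` (tibble: `sample_id`, `gene`, `replicate`, `cq`)
#'   and `dilution` (tibble: `gene`, `log10_dilution`, `cq`).
#' @export
simulate_qpcr <- function(true_ratios, efficiency_target = 2,
                          efficiency_ref = 2, noise_sd_cq = 0,
                          n_replicates = 3, seed = 1,
                          cq_cal_target = 22, cq_cal_ref = 18) {
  if (any(true_ratios <= 0)) abort("Relative expression ratios must be > 0.")
  for (E in c(efficiency_target, efficiency_ref))
    if (E <= 1 || E > 2) abort("Efficiencies must lie in (1, 2].")
  if (noise_sd_cq < 0) abort("`noise_sd_cq` must be >= 0.")
  ids <- names(true_ratios) %||% sprintf("S%02d", seq_along(true_ratios))
  withr::with_seed(seed, {
    cq <- purrr::map_dfr(seq_along(true_ratios), function(i) {
      tgt <- cq_cal_target - log(true_ratios[i], base = efficiency_target)
      dplyr::bind_rows(
        tibble::tibble(sample_id = ids[i], gene = "target",
                       replicate = seq_len(n_replicates),
                       cq = tgt + rnorm(n_replicates, 0, noise_sd_cq)),
        tibble::tibble(sample_id = ids[i], gene = "rp49",
                       replicate = seq_len(n_replicates),
                       cq = cq_cal_ref + rnorm(n_replicates, 0, noise_sd_cq))
      )
    })
    dil <- purrr::map_dfr(
      list(c("target", efficiency_target, 15), c("rp49", efficiency_ref, 14)),
      function(g) {
        ld <- 0:-4
        tibble::tibble(gene = g[1],
                       log10_dilution = ld,
                       cq = as.numeric(g[3]) - ld / log10(as.numeric(g[2])) +
                         rnorm(5, 0, noise_sd_cq))
      })
  })
  list(cq = cq, dilution = dil)
}

#' Simulate a grayscale stained-brain image plane
#'
#' Gaussian-profile blobs (stained somata or arborization fields) are added
#' to a uniform background with optional pixel noise.  Ground-truth ROI
#' masks accompany the image so densitometry can be validated against the
#' closed-form blob means.
#'
#' @param cell_centers_um Matrix/data frame of blob centres (x, y) in
#'   micrometres.
#' @param cell_intensities Peak amplitude of each blob (gray units, >= 0).
#' @param cell_sigma_um Gaussian radius of each blob in micrometres.
#' @param background_level Uniform background gray value.
#' @param noise_sd Gaussian pixel noise SD.
#' @param scale_um_per_px Micrometres per pixel (> 0).
#' @param dim_px Image size `c(nrow, ncol)` in pixels.
#' @param seed Integer seed.
#' @return An `image_plane`: list with `pixels` (matrix),
#'   `scale_um_per_px`, `truth` (blob table), and `masks` (list of logical
#'   matrices covering each blob out to 3 sigma).
#' @export
simulate_brain_image <- function(cell_centers_um = NULL,
                                 cell_intensities = numeric(),
                                 cell_sigma_um = 8,
                                 background_level = 100, noise_sd = 0,
                                 scale_um_per_px = 1,
                                 dim_px = c(256, 256), seed = 1) {
  if (scale_um_per_px <= 0) abort("`scale_um_per_px` must be > 0.")
  if (any(cell_intensities < 0)) abort("Blob intensities must be >= 0.")
  n_cells <- length(cell_intensities)
  if (n_cells > 0) {
    cell_centers_um <- as.matrix(cell_centers_um)
    stopifnot(nrow(cell_centers_um) == n_cells, ncol(cell_centers_um) == 2)
  }
  sig <- rep_len(cell_sigma_um, n_cells)
  px <- matrix(background_level, dim_px[1], dim_px[2])
  # pixel (r, c) is centred at ((c - 0.5) * scale, (r - 0.5) * scale) um
  xs <- (seq_len(dim_px[2]) - 0.5) * scale_um_per_px
  ys <- (seq_len(dim_px[1]) - 0.5) * scale_um_per_px
  masks <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    dx2 <- outer(rep(1, dim_px[1]), (xs - cell_centers_um[k, 1])^2)
    dy2 <- outer((ys - cell_centers_um[k, 2])^2, rep(1, dim_px[2]))
    r2 <- dx2 + dy2
    px <- px + cell_intensities[k] * exp(-r2 / (2 * sig[k]^2))
    masks[[k]] <- r2 <= (3 * sig[k])^2
  }
  if (noise_sd > 0)
    px <- px + withr::with_seed(seed, matrix(rnorm(length(px), 0, noise_sd),
                                             nrow(px), ncol(px)))
  structure(list(
    pixels = px, scale_um_per_px = scale_um_per_px,
    truth = tibble::tibble(
      x_um = if (n_cells) cell_centers_um[, 1] else double(),
      y_um = if (n_cells) cell_centers_um[, 2] else double(),
      intensity = cell_intensities, sigma_um = sig),
    masks = masks
  ), class = "image_plane")
}
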