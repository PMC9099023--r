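#' Rectangular or mask region of interest for densitometry
#'
#' Geometry is given in micrometres and converted to pixels against the
#' image scale with half-open rounding (floor of the start edge, ceiling
#' of the end edge), so ROI placement is deterministic.
#'
#' @param kind `"rectangle"` or `"mask"`.
#' @param x_um,y_um,width_um,height_um Rectangle geometry in micrometres
#'   (top-left corner plus extent).
#' @param mask Logical matrix (for `kind = "mask"`), same size as the
#'   image.
#' @param role `"cell_body"`, `"projection_field"` or `"background"`.
#' @return A `roi` object.
#' @export
roi <- function(kind = c("rectangle", "mask"), x_um = NULL, y_um = NULL,
                width_um = NULL, height_um = NULL, mask = NULL,
                role = "projection_field") {
  kind <- match.arg(kind)
  if (kind == "rectangle") {
    stopifnot(!is.null(x_um), !is.null(y_um), !is.null(width_um),
              !is.null(height_um))
    if (width_um <= 0 || height_um <= 0) abort("ROI area must be positive.")
  } else {
    stopifnot(is.logical(mask))
    if (!any(mask)) abort("ROI mask is empty.")
  }
  structure(list(kind = kind, x_um = x_um, y_um = y_um, width_um = width_um,
                 height_um = height_um, mask = mask, role = role),
            class = "roi")
}

roi_pixels <- function(image, r) {
  px <- image$pixels
  if (r$kind == "mask") {
    if (!all(dim(r$mask) == dim(px))) abort("Mask size differs from image.")
    return(which(r$mask))
  }
  s <- image$scale_um_per_px
  c0 <- floor(r$x_um / s) + 1L
  c1 <- ceiling((r$x_um + r$width_um) / s)
  r0 <- floor(r$y_um / s) + 1L
  r1 <- ceiling((r$y_um + r$height_um) / s)
  if (c0 < 1 || r0 < 1 || c1 > ncol(px) || r1 > nrow(px))
    abort("ROI falls outside the image bounds.")
  idx <- as.vector(outer(r0:r1, (c0:c1 - 1L) * nrow(px), `+`))
  idx
}

#' Mean gray value under a region of interest
#'
#' @param image An `image_plane` (see [simulate_brain_image()]) or a list
#'   with `pixels` and `scale_um_per_px`.
#' @param region A [roi()].
#' @return Arithmetic mean of the pixels under the ROI.
#' @export
roi_mean <- function(image, region) {
  mean(image$pixels[roi_pixels(image, region)])
}

#' Background-corrected staining intensity
#'
#' Mean gray value of the signal ROI minus the mean of a nearby
#' background ROI (conventionally a 20 x 20 um rectangle outside the
#' stained structures).  Negative corrected values are kept and flagged
#' rather than clamped, so group statistics stay unbiased.
#'
#' @param image An `image_plane`.
#' @param signal_roi,background_roi [roi()] objects; must not overlap.
#' @param hemisphere Optional label carried on the result.
#' @return One-row tibble: `raw_mean`, `background_mean`, `corrected`,
#'   `negative_flag`, `hemisphere`.
#' @export
corrected_intensity <- function(image, signal_roi, background_roi,
                                hemisphere = NA_character_) {
  si <- roi_pixels(image, signal_roi)
  bi <- roi_pixels(image, background_roi)
  if (length(intersect(si, bi)) > 0)
    abort("Signal and background ROIs overlap.")
  raw <- mean(image$pixels[si])
  bg <- mean(image$pixels[bi])
  tibble::tibble(raw_mean = raw, background_mean = bg,
                 corrected = raw - bg, negative_flag = (raw - bg) < 0,
                 hemisphere = hemisphere)
}

#' Per-brain staining intensity from the two hemispheres
#'
#' @param left,right One-row tibbles from [corrected_intensity()]; either
#'   may be `NULL` (single-hemisphere fallback, flagged).
#' @return One-row tibble: `intensity`, `n_hemispheres`,
#'   `single_hemisphere_flag`.
#' @export
brain_intensity <- function(left = NULL, right = NULL) {
  vals <- c(if (!is.null(left)) left$corrected,
            if (!is.null(right)) right$corrected)
  if (length(vals) == 0) abort("At least one hemisphere is required.")
  tibble::tibble(intensity = mean(vals), n_hemispheres = length(vals),
                 single_hemisphere_flag = length(vals) == 1L)
}
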