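#' Planar ROI count sums for the lung shunt fraction
#'
#' The four inputs of the geometric-mean lung-shunt-fraction equation: total
#' counts in the lung and liver ROIs on the anterior and posterior planar
#' views.
#'
#' @param lungs_anterior,lungs_posterior,liver_anterior,liver_posterior ROI
#'   count sums, each finite and >= 0.
#' @return An object of class `lsf_inputs`.
#' @export
lsf_inputs <- function(lungs_anterior, lungs_posterior,
                       liver_anterior, liver_posterior) {
  x <- c(lungs_anterior = as.numeric(lungs_anterior)[1],
         lungs_posterior = as.numeric(lungs_posterior)[1],
         liver_anterior = as.numeric(liver_anterior)[1],
         liver_posterior = as.numeric(liver_posterior)[1])
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("all four ROI count sums must be finite and >= 0")
  }
  structure(as.list(x), class = "lsf_inputs")
}

#' Lung shunt fraction from planar ROI counts
#'
#' The fraction of activity shunted to the lungs, using the geometric mean
#' of the anterior and posterior views to cancel depth attenuation:
#'
#' LSF = sqrt(lungs_ant * lungs_post) /
#'       (sqrt(lungs_ant * lungs_post) + sqrt(liver_ant * liver_post))
#'
#' One organ's geometric mean being zero is a valid degenerate input (LSF 0
#' or 1); only both zero is undefined.
#'
#' @param inputs an [lsf_inputs()], or a numeric vector of length 4 in the
#'   order lungs_anterior, lungs_posterior, liver_anterior, liver_posterior.
#' @return The shunt fraction, in `[0, 1]`.
#' @examples
#' lung_shunt_fraction(lsf_inputs(100, 400, 1600, 1600))  # 0.1111
#' @export
lung_shunt_fraction <- function(inputs) {
  if (is.numeric(inputs) && length(inputs) == 4L) {
    inputs <- lsf_inputs(inputs[1], inputs[2], inputs[3], inputs[4])
  }
  if (!inherits(inputs, "lsf_inputs")) {
    stop("`inputs` must be an lsf_inputs or 4 numbers")
  }
  gm_lung <- sqrt(inputs$lungs_anterior * inputs$lungs_posterior)
  gm_liver <- sqrt(inputs$liver_anterior * inputs$liver_posterior)
  if (gm_lung + gm_liver <= 0) {
    stop("lung shunt fraction undefined: both geometric means are zero")
  }
  gm_lung / (gm_lung + gm_liver)
}

#' Lung shunt fraction from planar images and ROI masks
#'
#' Sums each organ ROI on each view with [mask_sum()] and applies
#' [lung_shunt_fraction()]. By default the same organ mask is used on both
#' views (the ROIs are drawn once on co-registered views).
#'
#' @param anterior,posterior the two [planar_image()] views.
#' @param lung_mask,liver_mask 2-D [roi_mask()]s for the anterior view.
#' @param lung_mask_posterior,liver_mask_posterior optional distinct masks
#'   for the posterior view.
#' @return The shunt fraction, in `[0, 1]`.
#' @export
lsf_from_planar <- function(anterior, posterior, lung_mask, liver_mask,
                            lung_mask_posterior = lung_mask,
                            liver_mask_posterior = liver_mask) {
  inputs <- lsf_inputs(
    lungs_anterior = mask_sum(anterior, lung_mask),
    lungs_posterior = mask_sum(posterior, lung_mask_posterior),
    liver_anterior = mask_sum(anterior, liver_mask),
    liver_posterior = mask_sum(posterior, liver_mask_posterior)
  )
  lung_shunt_fraction(inputs)
}
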