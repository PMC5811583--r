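# Phantom threshold calibration: sweep candidate percentage-of-maximum
# thresholds over the sphere images and select the smallest threshold whose
# volumes approximate or underestimate — never overestimate — the true
# volumes. Underestimating the volume overestimates the absorbed dose,
# which is the conservative direction for a safety analysis.

#' Sweep delineation thresholds over phantom spheres
#'
#' For each sphere and each candidate threshold fraction, estimates the
#' volume with [estimate_volume()] inside that sphere's margin mask, the
#' activity with [estimate_activity()], and the resulting dose with
#' [absorbed_dose()]; tabulates estimates against the ground truth (true
#' dose = dose of the known concentration times the true volume).
#'
#' @param phantom_image the phantom [voxel_image()].
#' @param margin_masks list of per-sphere margin [roi_mask()]s, e.g. from
#'   [phantom_margin_masks()]; one per truth row, in order.
#' @param truth ground-truth table from [generate_phantom()].
#' @param grid candidate threshold fractions in (0, 1]; default 0.05 to
#'   0.95 in steps of 0.05.
#' @param constants a [dose_constants()].
#' @return A `threshold_sweep`: list with `table` (long data frame: sphere,
#'   threshold_fraction, est_volume_ml, est_activity_mbq, est_dose_gy,
#'   true_volume_ml, true_dose_gy, volume_ratio, dose_ratio) and `grid`.
#' @export
sweep_thresholds <- function(phantom_image, margin_masks, truth,
                             grid = seq(0.05, 0.95, by = 0.05),
                             constants = dose_constants()) {
  if (length(margin_masks) != nrow(truth)) {
    stop("got ", length(margin_masks), " margin masks for ", nrow(truth),
         " spheres in the truth table")
  }
  grid <- sort(unique(as.numeric(grid)))
  if (!length(grid) || any(grid <= 0 | grid > 1)) {
    stop("`grid` fractions must lie in (0, 1]")
  }
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    act <- estimate_activity(phantom_image, margin_masks[[i]])
    true_v <- truth$volume_ml[i]
    true_d <- absorbed_dose(truth$activity_mbq[i], true_v, constants)
    vols <- vapply(grid, function(t) {
      estimate_volume(phantom_image, margin_masks[[i]], t)
    }, 0)
    doses <- vapply(vols, function(v) absorbed_dose(act, v, constants), 0)
    data.frame(
      sphere = truth$sphere[i], threshold_fraction = grid,
      est_volume_ml = vols, est_activity_mbq = act, est_dose_gy = doses,
      true_volume_ml = true_v, true_dose_gy = true_d,
      volume_ratio = vols / true_v, dose_ratio = doses / true_d
    )
  })
  structure(list(table = do.call(rbind, rows), grid = grid),
            class = "threshold_sweep")
}

#' Select the delineation threshold from a sweep
#'
#' Returns the smallest grid fraction at which no sphere with true volume of
#' at least `min_volume_ml` has an estimated volume exceeding its true
#' volume ("approximate or underestimate, but not overestimate"). The
#' smallest qualifying fraction gives the least underestimation. Spheres
#' below `min_volume_ml` (default 1 ml, the clinically irrelevant smallest
#' sphere) are exempt from the criterion.
#'
#' @param sweep a `threshold_sweep` from [sweep_thresholds()].
#' @param min_volume_ml smallest true volume the criterion must protect.
#' @param tolerance relative tolerance on the non-overestimation test
#'   (estimated <= true * (1 + tolerance)); default 0, the strict reading.
#' @return The selected threshold fraction.
#' @export
select_threshold <- function(sweep, min_volume_ml = 1, tolerance = 0) {
  if (!inherits(sweep, "threshold_sweep")) {
    stop("`sweep` must be a threshold_sweep")
  }
  tab <- sweep$table[sweep$table$true_volume_ml >= min_volume_ml, ]
  if (!nrow(tab)) stop("no sphere has true volume >= ", min_volume_ml, " ml")
  for (t in sweep$grid) {
    at_t <- tab[tab$threshold_fraction == t, ]
    if (all(at_t$est_volume_ml <= at_t$true_volume_ml * (1 + tolerance))) {
      return(t)
    }
  }
  worst <- tab[tab$threshold_fraction == max(sweep$grid) &
                 tab$est_volume_ml > tab$true_volume_ml * (1 + tolerance), ]
  stop("no grid fraction satisfies the non-overestimation criterion; ",
       "still overestimating at ", max(sweep$grid), ": sphere(s) ",
       paste(worst$sphere, collapse = ", "))
}

#' Run the full phantom calibration
#'
#' Generates the phantom, builds per-sphere margin masks, sweeps the
#' threshold grid, and selects the threshold.
#'
#' @param spec a [phantom_spec()].
#' @param grid candidate threshold fractions; see [sweep_thresholds()].
#' @param margin_mm margin for [phantom_margin_masks()]; default twice the
#'   PSF FWHM.
#' @param min_volume_ml,tolerance passed to [select_threshold()].
#' @param constants a [dose_constants()].
#' @return List with `sweep`, `selected_threshold`, `truth`, `image`.
#' @export
calibrate_threshold <- function(spec = phantom_spec(),
                                grid = seq(0.05, 0.95, by = 0.05),
                                margin_mm = 2 * spec$psf_fwhm,
                                min_volume_ml = 1, tolerance = 0,
                                constants = dose_constants()) {
  ph <- generate_phantom(spec)
  masks <- phantom_margin_masks(ph$image, ph$truth, margin_mm = margin_mm)
  sweep <- sweep_thresholds(ph$image, masks, ph$truth, grid = grid,
                            constants = constants)
  list(
    sweep = sweep,
    selected_threshold = select_threshold(sweep, min_volume_ml, tolerance),
    truth = ph$truth,
    image = ph$image
  )
}
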