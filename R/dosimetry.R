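# Quantification of one extrahepatic deposition: activity by margin-ROI
# summation (no threshold, so displaced counts are not lost), volume by
# percentage-of-maximum threshold delineation inside the margin, and beta
# absorbed dose by D(Gy) = 15.87 (mJ/MBq) * A (MBq) / (V (cm^3) * 1.06
# (g/cm^3)). All beta energy is assumed absorbed locally (mean beta range
# 2.5 mm); the gamma contribution to local dose is neglected.

#' Estimate deposition activity by margin-ROI summation
#'
#' Sums all voxel values (Bq) inside the margin delineation, without any
#' threshold, and converts to MBq. Taking the full margin sum deliberately
#' overestimates rather than underestimates the deposited activity.
#'
#' @param image a [voxel_image()] (values in Bq).
#' @param margin_mask nonempty [roi_mask()] congruent with `image`.
#' @return Activity in MBq.
#' @export
estimate_activity <- function(image, margin_mask) {
  if (!inherits(margin_mask, "roi_mask")) stop("`margin_mask` must be an roi_mask")
  check_congruent(image, margin_mask)
  if (!any(margin_mask$selected)) {
    stop("margin mask is empty: nothing delineated")
  }
  mask_sum(image, margin_mask) / 1e6
}

#' Estimate deposition volume by threshold delineation
#'
#' The threshold is `threshold_fraction` times the maximum voxel value
#' inside the margin mask (so hepatic activity outside the margin cannot set
#' it); the volume is the number of in-mask voxels at or above the threshold
#' times the voxel volume. Voxels exactly at the threshold are inside. No
#' connected-component filtering is applied.
#'
#' @param image a [voxel_image()].
#' @param margin_mask nonempty [roi_mask()] congruent with `image`.
#' @param threshold_fraction fraction of the in-mask maximum, in (0, 1];
#'   default 0.30, the phantom-calibrated value.
#' @return Volume in ml.
#' @export
estimate_volume <- function(image, margin_mask, threshold_fraction = 0.30) {
  if (!inherits(margin_mask, "roi_mask")) stop("`margin_mask` must be an roi_mask")
  check_congruent(image, margin_mask)
  if (!any(margin_mask$selected)) {
    stop("margin mask is empty: nothing delineated")
  }
  if (!is.finite(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1) {
    stop("`threshold_fraction` must be in (0, 1]")
  }
  vals <- image$values[margin_mask$selected]
  mx <- max(vals)
  if (mx <= 0) {
    stop("all voxels in the margin are zero: threshold undefined")
  }
  sum(vals >= threshold_fraction * mx) * voxel_volume_ml(image)
}

#' Beta absorbed dose of a deposition
#'
#' D (Gy) = energy_per_activity (mJ/MBq) * A (MBq) /
#' (V (cm^3) * tissue_density (g/cm^3)); mJ/g is numerically Gy.
#'
#' @param activity_mbq deposited activity A (MBq, >= 0).
#' @param volume_ml delineated volume V (ml, > 0).
#' @param constants a [dose_constants()].
#' @return Absorbed dose in Gy.
#' @examples
#' absorbed_dose(3.7, 15.3)  # ~3.6 Gy
#' @export
absorbed_dose <- function(activity_mbq, volume_ml, constants = dose_constants()) {
  if (!inherits(constants, "dose_constants")) {
    stop("`constants` must be a dose_constants")
  }
  if (!is.finite(volume_ml) || volume_ml <= 0) {
    stop("`volume_ml` must be > 0 to report a dose")
  }
  if (!is.finite(activity_mbq) || activity_mbq < 0) {
    stop("`activity_mbq` must be >= 0")
  }
  constants$energy_per_activity * activity_mbq /
    (volume_ml * constants$tissue_density)
}

#' Quantify one extrahepatic deposition
#'
#' Composes [estimate_activity()] (margin sum, no threshold),
#' [estimate_volume()] (percentage-of-maximum threshold), and
#' [absorbed_dose()] into one record.
#'
#' @inheritParams estimate_volume
#' @param constants a [dose_constants()].
#' @return A `deposition_record`: list with `activity_mbq`, `volume_ml`,
#'   `dose_gy`, `threshold_fraction`, `mask_label`, `margin_volume_ml`
#'   (provenance of the delineation), and `constants`.
#' @export
quantify_deposition <- function(image, margin_mask, threshold_fraction = 0.30,
                                constants = dose_constants()) {
  a <- estimate_activity(image, margin_mask)
  v <- estimate_volume(image, margin_mask, threshold_fraction)
  structure(
    list(
      activity_mbq = a,
      volume_ml = v,
      dose_gy = absorbed_dose(a, v, constants),
      threshold_fraction = threshold_fraction,
      mask_label = margin_mask$label,
      margin_volume_ml = sum(margin_mask$selected) * voxel_volume_ml(image),
      constants = constants
    ),
    class = "deposition_record"
  )
}

#' Build a deposition record from known activity and volume
#'
#' For cohort work where activity (MBq) and threshold volume (ml) are
#' already tabulated; the dose is recomputed from them.
#'
#' @inheritParams absorbed_dose
#' @param threshold_fraction threshold used for the volume (provenance).
#' @param mask_label delineation provenance label.
#' @return A `deposition_record`.
#' @export
deposition_record <- function(activity_mbq, volume_ml,
                              constants = dose_constants(),
                              threshold_fraction = 0.30, mask_label = "") {
  structure(
    list(
      activity_mbq = as.numeric(activity_mbq)[1],
      volume_ml = as.numeric(volume_ml)[1],
      dose_gy = absorbed_dose(activity_mbq, volume_ml, constants),
      threshold_fraction = threshold_fraction,
      mask_label = as.character(mask_label)[1],
      margin_volume_ml = NA_real_,
      constants = constants
    ),
    class = "deposition_record"
  )
}

#' @export
print.deposition_record <- function(x, ...) {
  cat(sprintf(
    "<deposition_record> A = %.1f MBq, V = %.1f ml, D = %.1f Gy (threshold %.0f%% of max)\n",
    x$activity_mbq, x$volume_ml, x$dose_gy, 100 * x$threshold_fraction
  ))
  invisible(x)
}

# Order-statistic medians. For even n the conventional median averages the
# central pair; the lower/upper medians are the n/2-th and (n/2+1)-th order
# statistics. Small clinical cohorts are often summarized with an observed
# value as "the median", which for even n is one of the latter two.
median_conventions <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2L == 1L) {
    m <- x[(n + 1L) / 2L]
    c(lower_median = m, median = m, upper_median = m)
  } else {
    c(lower_median = x[n / 2L],
      median = (x[n / 2L] + x[n / 2L + 1L]) / 2,
      upper_median = x[n / 2L + 1L])
  }
}

#' Summarize a cohort of deposition records
#'
#' Per-metric (activity, volume, dose) minimum, maximum, and three median
#' conventions: the conventional median (mean of the central pair for even
#' n), and the lower/upper medians (the n/2-th and (n/2+1)-th order
#' statistics for even n; all three coincide for odd n). All are reported
#' because a small even cohort summarized by an observed value matches an
#' order-statistic convention, not the interpolated one.
#'
#' @param records nonempty list of `deposition_record`s.
#' @return A `cohort_summary`: list with `records` (data frame of per-record
#'   values) and `summary` (data frame: metric, min, lower_median, median,
#'   upper_median, max, n).
#' @export
cohort_summary <- function(records) {
  if (inherits(records, "deposition_record")) records <- list(records)
  if (!length(records)) stop("`records` must be a nonempty list")
  if (!all(vapply(records, inherits, TRUE, "deposition_record"))) {
    stop("all elements must be deposition_record objects")
  }
  df <- data.frame(
    activity_mbq = vapply(records, function(r) r$activity_mbq, 0),
    volume_ml = vapply(records, function(r) r$volume_ml, 0),
    dose_gy = vapply(records, function(r) r$dose_gy, 0),
    mask_label = vapply(records, function(r) r$mask_label, "")
  )
  summ <- do.call(rbind, lapply(
    c(activity_mbq = "activity_mbq", volume_ml = "volume_ml",
      dose_gy = "dose_gy"),
    function(col) {
      m <- median_conventions(df[[col]])
      data.frame(metric = col, min = min(df[[col]]),
                 lower_median = m[["lower_median"]], median = m[["median"]],
                 upper_median = m[["upper_median"]], max = max(df[[col]]),
                 n = nrow(df))
    }
  ))
  rownames(summ) <- NULL
  structure(list(records = df, summary = summ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", nrow(x$records), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Reported extrahepatic-deposition cohort
#'
#' The six extrahepatic scout-dose depositions of the clinical cohort this
#' package accompanies: threshold volume (ml, 30\% threshold) and margin-sum
#' activity (MBq) per patient, as tabulated at one-decimal precision. Doses
#' are not stored; they are recomputed with [absorbed_dose()].
#'
#' @return Data frame with columns `patient`, `location`, `volume_ml`,
#'   `activity_mbq`.
#' @export
extrahepatic_cohort <- function() {
  path <- system.file("extdata", "extrahepatic_depositions.csv",
                      package = "scoutdose")
  if (path == "") {
    path <- file.path("inst", "extdata", "extrahepatic_depositions.csv")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}
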