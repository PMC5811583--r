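#' Quantitative voxel image
#'
#' Container for a reconstructed quantitative emission image: a 3-D grid of
#' activity values in becquerel (Bq) per voxel, together with the physical
#' voxel spacing and the position of the first voxel's center. Voxel indices
#' are 0-based in physical-coordinate arithmetic; physical coordinates refer
#' to voxel centers.
#'
#' @param values numeric 3-D array of per-voxel activity (Bq); all finite
#'   and non-negative.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm; all
#'   strictly positive.
#' @param origin numeric length-3 vector, physical position (mm) of the
#'   center of voxel (0, 0, 0).
#' @return An object of class `voxel_image`.
#' @examples
#' img <- voxel_image(array(1, c(4, 4, 4)), spacing = c(4.8, 4.8, 4.8))
#' voxel_volume_ml(img)
#' @export
voxel_image <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array, got ", length(dim(values)), " dims")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive finite numbers (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers (mm)")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("voxel values must all be finite and >= 0 (activity in Bq)")
  }
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = "voxel_image"
  )
}

#' Planar scintigraphy image
#'
#' A 2-D grid of detected counts per pixel, as acquired in anterior or
#' posterior planar imaging of the thorax and abdomen.
#'
#' @param values numeric 2-D matrix of counts; all finite and non-negative.
#' @param spacing numeric length-2 pixel edge lengths (mm).
#' @return An object of class `planar_image`.
#' @export
planar_image <- function(values, spacing = c(4.8, 4.8)) {
  values <- as.matrix(values)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 2 strictly positive finite numbers (mm)")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("pixel values must all be finite and >= 0 (counts)")
  }
  structure(list(values = values, spacing = spacing), class = "planar_image")
}

#' Region-of-interest mask
#'
#' Boolean selection grid congruent with the image it annotates; used for
#' lung/liver ROIs on planar images and margin delineations on voxel images.
#' The empty mask is valid.
#'
#' @param selected logical array (2-D or 3-D) of selected positions.
#' @param label free-text ROI name recorded for provenance.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(selected, label = "") {
  selected <- as.array(selected)
  if (!is.logical(selected)) {
    if (is.numeric(selected)) {
      selected <- array(selected != 0, dim(selected))
    } else {
      stop("`selected` must be a logical (or 0/1 numeric) array")
    }
  }
  if (anyNA(selected)) stop("mask must not contain NA")
  structure(
    list(selected = selected, label = as.character(label)[1]),
    class = "roi_mask"
  )
}

#' Beta-dose constants for holmium-166
#'
#' Physical constants of the absorbed-dose conversion: the total beta energy
#' absorbed in tissue per unit activity of holmium-166 (the beta decay
#' carries 96\% of the emitted energy; the high-energy gamma contribution to
#' the local dose is negligible and is set to zero), and the mass density of
#' soft tissue.
#'
#' @param energy_per_activity absorbed beta energy per activity, mJ/MBq.
#'   Default 15.87.
#' @param tissue_density soft-tissue mass density, g/cm^3. Default 1.06.
#' @return An object of class `dose_constants`.
#' @export
dose_constants <- function(energy_per_activity = 15.87, tissue_density = 1.06) {
  energy_per_activity <- as.numeric(energy_per_activity)[1]
  tissue_density <- as.numeric(tissue_density)[1]
  if (!is.finite(energy_per_activity) || energy_per_activity <= 0) {
    stop("`energy_per_activity` must be > 0 (mJ/MBq)")
  }
  if (!is.finite(tissue_density) || tissue_density <= 0) {
    stop("`tissue_density` must be > 0 (g/cm^3)")
  }
  structure(
    list(
      energy_per_activity = energy_per_activity,
      tissue_density = tissue_density
    ),
    class = "dose_constants"
  )
}

image_values <- function(image) {
  if (inherits(image, "voxel_image") || inherits(image, "planar_image")) {
    return(image$values)
  }
  if (is.array(image) || is.matrix(image)) return(image)
  stop("expected a voxel_image, planar_image, or array")
}

check_congruent <- function(image, mask) {
  di <- dim(image_values(image))
  dm <- dim(mask$selected)
  if (length(di) != length(dm) || any(di != dm)) {
    stop(
      "mask shape (", paste(dm, collapse = "x"),
      ") does not match image shape (", paste(di, collapse = "x"), ")"
    )
  }
  invisible(TRUE)
}

#' Sum image values inside a mask
#'
#' Sums the image values at all selected positions — the voxel summation
#' used to estimate a deposition's activity (in Bq, no threshold) and the
#' pixel summation behind planar ROI counts. An empty mask sums to 0.
#'
#' @param image a [voxel_image()] or [planar_image()].
#' @param mask an [roi_mask()] congruent with `image`.
#' @return Scalar sum (Bq for voxel images, counts for planar images).
#' @export
mask_sum <- function(image, mask) {
  if (!inherits(mask, "roi_mask")) stop("`mask` must be an roi_mask")
  check_congruent(image, mask)
  sum(image_values(image)[mask$selected])
}

#' Voxel volume in millilitres
#'
#' @param image a [voxel_image()].
#' @return Product of the voxel spacings (mm^3) divided by 1000, in ml.
#' @export
voxel_volume_ml <- function(image) {
  if (!inherits(image, "voxel_image")) stop("`image` must be a voxel_image")
  prod(image$spacing) / 1000
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(
    "<voxel_image> ", paste(dim(x$values), collapse = " x "),
    " voxels @ ", paste(format(x$spacing), collapse = " x "), " mm",
    "; total ", format(sum(x$values) / 1e6, digits = 6), " MBq\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.planar_image <- function(x, ...) {
  cat(
    "<planar_image> ", paste(dim(x$values), collapse = " x "),
    " pixels @ ", paste(format(x$spacing), collapse = " x "), " mm",
    "; total ", format(sum(x$values), digits = 6), " counts\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(
    "<roi_mask> '", x$label, "' ", paste(dim(x$selected), collapse = " x "),
    "; ", sum(x$selected), " selected\n",
    sep = ""
  )
  invisible(x)
}
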