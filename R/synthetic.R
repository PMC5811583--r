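# Synthetic quantitative-image generator with known ground truth: a NEMA
# IQ-style sphere phantom and patient-like scenes (hepatic distribution plus
# a small extrahepatic deposition), rasterized with sub-voxel partial-volume
# fractions, blurred with a sum-preserving isotropic Gaussian PSF, and
# optionally Poisson-noised. Stands in for quantitative SPECT/CT scans.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sphere specification
#'
#' One hot sphere of the phantom (or a sphere-like deposition): physical
#' center, true volume, and activity concentration. The radius is derived
#' from the volume, r = (3V / 4 pi)^(1/3).
#'
#' @param center physical center (mm), length 3.
#' @param volume_ml true volume in ml (> 0).
#' @param concentration activity concentration in MBq/ml (>= 0).
#' @return An object of class `sphere_spec` with derived `radius_mm`.
#' @export
sphere_spec <- function(center, volume_ml, concentration) {
  center <- as.numeric(center)
  volume_ml <- as.numeric(volume_ml)[1]
  concentration <- as.numeric(concentration)[1]
  if (length(center) != 3L || any(!is.finite(center))) {
    stop("`center` must be 3 finite numbers (mm)")
  }
  if (!is.finite(volume_ml) || volume_ml <= 0) stop("`volume_ml` must be > 0")
  if (!is.finite(concentration) || concentration < 0) {
    stop("`concentration` must be >= 0 (MBq/ml)")
  }
  radius_mm <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  structure(
    list(center = center, volume_ml = volume_ml,
         concentration = concentration, radius_mm = radius_mm),
    class = "sphere_spec"
  )
}

#' Default NEMA IQ sphere set
#'
#' The six fillable spheres of the NEMA NU2 image-quality phantom, spanning
#' 0.5 to 26.5 ml, arranged on a ring in the central transaxial plane. The
#' ring radius is widened (70 mm) relative to the physical phantom so that
#' per-sphere margin delineations at the default PSF stay well separated.
#'
#' @param volumes_ml sphere volumes, largest NEMA set by default.
#' @param concentration common activity concentration (MBq/ml). The phantom
#'   solution concentration is a free parameter of the experiment; the
#'   calibration properties are concentration-invariant.
#' @param ring_radius radius (mm) of the ring of sphere centers.
#' @param z axial position (mm) of the sphere plane.
#' @return List of [sphere_spec()].
#' @export
nema_iq_spheres <- function(volumes_ml = c(0.5, 1.2, 2.6, 5.6, 11.5, 26.5),
                            concentration = 1.0,
                            ring_radius = 70, z = 0) {
  angles <- (seq_along(volumes_ml) - 1) * 2 * pi / length(volumes_ml)
  mapply(function(v, a) {
    sphere_spec(center = c(ring_radius * cos(a), ring_radius * sin(a), z),
                volume_ml = v, concentration = concentration)
  }, volumes_ml, angles, SIMPLIFY = FALSE)
}

#' Phantom specification
#'
#' Geometry and imaging parameters of the synthetic IQ phantom: the sphere
#' set, the water-filled background compartment (9.7 L, cold by default),
#' the voxel grid, the system PSF, and the noise settings.
#'
#' @param spheres list of [sphere_spec()]; defaults to [nema_iq_spheres()].
#' @param background_volume_l background compartment volume (L), default 9.7.
#' @param background_concentration background concentration (MBq/ml),
#'   default 0 (cold water).
#' @param grid_shape voxel grid dimensions.
#' @param spacing voxel spacing (mm); 4.8 mm isotropic by default, the
#'   reconstruction matrix of the quantitative scans.
#' @param psf_fwhm isotropic Gaussian PSF full width at half maximum (mm);
#'   default 12, a typical medium-energy-collimator SPECT resolution.
#' @param noise_enabled apply voxel-wise Poisson noise after blurring.
#' @param counts_per_bq scaling from Bq to Poisson counts (default 1).
#' @param seed integer seed for the noise generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(spheres = nema_iq_spheres(),
                         background_volume_l = 9.7,
                         background_concentration = 0,
                         grid_shape = c(96, 96, 48),
                         spacing = c(4.8, 4.8, 4.8),
                         psf_fwhm = 12,
                         noise_enabled = FALSE,
                         counts_per_bq = 1,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2),
            length(spacing) == 3L, all(spacing > 0),
            psf_fwhm >= 0, counts_per_bq > 0,
            background_volume_l > 0, background_concentration >= 0)
  if (!length(spheres) || !all(vapply(spheres, inherits, TRUE, "sphere_spec"))) {
    stop("`spheres` must be a nonempty list of sphere_spec")
  }
  structure(
    list(spheres = spheres,
         background_volume_l = background_volume_l,
         background_concentration = background_concentration,
         grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         psf_fwhm = psf_fwhm, noise_enabled = isTRUE(noise_enabled),
         counts_per_bq = counts_per_bq, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Patient-like scene specification
#'
#' A simplified anatomy with known ground truth: a large hepatic activity
#' distribution (ellipsoid), two lung fields (ellipsoids, for the planar
#' lung-shunt projection), and one small extrahepatic deposition (sphere)
#' disjoint from the liver. Defaults emulate the extrahepatic-deposition
#' regime observed clinically: a ~250 MBq scout dose of which a few MBq
#' (default 3.7 MBq in 15.3 ml) lodge extrahepatically.
#'
#' @param liver_center,liver_semiaxes liver ellipsoid geometry (mm).
#' @param liver_activity_mbq total hepatic activity (MBq).
#' @param deposition_center deposition sphere center (mm).
#' @param deposition_volume_ml true deposition volume (ml).
#' @param deposition_activity_mbq total deposition activity (MBq; may be 0).
#' @param lung_centers list of two lung ellipsoid centers (mm).
#' @param lung_semiaxes common lung ellipsoid semi-axes (mm).
#' @param lung_activity_mbq total lung (shunted) activity (MBq).
#' @param margin_mm margin added to the deposition radius for the margin
#'   delineation; default 2.5 x `psf_fwhm`, wide enough to cover the blurred
#'   support of the deposition.
#' @inheritParams phantom_spec
#' @return An object of class `patient_scene_spec`.
#' @export
patient_scene_spec <- function(liver_center = c(-80, 0, -60),
                               liver_semiaxes = c(75, 55, 65),
                               liver_activity_mbq = 220,
                               deposition_center = c(110, 0, -20),
                               deposition_volume_ml = 15.3,
                               deposition_activity_mbq = 3.7,
                               lung_centers = list(c(-55, 0, 100), c(55, 0, 100)),
                               lung_semiaxes = c(45, 40, 45),
                               lung_activity_mbq = 30,
                               grid_shape = c(96, 96, 72),
                               spacing = c(4.8, 4.8, 4.8),
                               psf_fwhm = 12,
                               noise_enabled = FALSE,
                               counts_per_bq = 1,
                               seed = 1L,
                               margin_mm = NULL) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2),
            length(spacing) == 3L, all(spacing > 0), psf_fwhm >= 0,
            counts_per_bq > 0, liver_activity_mbq >= 0,
            deposition_activity_mbq >= 0, lung_activity_mbq >= 0,
            deposition_volume_ml > 0)
  if (is.null(margin_mm)) margin_mm <- 2.5 * max(psf_fwhm, 4.8)
  if (is.matrix(lung_centers)) {
    lung_centers <- lapply(seq_len(nrow(lung_centers)),
                           function(i) lung_centers[i, ])
  }
  structure(
    list(liver_center = as.numeric(liver_center),
         liver_semiaxes = as.numeric(liver_semiaxes),
         liver_activity_mbq = liver_activity_mbq,
         deposition_center = as.numeric(deposition_center),
         deposition_volume_ml = deposition_volume_ml,
         deposition_activity_mbq = deposition_activity_mbq,
         lung_centers = lapply(lung_centers, as.numeric),
         lung_semiaxes = as.numeric(lung_semiaxes),
         lung_activity_mbq = lung_activity_mbq,
         grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         psf_fwhm = psf_fwhm, noise_enabled = isTRUE(noise_enabled),
         counts_per_bq = counts_per_bq, seed = as.integer(seed),
         margin_mm = margin_mm),
    class = "patient_scene_spec"
  )
}

# Physical coordinates of voxel centers along one axis (0-based indices);
# the grid is centered on the physical origin.
grid_axis <- function(n, sp) (seq_len(n) - 1 - (n - 1) / 2) * sp

grid_origin <- function(grid_shape, spacing) -(grid_shape - 1) / 2 * spacing

# Fractional voxel fill of a sphere: voxels well inside get 1, well outside
# 0. Boundary-band voxels get a semi-analytic partial-volume fraction: the
# in-sphere column length along z is exact, and the transaxial (x, y)
# integral is a midpoint rule on an nsub x nsub sub-grid. The continuous
# column-length integrand makes this accurate to ~0.1% per sphere even for
# the 0.5 ml sphere on 4.8 mm voxels.
rasterize_sphere <- function(grid_shape, spacing, center, radius, nsub = 16L) {
  ax <- lapply(1:3, function(k) grid_axis(grid_shape[k], spacing[k]))
  idx <- lapply(1:3, function(k) {
    which(abs(ax[[k]] - center[k]) <= radius + spacing[k])
  })
  frac <- array(0, grid_shape)
  if (any(lengths(idx) == 0)) return(frac)
  g <- expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]])
  dx <- ax[[1]][g$i] - center[1]
  dy <- ax[[2]][g$j] - center[2]
  dz <- ax[[3]][g$k] - center[3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  halfdiag <- sqrt(sum((spacing / 2)^2))
  f <- as.numeric(d <= radius - halfdiag)
  band <- which(d < radius + halfdiag & d > radius - halfdiag)
  if (length(band)) {
    off1 <- (seq_len(nsub) - (nsub + 1) / 2) / nsub
    offs <- as.matrix(expand.grid(off1 * spacing[1], off1 * spacing[2]))
    hz <- spacing[3]
    acc <- numeric(length(band))
    for (s in seq_len(nrow(offs))) {
      q <- radius^2 - (dx[band] + offs[s, 1])^2 - (dy[band] + offs[s, 2])^2
      zmax <- sqrt(pmax(0, q))
      acc <- acc + pmax(0, pmin(dz[band] + hz / 2, zmax) -
                          pmax(dz[band] - hz / 2, -zmax)) / hz
    }
    f[band] <- acc / nrow(offs)
  }
  frac[cbind(g$i, g$j, g$k)] <- f
  frac
}

# Fractional voxel fill of an axis-aligned ellipsoid, same semi-analytic
# scheme: exact column length along z, midpoint sub-grid in (x, y), applied
# in the normalized-radius boundary band.
rasterize_ellipsoid <- function(grid_shape, spacing, center, semiaxes,
                                nsub = 8L) {
  ax <- lapply(1:3, function(k) grid_axis(grid_shape[k], spacing[k]))
  idx <- lapply(1:3, function(k) {
    which(abs(ax[[k]] - center[k]) <= semiaxes[k] + spacing[k])
  })
  frac <- array(0, grid_shape)
  if (any(lengths(idx) == 0)) return(frac)
  g <- expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]])
  u <- (ax[[1]][g$i] - center[1]) / semiaxes[1]
  v <- (ax[[2]][g$j] - center[2]) / semiaxes[2]
  dz <- ax[[3]][g$k] - center[3]
  rho <- sqrt(u^2 + v^2 + (dz / semiaxes[3])^2)
  delta <- sqrt(sum((spacing / (2 * semiaxes))^2))
  f <- as.numeric(rho <= 1 - delta)
  band <- which(rho < 1 + delta & rho > 1 - delta)
  if (length(band)) {
    off1 <- (seq_len(nsub) - (nsub + 1) / 2) / nsub
    offs <- as.matrix(expand.grid(off1 * spacing[1] / semiaxes[1],
                                  off1 * spacing[2] / semiaxes[2]))
    hz <- spacing[3]
    acc <- numeric(length(band))
    for (s in seq_len(nrow(offs))) {
      q <- 1 - (u[band] + offs[s, 1])^2 - (v[band] + offs[s, 2])^2
      zmax <- semiaxes[3] * sqrt(pmax(0, q))
      acc <- acc + pmax(0, pmin(dz[band] + hz / 2, zmax) -
                          pmax(dz[band] - hz / 2, -zmax)) / hz
    }
    f[band] <- acc / nrow(offs)
  }
  frac[cbind(g$i, g$j, g$k)] <- f
  frac
}

gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  offs <- -half:half
  k <- exp(-0.5 * (offs / sigma_vox)^2)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (d in seq_along(offs)) {
    o <- offs[d]
    j <- which(seq_len(n) + o >= 1L & seq_len(n) + o <= n)
    M[cbind(j + o, j)] <- M[cbind(j + o, j)] + k[d]
  }
  M
}

#' Blur an activity array with an isotropic Gaussian PSF
#'
#' Separable convolution with a discrete Gaussian whose taps are normalized
#' to sum to one, so total activity is conserved as long as the object keeps
#' a margin from the grid border (zero padding loses only the out-of-grid
#' tail).
#'
#' @param arr 3-D numeric array.
#' @param spacing voxel spacing (mm).
#' @param fwhm PSF full width at half maximum (mm); 0 is the identity.
#' @return Blurred array of the same shape.
#' @export
blur_gaussian <- function(arr, spacing, fwhm) {
  if (fwhm < 0) stop("`fwhm` must be >= 0")
  if (fwhm == 0) return(arr)
  sigma <- fwhm * FWHM_TO_SIGMA
  d <- dim(arr)
  M1 <- gaussian_kernel_matrix(d[1], sigma / spacing[1])
  arr <- array(M1 %*% matrix(arr, d[1], d[2] * d[3]), d)
  M2 <- gaussian_kernel_matrix(d[2], sigma / spacing[2])
  arr <- aperm(array(M2 %*% matrix(aperm(arr, c(2, 1, 3)), d[2], d[1] * d[3]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))
  M3 <- gaussian_kernel_matrix(d[3], sigma / spacing[3])
  arr <- aperm(array(M3 %*% matrix(aperm(arr, c(3, 1, 2)), d[3], d[1] * d[2]),
                     c(d[3], d[1], d[2])), c(2, 3, 1))
  arr
}

#' Apply voxel-wise Poisson noise
#'
#' Voxel activities are scaled to expected counts (`value * counts_per_bq`),
#' replaced by Poisson draws, and scaled back, emulating counting statistics
#' in a quantitative reconstruction. The draw is seeded and leaves the
#' global RNG state untouched.
#'
#' @param image a [voxel_image()].
#' @param counts_per_bq expected counts per Bq of voxel activity.
#' @param seed integer seed.
#' @return A noisy [voxel_image()] on the same grid.
#' @export
apply_poisson_noise <- function(image, counts_per_bq = 1, seed = 1L) {
  if (!inherits(image, "voxel_image")) stop("`image` must be a voxel_image")
  lam <- image$values * counts_per_bq
  noisy <- with_seed(seed, stats::rpois(length(lam), lam)) / counts_per_bq
  voxel_image(array(noisy, dim(lam)), image$spacing, image$origin)
}

check_psf_margin <- function(center, reach, grid_shape, spacing, what) {
  half <- grid_shape * spacing / 2
  if (any(abs(center) + reach > half)) {
    stop(what, " at (", paste(round(center, 1), collapse = ", "),
         ") mm with reach ", round(reach, 1),
         " mm overlaps the grid border (half-extent ",
         paste(round(half, 1), collapse = ", "), " mm)")
  }
}

#' Generate a synthetic IQ phantom image
#'
#' Rasterizes each sphere with sub-voxel partial-volume fractions onto the
#' voxel grid (uniform concentration inside; optional hot background in a
#' cylindrical compartment), convolves with the Gaussian PSF, and optionally
#' applies seeded Poisson noise. Spheres must be mutually disjoint and keep
#' a margin of at least twice the PSF FWHM from the grid border.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` (a [voxel_image()], Bq per voxel), `truth`
#'   (data frame: sphere index, center, true volume ml, true activity MBq,
#'   concentration, and the seed used), and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  ns <- length(spec$spheres)
  for (a in seq_len(ns)) {
    sa <- spec$spheres[[a]]
    check_psf_margin(sa$center, sa$radius_mm + 2 * spec$psf_fwhm,
                     spec$grid_shape, spec$spacing, paste0("sphere ", a))
    for (b in seq_len(ns)) {
      if (b <= a) next
      sb <- spec$spheres[[b]]
      if (sqrt(sum((sa$center - sb$center)^2)) < sa$radius_mm + sb$radius_mm) {
        stop("spheres ", a, " and ", b, " overlap")
      }
    }
  }
  vox_ml <- prod(spec$spacing) / 1000
  arr <- array(0, spec$grid_shape)
  bg_frac <- NULL
  if (spec$background_concentration > 0) {
    # Background compartment as a centered cylinder of the specified volume.
    height <- 0.8 * spec$grid_shape[3] * spec$spacing[3]
    r_bg <- sqrt(spec$background_volume_l * 1e6 / (pi * height))
    bg_frac <- rasterize_cylinder(spec$grid_shape, spec$spacing, r_bg, height)
    arr <- arr + spec$background_concentration * bg_frac * vox_ml * 1e6
  }
  truth <- data.frame(
    sphere = seq_len(ns),
    center_x = vapply(spec$spheres, function(s) s$center[1], 0),
    center_y = vapply(spec$spheres, function(s) s$center[2], 0),
    center_z = vapply(spec$spheres, function(s) s$center[3], 0),
    volume_ml = vapply(spec$spheres, function(s) s$volume_ml, 0),
    concentration_mbq_ml = vapply(spec$spheres, function(s) s$concentration, 0),
    activity_mbq = vapply(spec$spheres,
                          function(s) s$concentration * s$volume_ml, 0),
    seed = spec$seed
  )
  for (s in spec$spheres) {
    frac <- rasterize_sphere(spec$grid_shape, spec$spacing, s$center,
                             s$radius_mm)
    add <- (s$concentration - spec$background_concentration) * frac
    arr <- arr + add * vox_ml * 1e6  # MBq/ml * ml -> MBq -> Bq
  }
  arr <- blur_gaussian(arr, spec$spacing, spec$psf_fwhm)
  arr[arr < 0] <- 0
  img <- voxel_image(arr, spec$spacing,
                     grid_origin(spec$grid_shape, spec$spacing))
  if (spec$noise_enabled) {
    img <- apply_poisson_noise(img, spec$counts_per_bq, spec$seed)
  }
  list(image = img, truth = truth, spec = spec)
}

rasterize_cylinder <- function(grid_shape, spacing, radius, height) {
  ax <- lapply(1:3, function(k) grid_axis(grid_shape[k], spacing[k]))
  r2 <- outer(ax[[1]]^2, ax[[2]]^2, "+")
  inplane <- r2 <= radius^2
  inz <- abs(ax[[3]]) <= height / 2
  frac <- array(0, grid_shape)
  for (k in which(inz)) frac[, , k] <- inplane
  frac
}

#' Per-sphere margin masks for a phantom image
#'
#' A sphere of radius `true radius + margin_mm` around each sphere center,
#' restricted to the Voronoi cell of that center so masks are disjoint even
#' when margins would touch. Emulates the generous manual delineation drawn
#' around each object to capture displaced counts.
#'
#' @param image the phantom [voxel_image()].
#' @param truth the ground-truth table from [generate_phantom()].
#' @param margin_mm margin beyond the true radius; default twice the PSF
#'   FWHM of the default phantom (24 mm).
#' @return List of [roi_mask()], one per sphere, labelled `sphere_<i>`.
#' @export
phantom_margin_masks <- function(image, truth, margin_mm = 24) {
  stopifnot(inherits(image, "voxel_image"))
  d <- dim(image$values)
  ax <- lapply(1:3, function(k) grid_axis(d[k], image$spacing[k]))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  centers <- as.matrix(truth[, c("center_x", "center_y", "center_z")])
  d2 <- sapply(seq_len(nrow(centers)), function(i) {
    (g$x - centers[i, 1])^2 + (g$y - centers[i, 2])^2 + (g$z - centers[i, 3])^2
  })
  nearest <- max.col(-d2, ties.method = "first")
  lapply(seq_len(nrow(centers)), function(i) {
    r <- (3 * truth$volume_ml[i] * 1000 / (4 * pi))^(1 / 3) + margin_mm
    sel <- array(d2[, i] <= r^2 & nearest == i, d)
    roi_mask(sel, label = paste0("sphere_", truth$sphere[i]))
  })
}

#' Generate a synthetic patient-like scene
#'
#' Builds the activity distribution (liver ellipsoid, two lung fields, one
#' extrahepatic deposition normalized to its exact total activity), blurs it
#' with the PSF, optionally applies Poisson noise, and returns organ label
#' masks, the margin delineation around the deposition (covering its blurred
#' support, excluding liver voxels), and the ground-truth record.
#'
#' @param spec a [patient_scene_spec()].
#' @return A list with `image`, `margin_mask`, `liver_mask`, `lung_mask`
#'   (3-D [roi_mask()]s), `truth` (true deposition activity MBq, volume ml,
#'   liver/lung activities, seed), and `spec`.
#' @export
generate_patient_scene <- function(spec) {
  if (!inherits(spec, "patient_scene_spec")) {
    stop("`spec` must be a patient_scene_spec")
  }
  dep_r <- (3 * spec$deposition_volume_ml * 1000 / (4 * pi))^(1 / 3)
  check_psf_margin(spec$deposition_center, dep_r + spec$margin_mm,
                   spec$grid_shape, spec$spacing, "deposition")
  liver_frac <- rasterize_ellipsoid(spec$grid_shape, spec$spacing,
                                    spec$liver_center, spec$liver_semiaxes)
  dep_frac <- rasterize_sphere(spec$grid_shape, spec$spacing,
                               spec$deposition_center, dep_r)
  if (any(liver_frac > 0 & dep_frac > 0)) {
    stop("deposition overlaps the liver region; they must be disjoint")
  }
  lung_frac <- array(0, spec$grid_shape)
  for (c0 in spec$lung_centers) {
    lung_frac <- lung_frac +
      rasterize_ellipsoid(spec$grid_shape, spec$spacing, c0, spec$lung_semiaxes)
  }
  lung_frac <- pmin(lung_frac, 1)
  add_norm <- function(arr, frac, total_mbq) {
    s <- sum(frac)
    if (s > 0 && total_mbq > 0) arr + frac * (total_mbq * 1e6 / s) else arr
  }
  arr <- array(0, spec$grid_shape)
  arr <- add_norm(arr, liver_frac, spec$liver_activity_mbq)
  arr <- add_norm(arr, lung_frac, spec$lung_activity_mbq)
  arr <- add_norm(arr, dep_frac, spec$deposition_activity_mbq)
  arr <- blur_gaussian(arr, spec$spacing, spec$psf_fwhm)
  arr[arr < 0] <- 0
  img <- voxel_image(arr, spec$spacing,
                     grid_origin(spec$grid_shape, spec$spacing))
  if (spec$noise_enabled) {
    img <- apply_poisson_noise(img, spec$counts_per_bq, spec$seed)
  }
  d <- spec$grid_shape
  ax <- lapply(1:3, function(k) grid_axis(d[k], spec$spacing[k]))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  d2 <- (g$x - spec$deposition_center[1])^2 +
    (g$y - spec$deposition_center[2])^2 +
    (g$z - spec$deposition_center[3])^2
  margin_sel <- array(d2 <= (dep_r + spec$margin_mm)^2, d) & liver_frac == 0
  list(
    image = img,
    margin_mask = roi_mask(margin_sel, label = "deposition_margin"),
    liver_mask = roi_mask(liver_frac > 0, label = "liver"),
    lung_mask = roi_mask(lung_frac > 0, label = "lungs"),
    truth = list(
      deposition_activity_mbq = spec$deposition_activity_mbq,
      deposition_volume_ml = spec$deposition_volume_ml,
      liver_activity_mbq = spec$liver_activity_mbq,
      lung_activity_mbq = spec$lung_activity_mbq,
      seed = spec$seed
    ),
    spec = spec
  )
}

#' Project a scene to anterior/posterior planar images
#'
#' Sums the voxel image along the anteroposterior axis (axis 2; the anterior
#' detector faces the low-index side) to emulate planar scintigraphy, with
#' an optional single-coefficient exponential depth attenuation. Organ ROI
#' masks are the projected label footprints, identical for both views. With
#' attenuation off the two views are identical; with attenuation on, the
#' geometric mean of paired ROI sums cancels the depth dependence up to the
#' common half-thickness factor — the property the lung-shunt-fraction
#' equation exploits.
#'
#' @param image the scene [voxel_image()].
#' @param lung_mask,liver_mask 3-D organ label [roi_mask()]s congruent with
#'   `image`.
#' @param mu linear attenuation coefficient (per mm); default 0 (off).
#' @return List with `anterior`, `posterior` ([planar_image()]s) and
#'   `lung_roi`, `liver_roi` (2-D [roi_mask()]s).
#' @export
project_planar <- function(image, lung_mask, liver_mask, mu = 0) {
  if (!inherits(image, "voxel_image")) stop("`image` must be a voxel_image")
  if (missing(lung_mask) || missing(liver_mask) ||
      !inherits(lung_mask, "roi_mask") || !inherits(liver_mask, "roi_mask")) {
    stop("lung and liver label masks are required")
  }
  check_congruent(image, lung_mask)
  check_congruent(image, liver_mask)
  if (mu < 0) stop("`mu` must be >= 0")
  d <- dim(image$values)
  sy <- image$spacing[2]
  depth_ant <- (seq_len(d[2]) - 0.5) * sy          # to the anterior face
  depth_post <- (d[2] - seq_len(d[2]) + 0.5) * sy  # to the posterior face
  proj <- function(w) {
    v <- sweep(image$values, 2, w, "*")
    apply(v, c(1, 3), sum)
  }
  ant <- proj(exp(-mu * depth_ant))
  post <- proj(exp(-mu * depth_post))
  sp2 <- image$spacing[c(1, 3)]
  list(
    anterior = planar_image(ant, spacing = sp2),
    posterior = planar_image(post, spacing = sp2),
    lung_roi = roi_mask(apply(lung_mask$selected, c(1, 3), any),
                        label = lung_mask$label),
    liver_roi = roi_mask(apply(liver_mask$selected, c(1, 3), any),
                         label = liver_mask$label)
  )
}
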