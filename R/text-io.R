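# Plain-text interchange: CSV for planar images and 2-D masks (inspectable
# test fixtures), CSV for ground-truth tables, JSON for scene/phantom specs.

#' Write a planar image (or 2-D mask) to CSV
#'
#' The first line is a comment carrying the pixel spacing
#' (`# planar_image,spacing_mm,<sx>,<sy>`); the remaining lines are rows of
#' values. Masks are written as 0/1 with their label in the comment line.
#'
#' @param x a [planar_image()] or a 2-D [roi_mask()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_planar_csv <- function(x, path) {
  if (inherits(x, "planar_image")) {
    header <- paste0("# planar_image,spacing_mm,",
                     x$spacing[1], ",", x$spacing[2])
    m <- x$values
  } else if (inherits(x, "roi_mask")) {
    if (length(dim(x$selected)) != 2L) stop("CSV masks must be 2-D")
    header <- paste0("# roi_mask,label,", x$label)
    m <- array(as.integer(x$selected), dim(x$selected))
  } else {
    stop("`x` must be a planar_image or 2-D roi_mask")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_planar_table <- function(path) {
  if (!file.exists(path)) stop("cannot read planar CSV: no such file: ", path)
  first <- readLines(path, n = 1L)
  meta <- NULL
  skip <- 0L
  if (startsWith(first, "#")) {
    meta <- strsplit(sub("^#\\s*", "", first), ",")[[1]]
    skip <- 1L
  }
  m <- as.matrix(utils::read.table(path, sep = ",", skip = skip,
                                   header = FALSE))
  dimnames(m) <- NULL
  list(values = m, meta = meta)
}

#' Read a planar image from CSV
#'
#' @param path a CSV written by [write_planar_csv()] (or any headerless
#'   numeric CSV; spacing then defaults to 4.8 mm pixels).
#' @return A [planar_image()].
#' @export
read_planar_csv <- function(path) {
  x <- read_planar_table(path)
  spacing <- c(4.8, 4.8)
  if (!is.null(x$meta) && identical(x$meta[1], "planar_image")) {
    spacing <- as.numeric(x$meta[3:4])
  }
  planar_image(x$values, spacing = spacing)
}

#' Read a 2-D ROI mask from CSV
#'
#' @param path a CSV of 0/1 values, optionally with the comment line written
#'   by [write_planar_csv()].
#' @param label ROI name; defaults to the label stored in the file, else the
#'   file name.
#' @return An [roi_mask()].
#' @export
read_mask_csv <- function(path, label = NULL) {
  x <- read_planar_table(path)
  if (is.null(label)) {
    label <- if (!is.null(x$meta) && identical(x$meta[1], "roi_mask") &&
                 length(x$meta) >= 3) x$meta[3] else basename(path)
  }
  roi_mask(x$values != 0, label = label)
}

spec_to_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a phantom specification from JSON
#'
#' @param path JSON file with the fields of [phantom_spec()]; absent fields
#'   take the defaults.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop("cannot read spec: no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spheres <- NULL
  if (!is.null(x$spheres)) {
    spheres <- lapply(seq_len(nrow(x$spheres)), function(i) {
      s <- x$spheres[i, ]
      sphere_spec(center = unlist(s$center), volume_ml = s$volume_ml,
                  concentration = s$concentration)
    })
  }
  args <- x[setdiff(names(x), "spheres")]
  if (!is.null(spheres)) args$spheres <- spheres
  do.call(phantom_spec, args)
}

#' Read a patient-scene specification from JSON
#'
#' @param path JSON file with the fields of [patient_scene_spec()]; absent
#'   fields take the defaults.
#' @return A [patient_scene_spec()].
#' @export
read_patient_scene_spec <- function(path) {
  if (!file.exists(path)) stop("cannot read spec: no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(patient_scene_spec, x)
}

#' Write a phantom or patient-scene specification to JSON
#'
#' @param spec a [phantom_spec()] or [patient_scene_spec()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_spec_json <- function(spec, path) {
  if (inherits(spec, "phantom_spec")) {
    out <- unclass(spec)
    out$spheres <- do.call(rbind, lapply(spec$spheres, function(s) {
      data.frame(center = I(list(s$center)), volume_ml = s$volume_ml,
                 concentration = s$concentration)
    }))
  } else if (inherits(spec, "patient_scene_spec")) {
    out <- unclass(spec)
  } else {
    stop("`spec` must be a phantom_spec or patient_scene_spec")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
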