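# Pipeline layer: one entry point dispatching the analysis stages
# (simulate-phantom, simulate-patient, calibrate, quantify, lsf, summarize),
# writing CSV/JSON reports that embed the effective configuration and seed.
# Timestamps are logged to stderr only, so every output file is regenerable
# bit-for-bit from its embedded configuration.

PIPELINE_STAGES <- c("simulate-phantom", "simulate-patient", "calibrate",
                     "quantify", "lsf", "summarize")

log_info <- function(quiet, ...) {
  if (!quiet) {
    message("[scoutdose ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
  }
}

effective_config <- function(stage, args) {
  c(list(stage = stage,
         version = as.character(utils::packageVersion("scoutdose"))),
    args)
}

require_file <- function(path, what) {
  if (is.null(path)) stop("missing required argument: ", what)
  if (!file.exists(path)) stop(what, " not found: ", path)
  path
}

parse_grid <- function(s) {
  if (is.numeric(s)) return(s)
  p <- as.numeric(strsplit(s, ":")[[1]])
  if (length(p) != 3L || any(!is.finite(p))) {
    stop("grid must be numeric or 'from:to:step', got '", s, "'")
  }
  seq(p[1], p[2], by = p[3])
}

#' Run one pipeline stage
#'
#' Dispatches a stage of the dosimetry pipeline with a named configuration
#' list and writes its report files. Stage errors are re-raised with the
#' stage label; every JSON report embeds the effective configuration
#' (including seed and package version) so it can be regenerated
#' bit-for-bit.
#'
#' Stages and their arguments:
#' \describe{
#'   \item{simulate-phantom}{`spec` (JSON path, optional), `out` (.nii/.nii.gz),
#'     `truth` (CSV), `seed`, `noise` (logical).}
#'   \item{simulate-patient}{`spec` (JSON path, optional), `out`, `mask`
#'     (margin mask .nii), `truth` (JSON), `seed`, `noise`.}
#'   \item{calibrate}{`image`, `truth` (from simulate-phantom), `grid`
#'     ("from:to:step" or numeric), `margin` (mm), `out` (sweep CSV),
#'     `selected` (JSON).}
#'   \item{quantify}{`image`, `mask`, `threshold` (default 0.30), `out`
#'     (record JSON).}
#'   \item{lsf}{either `counts` (4 numbers) or `ant`/`post` planar CSVs with
#'     `lung_mask`/`liver_mask` CSVs; optional `out` JSON.}
#'   \item{summarize}{`records` (character vector of record JSON paths),
#'     `out` (cohort CSV).}
#' }
#'
#' @param config named list with `stage` plus stage arguments; `quiet`
#'   suppresses the stderr log.
#' @return The stage result, invisibly (also written to the `out` files).
#' @export
run_pipeline <- function(config) {
  stage <- config$stage
  if (is.null(stage) || !stage %in% PIPELINE_STAGES) {
    stop("invalid config: `stage` must be one of ",
         paste(PIPELINE_STAGES, collapse = ", "))
  }
  quiet <- isTRUE(config$quiet)
  log_info(quiet, "stage ", stage, " starting")
  res <- tryCatch(
    switch(stage,
      "simulate-phantom" = stage_simulate_phantom(config, quiet),
      "simulate-patient" = stage_simulate_patient(config, quiet),
      "calibrate" = stage_calibrate(config, quiet),
      "quantify" = stage_quantify(config, quiet),
      "lsf" = stage_lsf(config, quiet),
      "summarize" = stage_summarize(config, quiet)
    ),
    error = function(e) {
      stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  log_info(quiet, "stage ", stage, " done")
  invisible(res)
}

stage_simulate_phantom <- function(config, quiet) {
  spec <- if (!is.null(config$spec)) {
    read_phantom_spec(require_file(config$spec, "phantom spec"))
  } else {
    phantom_spec(seed = as.integer(config$seed %||% 1L),
                 noise_enabled = isTRUE(config$noise))
  }
  ph <- generate_phantom(spec)
  if (!is.null(config$out)) write_image(ph$image, config$out)
  if (!is.null(config$truth)) {
    utils::write.csv(ph$truth, config$truth, row.names = FALSE)
  }
  log_info(quiet, "phantom: ", nrow(ph$truth), " spheres, total ",
           format(sum(ph$image$values) / 1e6, digits = 6), " MBq, seed ",
           spec$seed)
  ph
}

stage_simulate_patient <- function(config, quiet) {
  spec <- if (!is.null(config$spec)) {
    read_patient_scene_spec(require_file(config$spec, "patient scene spec"))
  } else {
    patient_scene_spec(seed = as.integer(config$seed %||% 1L),
                       noise_enabled = isTRUE(config$noise))
  }
  sc <- generate_patient_scene(spec)
  if (!is.null(config$out)) write_image(sc$image, config$out)
  if (!is.null(config$mask)) {
    write_mask(sc$margin_mask, config$mask, spacing = sc$image$spacing,
               origin = sc$image$origin)
  }
  if (!is.null(config$truth)) {
    jsonlite::write_json(
      c(sc$truth, list(config = effective_config("simulate-patient",
                                                 unclass(spec)))),
      config$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  log_info(quiet, "patient scene: deposition ",
           spec$deposition_activity_mbq, " MBq / ",
           spec$deposition_volume_ml, " ml, seed ", spec$seed)
  sc
}

stage_calibrate <- function(config, quiet) {
  image <- read_image(require_file(config$image, "phantom image"))
  truth <- utils::read.csv(require_file(config$truth, "truth table"))
  grid <- parse_grid(config$grid %||% "0.05:0.95:0.05")
  margin <- as.numeric(config$margin %||% 24)
  masks <- phantom_margin_masks(image, truth, margin_mm = margin)
  sweep <- sweep_thresholds(image, masks, truth, grid = grid)
  selected <- select_threshold(sweep,
                               min_volume_ml = as.numeric(config$min_volume %||% 1))
  if (!is.null(config$out)) {
    utils::write.csv(sweep$table, config$out, row.names = FALSE)
  }
  if (!is.null(config$selected)) {
    jsonlite::write_json(
      list(selected_threshold = selected,
           config = effective_config("calibrate",
                                     list(image = config$image,
                                          truth = config$truth,
                                          grid = grid, margin_mm = margin))),
      config$selected, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  log_info(quiet, "selected threshold: ", selected)
  list(sweep = sweep, selected_threshold = selected)
}

stage_quantify <- function(config, quiet) {
  image <- read_image(require_file(config$image, "image"))
  mask <- read_mask(require_file(config$mask, "margin mask"))
  threshold <- as.numeric(config$threshold %||% 0.30)
  constants <- dose_constants(
    energy_per_activity = as.numeric(config$energy_per_activity %||% 15.87),
    tissue_density = as.numeric(config$tissue_density %||% 1.06)
  )
  rec <- quantify_deposition(image, mask, threshold, constants)
  if (!is.null(config$out)) {
    jsonlite::write_json(
      c(unclass(rec)[c("activity_mbq", "volume_ml", "dose_gy",
                       "threshold_fraction", "mask_label",
                       "margin_volume_ml")],
        list(constants = unclass(constants),
             config = effective_config("quantify",
                                       list(image = config$image,
                                            mask = config$mask,
                                            threshold = threshold)))),
      config$out, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  log_info(quiet, sprintf("A = %.3f MBq, V = %.3f ml, D = %.3f Gy",
                          rec$activity_mbq, rec$volume_ml, rec$dose_gy))
  rec
}

stage_lsf <- function(config, quiet) {
  frac <- if (!is.null(config$counts)) {
    counts <- as.numeric(config$counts)
    if (length(counts) != 4L) {
      stop("`counts` needs 4 numbers: lungs_ant lungs_post liver_ant liver_post")
    }
    lung_shunt_fraction(counts)
  } else {
    ant <- read_planar_csv(require_file(config$ant, "anterior planar CSV"))
    post <- read_planar_csv(require_file(config$post, "posterior planar CSV"))
    lung <- read_mask_csv(require_file(config$lung_mask, "lung mask CSV"))
    liver <- read_mask_csv(require_file(config$liver_mask, "liver mask CSV"))
    lsf_from_planar(ant, post, lung, liver)
  }
  cat(sprintf("LSF = %.4f (%.1f%%)\n", frac, 100 * frac))
  if (!is.null(config$out)) {
    jsonlite::write_json(
      list(lsf_fraction = frac, lsf_percent = 100 * frac,
           config = effective_config("lsf", config[setdiff(names(config),
                                                           c("stage", "quiet"))])),
      config$out, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  frac
}

stage_summarize <- function(config, quiet) {
  paths <- config$records
  if (is.null(paths) || !length(paths)) stop("missing required argument: records")
  records <- lapply(paths, function(p) {
    x <- jsonlite::read_json(require_file(p, "record JSON"),
                             simplifyVector = TRUE)
    deposition_record(x$activity_mbq, x$volume_ml,
                      threshold_fraction = x$threshold_fraction %||% 0.30,
                      mask_label = x$mask_label %||% basename(p))
  })
  cs <- cohort_summary(records)
  if (!is.null(config$out)) {
    utils::write.csv(render_cohort_table(records), config$out,
                     row.names = FALSE)
  }
  log_info(quiet, "summarized ", length(records), " records")
  cs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a cohort table with summary rows
#'
#' One row per deposition with volume (ml), activity (MBq), and estimated
#' dose (Gy) rounded to one decimal for display (full precision is retained
#' in the records themselves), followed by min/max rows and the three median
#' conventions. The summary is invariant under record order.
#'
#' @param records list of `deposition_record`s (or a `cohort_summary`).
#' @return Data frame with columns `row`, `volume_ml`, `activity_mbq`,
#'   `dose_gy`.
#' @export
render_cohort_table <- function(records) {
  cs <- if (inherits(records, "cohort_summary")) records else cohort_summary(records)
  df <- cs$records
  body <- data.frame(
    row = as.character(seq_len(nrow(df))),
    volume_ml = round(df$volume_ml, 1),
    activity_mbq = round(df$activity_mbq, 1),
    dose_gy = round(df$dose_gy, 1)
  )
  s <- cs$summary
  pick <- function(stat) {
    vapply(c("volume_ml", "activity_mbq", "dose_gy"),
           function(m) round(s[[stat]][s$metric == m], 1), 0)
  }
  summary_rows <- do.call(rbind, lapply(
    c("min", "lower_median", "median", "upper_median", "max"),
    function(stat) {
      v <- pick(stat)
      data.frame(row = stat, volume_ml = v[["volume_ml"]],
                 activity_mbq = v[["activity_mbq"]], dose_gy = v[["dose_gy"]])
    }
  ))
  rbind(body, summary_rows)
}
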