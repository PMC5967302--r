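# Config-driven orchestration: validate a YAML/JSON task configuration, run
# the named generator or analysis end-to-end, and write outputs plus a
# manifest (inputs, parameters, seed, package version, checksums). A given
# (config, seed) pair reproduces byte-identical numeric outputs.

.task_defaults <- list(
  simulate = list(what = NULL, params = list(), seed = 1L),
  morphometry = list(label_tiff = NULL, nuclei_csv = NULL,
                     channel_tiff = NA_character_, pixel_size = 1,
                     fusion_nuclei_threshold = 16L,
                     elongation_ar_threshold = 3,
                     myhc_threshold = NA_real_,
                     multinucleated_only = FALSE),
  cortical = list(image_tiff = NULL, mask_tiff = NULL, pixel_size = 1,
                  peak_band = c(0, 5), mean_band = c(2, 7),
                  rectangle_width = 1, rectangle_spacing = 2,
                  profile_depth = 12, profile_step = 0.2, phase = 0),
  trap_calibration = list(track_csv = NULL, temperature = 296.15,
                          method = "gaussian_fit"),
  tether = list(bead_csv = NULL, stage_csv = NULL,
                stiffness = NA_real_, calibration_json = NA_character_,
                baseline_window = 0.5, axis = "stage",
                r2_min = 0.98, min_points = 10L),
  traces = list(trace_csv = NULL, t_ref = 60, basal_window = c(0, 60))
)

.sim_generators <- list(
  field = "generate_syncytium_field",
  cortical = "generate_cortical_image",
  trap = "simulate_trapped_bead",
  tether = "simulate_tether_pull",
  fura2 = "generate_fura2_trace",
  population = "generate_intensity_population"
)

#' Validate and normalize a run configuration
#'
#' Reads YAML (or JSON) if given a path, fills documented defaults, and
#' rejects every unknown key with its key path. For `simulate` tasks the
#' `params` block is checked against the formal arguments of the selected
#' generator.
#'
#' @param config A named list, or path to a YAML/JSON file.
#' @return A normalized `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config) || !is.list(config) || length(config) == 0L) {
    stop("config is empty or not a mapping", call. = FALSE)
  }
  task <- config$task
  if (is.null(task) || !task %in% names(.task_defaults)) {
    stop("unknown or missing task: ",
         if (is.null(task)) "<none>" else task,
         " (expected one of: ", paste(names(.task_defaults), collapse = ", "),
         ")", call. = FALSE)
  }
  defaults <- .task_defaults[[task]]
  body <- config[setdiff(names(config), c("task", "seed"))]
  unknown <- setdiff(names(body), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  merged <- utils::modifyList(defaults, body)
  required <- names(defaults)[vapply(defaults, is.null, logical(1))]
  missing <- required[vapply(merged[required], is.null, logical(1))]
  if (length(missing) > 0L) {
    stop("missing required key(s) for task '", task, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  if (task == "simulate") {
    if (!merged$what %in% names(.sim_generators)) {
      stop("unknown simulate target `what`: ", merged$what, call. = FALSE)
    }
    gen <- get(.sim_generators[[merged$what]], mode = "function")
    bad <- setdiff(names(merged$params), names(formals(gen)))
    if (length(bad) > 0L) {
      stop("unknown config key(s): ",
           paste(paste0("params.", bad), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(merged$pixel_size)) {
    .check_positive(merged$pixel_size, "pixel_size")
  }
  out <- c(list(task = task,
                seed = if (is.null(config$seed)) 1L
                       else .check_count(config$seed, "seed", 0L)),
           merged)
  class(out) <- "run_config"
  out
}

.path_or_null <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) NULL else x
}

.require_input <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("missing input for %s: %s", what,
                 if (is.null(path)) "<unset>" else path), call. = FALSE)
  }
  path
}

#' Run a configured task
#'
#' Executes the task named in the config, writes its outputs under
#' `out_dir`, and writes `manifest.json` recording the configuration, seed,
#' package version and an MD5 checksum per output file. Identical
#' (config, seed) pairs produce byte-identical numeric outputs.
#'
#' @param config A `run_config`, named list, or path to a YAML/JSON config.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config's seed.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- .check_count(seed, "seed", 0L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  files <- switch(
    cfg$task,
    simulate = .run_simulate(cfg, p),
    morphometry = .run_morphometry(cfg, p),
    cortical = .run_cortical(cfg, p),
    trap_calibration = .run_trap_calibration(cfg, p),
    tether = .run_tether(cfg, p),
    traces = .run_traces(cfg, p)
  )
  manifest <- list(
    package = "myoquant",
    version = as.character(utils::packageVersion("myoquant")),
    task = cfg$task,
    seed = cfg$seed,
    config = unclass(cfg),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

.run_simulate <- function(cfg, p) {
  params <- cfg$params
  if (is.null(params$seed)) params$seed <- cfg$seed
  switch(
    cfg$what,
    field = {
      if (is.null(params$cells)) {
        params$cells <- random_field_cells(
          seed = params$seed,
          image_shape = if (is.null(params$image_shape)) c(400L, 400L)
                        else params$image_shape,
          pixel_size = if (is.null(params$pixel_size)) 0.5
                       else params$pixel_size)
      }
      fld <- do.call(generate_syncytium_field, params)
      write_label_tiff(fld$label_mask, p("label.tif"))
      write_intensity_tiff(fld$channel, p("channel.tif"))
      write_table_csv(fld$nuclei, p("nuclei.csv"))
      write_table_csv(fld$truth_cells, p("truth_cells.csv"))
      write_table_csv(fld$truth_summary, p("truth_summary.csv"))
      p(c("label.tif", "channel.tif", "nuclei.csv", "truth_cells.csv",
          "truth_summary.csv"))
    },
    cortical = {
      ci <- do.call(generate_cortical_image, params)
      write_label_tiff(ci$mask * 1L, p("mask.tif"))
      write_intensity_tiff(ci$image, p("image.tif"))
      jsonlite::write_json(ci[c("pixel_size", "cortex_depth", "cortex_level",
                                "interior_level", "seed")],
                           p("truth.json"), auto_unbox = TRUE, digits = NA)
      p(c("mask.tif", "image.tif", "truth.json"))
    },
    trap = {
      trk <- do.call(simulate_trapped_bead, params)
      write_table_csv(trk, p("track.csv"))
      jsonlite::write_json(attr(trk, "params"), p("truth.json"),
                           auto_unbox = TRUE, digits = NA)
      p(c("track.csv", "truth.json"))
    },
    tether = {
      tp <- do.call(simulate_tether_pull, params)
      write_table_csv(tp$bead, p("bead.csv"))
      write_table_csv(tp$stage, p("stage.csv"))
      jsonlite::write_json(tp[c("tether_stiffness", "trap_stiffness",
                                "dwell")],
                           p("truth.json"), auto_unbox = TRUE, digits = NA)
      p(c("bead.csv", "stage.csv", "truth.json"))
    },
    fura2 = {
      tr <- do.call(generate_fura2_trace, params)
      write_table_csv(tr, p("trace.csv"))
      jsonlite::write_json(list(amplitude = attr(tr, "amplitude"),
                                baseline = attr(tr, "baseline")),
                           p("truth.json"), auto_unbox = TRUE, digits = NA)
      p(c("trace.csv", "truth.json"))
    },
    population = {
      x <- do.call(generate_intensity_population, params)
      write_table_csv(data.frame(intensity = as.numeric(x),
                                 is_positive = attr(x, "is_positive")),
                      p("population.csv"))
      p("population.csv")
    }
  )
}

.run_morphometry <- function(cfg, p) {
  label <- read_label_tiff(.require_input(cfg$label_tiff, "label_tiff"))
  nuclei <- read_table_csv(.require_input(cfg$nuclei_csv, "nuclei_csv"),
                           required = c("x_px", "y_px"))
  channel_path <- .path_or_null(cfg$channel_tiff)
  channel <- if (is.null(channel_path)) NULL else {
    read_intensity_tiff(.require_input(channel_path, "channel_tiff"))
  }
  mc <- morphometry_config(
    fusion_nuclei_threshold = cfg$fusion_nuclei_threshold,
    elongation_ar_threshold = cfg$elongation_ar_threshold,
    pixel_size = cfg$pixel_size,
    myhc_threshold = .path_or_null(cfg$myhc_threshold),
    multinucleated_only = cfg$multinucleated_only)
  res <- analyze_field(label, nuclei, config = mc, channel = channel)
  write_table_csv(res$records, p("records.csv"))
  write_table_csv(res$summary, p("summary.csv"))
  jsonlite::write_json(c(as.list(res$summary),
                         list(n_unassigned = res$n_unassigned)),
                       p("summary.json"), auto_unbox = TRUE, digits = NA)
  p(c("records.csv", "summary.csv", "summary.json"))
}

.run_cortical <- function(cfg, p) {
  image <- read_intensity_tiff(.require_input(cfg$image_tiff, "image_tiff"))
  mask <- read_label_tiff(.require_input(cfg$mask_tiff, "mask_tiff"))
  cc <- cortical_config(peak_band = cfg$peak_band, mean_band = cfg$mean_band,
                        rectangle_width = cfg$rectangle_width,
                        rectangle_spacing = cfg$rectangle_spacing,
                        profile_depth = cfg$profile_depth,
                        profile_step = cfg$profile_step)
  res <- cortex_cytoplasm_ratio(image, mask, cfg$pixel_size, config = cc,
                                phase = cfg$phase)
  write_table_csv(res$rectangles, p("rectangles.csv"))
  jsonlite::write_json(res[c("ratio", "n_rectangles_used", "n_invalid",
                             "n_zero_mean")],
                       p("summary.json"), auto_unbox = TRUE, digits = NA)
  p(c("rectangles.csv", "summary.json"))
}

.run_trap_calibration <- function(cfg, p) {
  trk <- read_bead_track(.require_input(cfg$track_csv, "track_csv"))
  cal <- stiffness_equipartition(trk, temperature = cfg$temperature,
                                 method = cfg$method)
  jsonlite::write_json(unclass(cal), p("calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  p("calibration.json")
}

.run_tether <- function(cfg, p) {
  bead <- read_bead_track(.require_input(cfg$bead_csv, "bead_csv"))
  stage <- read_stage_track(.require_input(cfg$stage_csv, "stage_csv"))
  calib <- if (!is.null(.path_or_null(cfg$calibration_json))) {
    jsonlite::read_json(.require_input(cfg$calibration_json,
                                       "calibration_json"),
                        simplifyVector = TRUE)
  } else if (!is.null(.path_or_null(cfg$stiffness))) {
    list(k_x = cfg$stiffness)
  } else {
    stop("tether task needs `stiffness` or `calibration_json`",
         call. = FALSE)
  }
  curve <- force_extension_curve(bead, stage, calib,
                                 baseline_window = cfg$baseline_window,
                                 axis = cfg$axis)
  fit <- linear_region_fit(curve, r2_min = cfg$r2_min,
                           min_points = cfg$min_points)
  write_table_csv(curve, p("curve.csv"))
  jsonlite::write_json(fit, p("fit.json"), auto_unbox = TRUE, digits = NA)
  p(c("curve.csv", "fit.json"))
}

.run_traces <- function(cfg, p) {
  tr <- read_trace(.require_input(cfg$trace_csv, "trace_csv"))
  stats_df <- data.frame(
    statistic = c("delta_ratio", "basal_level"),
    value = c(delta_ratio(tr, t_ref = cfg$t_ref),
              basal_level(tr, window = cfg$basal_window)),
    t_ref_s = c(cfg$t_ref, NA),
    window_start_s = c(NA, cfg$basal_window[1]),
    window_end_s = c(NA, cfg$basal_window[2]))
  write_table_csv(stats_df, p("trace_stats.csv"))
  jsonlite::write_json(stats::setNames(as.list(stats_df$value),
                                       stats_df$statistic),
                       p("trace_stats.json"), auto_unbox = TRUE, digits = NA)
  p(c("trace_stats.csv", "trace_stats.json"))
}
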