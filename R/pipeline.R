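#' Configuration for a contractility run
#'
#' Every stage parameter has a default; tile sizes (64/32 px) and the
#' 4-pixel fine search radius are the method's standard values, the rest
#' are documented package defaults.
#'
#' @param input an [image_sequence()], or the path of a multi-page TIFF.
#' @param out_dir output directory (created if missing).
#' @param frame_rate frames per second (required when `input` is a path).
#' @param reference `"auto"` or an explicit reference frame index.
#' @param tile_size,step_frac,search_radius,fine_tile,fine_radius,lambda
#'   flow parameters, see [compute_flow()].
#' @param min_freq dominant-frequency floor, Hz.
#' @param center_threshold convergence threshold for center calls, or
#'   `NULL` to derive it from resting frames via [convergence_threshold()].
#' @param center_min_separation minimum separation of center calls, pixels.
#' @param motion_args arguments for the cheap [frame_motion()] pass.
#' @return list of class `contractility_config`.
#' @export
contractility_config <- function(input, out_dir, frame_rate = NULL,
                                 reference = "auto",
                                 tile_size = 64, step_frac = 0.5,
                                 search_radius = 16, fine_tile = 32,
                                 fine_radius = 4, lambda = "gcv",
                                 min_freq = 0.05, center_threshold = NULL,
                                 center_min_separation = 32,
                                 motion_args = list()) {
  structure(as.list(environment()), class = "contractility_config")
}

config_echo <- function(config) {
  lapply(config, function(x)
    if (inherits(x, "image_sequence"))
      sprintf("<in-memory sequence: %d frames>", length(x$frames)) else x)
}

run_stage <- function(name, timings, code) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(code), error = function(e)
    stopf("stage %s: %s", name, conditionMessage(e)))
  timings[[name]] <- proc.time()[["elapsed"]] - t0
  list(value = out, timings = timings)
}

#' Run the full video contractility pipeline
#'
#' Executes, in order: frame-motion reference selection, two-stage optical
#' flow, beat pattern, power spectrum + dominant frequency, convergence
#' maps and contractile-center calls. All intermediate artifacts are
#' written to `out_dir` (`flow.csv`, `beats.csv`, `spectrum.csv`,
#' `convergence.csv`, `centers.csv`, `summary.json`, `run_record.json`);
#' outputs of completed stages are preserved if a later stage fails. The
#' run is deterministic: identical config + input give byte-identical data
#' files.
#'
#' @param config a [contractility_config()].
#' @return Invisibly, a list with `record` (config echo, package version,
#'   per-stage timings, output checksums) and `results` (the in-memory
#'   stage outputs).
#' @export
run_contractility <- function(config) {
  stopifnot(inherits(config, "contractility_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()

  s <- run_stage("read", timings, {
    if (inherits(config$input, "image_sequence")) config$input
    else {
      if (is.null(config$frame_rate))
        stopf("frame_rate is required when reading a TIFF stack")
      read_image_stack(config$input, 1 / config$frame_rate)
    }
  })
  sequence <- s$value; timings <- s$timings

  s <- run_stage("reference", timings, {
    if (identical(config$reference, "auto")) {
      motion <- do.call(frame_motion, c(list(sequence), config$motion_args))
      list(motion = motion, index = select_reference(motion))
    } else list(motion = NULL, index = as.integer(config$reference))
  })
  ref <- s$value; timings <- s$timings

  s <- run_stage("flow", timings, compute_flow(
    sequence, reference_index = ref$index, tile_size = config$tile_size,
    step_frac = config$step_frac, search_radius = config$search_radius,
    fine_tile = config$fine_tile, fine_radius = config$fine_radius,
    lambda = config$lambda))
  flow <- s$value; timings <- s$timings
  write.csv(flow_table(flow), file.path(config$out_dir, "flow.csv"),
            row.names = FALSE)

  s <- run_stage("beats", timings, beat_pattern(flow))
  beats <- s$value; timings <- s$timings
  write.csv(data.frame(frame = seq_along(beats$D), time_s = beats$times,
                       D_px = beats$D),
            file.path(config$out_dir, "beats.csv"), row.names = FALSE)

  s <- run_stage("spectrum", timings, {
    sp <- power_spectrum(beats)
    list(spectrum = sp, dominant = dominant_frequency(sp, config$min_freq))
  })
  spec <- s$value; timings <- s$timings
  write.csv(data.frame(freq_hz = spec$spectrum$frequencies,
                       power = spec$spectrum$power),
            file.path(config$out_dir, "spectrum.csv"), row.names = FALSE)

  s <- run_stage("convergence", timings, {
    series <- convergence_series(flow, lambda = config$lambda)
    thr <- config$center_threshold
    if (is.null(thr)) {
      rest <- which(beats$D <= quantile(beats$D, 0.2))
      thr <- convergence_threshold(series, rest)
    }
    list(series = series,
         centers = locate_centers(series, thr, config$center_min_separation),
         threshold = thr)
  })
  conv <- s$value; timings <- s$timings
  write.csv(convergence_table(conv$series),
            file.path(config$out_dir, "convergence.csv"), row.names = FALSE)
  write.csv(conv$centers, file.path(config$out_dir, "centers.csv"),
            row.names = FALSE)

  summary <- list(
    n_frames = length(sequence$frames),
    frame_rate = 1 / sequence$frame_interval,
    t_star = flow$reference_index,
    f_dominant_hz = spec$dominant$frequency,
    peak_power = spec$dominant$power,
    max_D_px = max(beats$D),
    max_convergence = max(conv$series$max_convergence),
    center_threshold = conv$threshold,
    n_centers = nrow(conv$centers))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  outputs <- file.path(config$out_dir,
                       c("flow.csv", "beats.csv", "spectrum.csv",
                         "convergence.csv", "centers.csv", "summary.json"))
  record <- list(config = config_echo(config),
                 package_version = as.character(packageVersion("cardioflow")),
                 timings = timings,
                 checksums = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(record, file.path(config$out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(record = record,
                 results = list(sequence = sequence, flow = flow,
                                beats = beats, spectrum = spec$spectrum,
                                dominant = spec$dominant,
                                convergence = conv$series,
                                centers = conv$centers, summary = summary)))
}

#' Configuration for a field-potential batch run
#'
#' @param manifest data.frame with columns `well_id`, `file` (CSV paths for
#'   [read_fp_trace()]), and optionally `condition`, `dose`; or a named
#'   list of in-memory [fp_trace()] objects.
#' @param out_dir output directory.
#' @param contrast optional list(`baseline =`, `treated =`) of well ids to
#'   contrast with [drug_contrast()].
#' @param ... metric parameters forwarded to [compute_beat_metrics()].
#' @return list of class `fp_config`.
#' @export
fp_config <- function(manifest, out_dir, contrast = NULL, ...) {
  structure(list(manifest = manifest, out_dir = out_dir,
                 contrast = contrast, metric_args = list(...)),
            class = "fp_config")
}

#' Run field-potential metrics over a batch of wells
#'
#' Computes [compute_beat_metrics()] per well; a well whose file is missing
#' or whose computation errors is flagged `failed` and the run continues.
#' Writes `metrics.json`, a tidy `metrics.csv` (well_id, condition, metric,
#' value), an optional `contrast.json`, and `run_record.json`.
#'
#' @param config an [fp_config()].
#' @return Invisibly, list with `record`, `metrics` (per well), and
#'   `contrast` (or `NULL`).
#' @export
run_fp <- function(config) {
  stopifnot(inherits(config, "fp_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- config$manifest
  timings <- list()

  if (is.data.frame(man)) {
    wells <- man$well_id
    loaders <- lapply(man$file, function(f) function() read_fp_trace(f))
    conditions <- if ("condition" %in% names(man)) man$condition else
      rep(NA_character_, nrow(man))
  } else {
    wells <- names(man)
    loaders <- lapply(man, function(tr) function() tr)
    conditions <- rep(NA_character_, length(man))
  }

  metrics <- list()
  status <- character(length(wells))
  for (i in seq_along(wells)) {
    s <- tryCatch(suppressWarnings({
      tr <- loaders[[i]]()
      m <- do.call(compute_beat_metrics, c(list(tr), config$metric_args))
      metrics[[wells[i]]] <- m
      "ok"
    }), error = function(e) paste("failed:", conditionMessage(e)))
    status[i] <- s
  }

  tidy <- do.call(rbind, lapply(seq_along(wells), function(i) {
    w <- wells[i]
    if (!startsWith(status[i], "ok"))
      return(data.frame(well_id = w, condition = conditions[i],
                        metric = "status", value = NA_real_))
    m <- metrics[[w]]
    data.frame(well_id = w, condition = conditions[i],
               metric = c("mean_beat_period_s", "mean_fpd_s", "fpdc_s",
                          "mean_spike_amplitude", "irregularity_cv",
                          "arrhythmic", "n_beats"),
               value = c(m$mean_beat_period, m$mean_fpd, m$fpdc,
                         m$mean_spike_amplitude, m$irregularity_cv,
                         as.numeric(isTRUE(m$arrhythmic)), m$n_beats))
  }))
  write.csv(tidy, file.path(config$out_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(metrics, function(m) m[c("mean_beat_period", "mean_fpd", "fpdc",
                                    "mean_spike_amplitude",
                                    "irregularity_cv", "arrhythmic",
                                    "n_beats")]),
    file.path(config$out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)

  contrast <- NULL
  if (!is.null(config$contrast)) {
    b <- metrics[[config$contrast$baseline]]
    t <- metrics[[config$contrast$treated]]
    if (!is.null(b) && !is.null(t)) {
      contrast <- drug_contrast(b, t)
      jsonlite::write_json(unclass(contrast),
                           file.path(config$out_dir, "contrast.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  record <- list(wells = as.list(stats::setNames(status, wells)),
                 package_version = as.character(packageVersion("cardioflow")),
                 metric_args = config$metric_args)
  jsonlite::write_json(record, file.path(config$out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(record = record, metrics = metrics, contrast = contrast))
}
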