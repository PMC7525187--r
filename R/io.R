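#' Read a multi-page grayscale TIFF stack
#'
#' First page = frame 1. 8/16-bit (or float) grayscale pages are returned
#' as matrices of intensities in `[0, 1]` as decoded by the TIFF reader.
#'
#' @param path TIFF file.
#' @param frame_interval seconds between frames.
#' @return An [image_sequence()].
#' @export
read_image_stack <- function(path, frame_interval) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # tolerate grey stored with channels
    p
  })
  image_sequence(frames, frame_interval)
}

#' Write an image sequence as a multi-page grayscale TIFF
#'
#' Intensities are clipped to `[0, 1]` and stored at the requested bit
#' depth.
#'
#' @param sequence an [image_sequence()].
#' @param path output file.
#' @param bits bits per sample (default 16).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(sequence, path, bits = 16) {
  stopifnot(inherits(sequence, "image_sequence"))
  frames <- lapply(sequence$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  invisible(path)
}

#' Read a field-potential trace from a two-column CSV
#'
#' Expects columns `time_s` and `voltage` (any further columns are
#' ignored); the sampling rate is inferred from the timestamps.
#'
#' @param path CSV file.
#' @return An [fp_trace()].
#' @export
read_fp_trace <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_s", "voltage") %in% names(d)))
    stopf("'%s' must have columns time_s and voltage", path)
  fp_trace(d$time_s, d$voltage)
}

#' Write a field-potential trace as a two-column CSV
#'
#' @param trace an [fp_trace()].
#' @param path output file.
#' @param ground_truth also write the generator's ground truth (spike
#'   times, FPD) as a JSON sidecar `<path>.json` when present.
#' @return `path`, invisibly.
#' @export
write_fp_trace <- function(trace, path, ground_truth = TRUE) {
  stopifnot(inherits(trace, "fp_trace"))
  write.csv(data.frame(time_s = trace$time, voltage = trace$voltage),
            path, row.names = FALSE)
  gt <- attr(trace, "ground_truth")
  if (ground_truth && !is.null(gt)) {
    jsonlite::write_json(list(spike_times = gt$spike_times, fpd = gt$fpd),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Flatten displacement fields into a long table
#'
#' @param flow a `flow_result`.
#' @return data.frame with `t`, `row`, `col` (tile center, pixels), `drow`,
#'   `dcol`, `score`, `valid`.
#' @export
flow_table <- function(flow) {
  stopifnot(inherits(flow, "flow_result"))
  do.call(rbind, lapply(flow$fields, function(f) {
    data.frame(t = f$t, row = f$grid$centers[, 1], col = f$grid$centers[, 2],
               drow = f$vectors[, 1], dcol = f$vectors[, 2],
               score = f$scores, valid = f$valid)
  }))
}

#' Flatten convergence maps into a long table
#'
#' @param series a `convergence_series`.
#' @return data.frame with `t`, `row`, `col`, `convergence`, `border`.
#' @export
convergence_table <- function(series) {
  stopifnot(inherits(series, "convergence_series"))
  g <- series$grid
  pos_r <- g$rows + (g$tile - 1) / 2
  pos_c <- g$cols + (g$tile - 1) / 2
  do.call(rbind, lapply(seq_along(series$maps), function(i) {
    m <- series$maps[[i]]
    data.frame(t = i,
               row = rep(pos_r, times = length(pos_c)),
               col = rep(pos_c, each = length(pos_r)),
               convergence = as.vector(m$values),
               border = as.vector(m$border))
  }))
}
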