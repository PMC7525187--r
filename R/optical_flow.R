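#' Regular grid of overlapping analysis tiles
#'
#' Tile origins (top-left corners, 1-based) are laid out every `step` pixels
#' starting at `1 + margin`, keeping every tile fully inside the image; the
#' grid is stored column-major (row origin varies fastest) so per-tile values
#' reshape directly into an `nr x nc` matrix.
#'
#' @param shape integer `(H, W)` of the frames.
#' @param tile tile width in pixels.
#' @param step center-to-center spacing in pixels, `<= tile` (tiles overlap).
#' @param margin extra border (pixels) kept free of tiles on every side,
#'   e.g. to guarantee in-bounds search windows for a known search radius.
#' @return An object of class `tile_grid` with `origins`, `centers`
#'   (`n x 2`), `rows`, `cols`, `tile`, `step` and `shape`.
#' @export
tile_grid <- function(shape, tile, step = tile / 2, margin = 0) {
  if (any(shape < tile)) stopf("image (%d x %d) is smaller than one %d-px tile",
                               shape[1], shape[2], tile)
  if (step > tile) stopf("step must be <= tile so tiles overlap or abut")
  if (step < 1) stopf("step must be >= 1 pixel")
  rows <- seq(1 + margin, shape[1] - tile + 1 - margin, by = step)
  cols <- seq(1 + margin, shape[2] - tile + 1 - margin, by = step)
  if (length(rows) == 0 || length(cols) == 0) stopf("tile grid is empty")
  origins <- cbind(rep(rows, times = length(cols)),
                   rep(cols, each = length(rows)))
  structure(list(origins = origins,
                 centers = origins + (tile - 1) / 2,
                 rows = rows, cols = cols,
                 tile = as.integer(tile), step = as.numeric(step),
                 shape = as.integer(shape)),
            class = "tile_grid")
}

new_displacement_field <- function(grid, vectors, scores, valid, level,
                                   t = NA_integer_, reference = NA_integer_) {
  structure(list(grid = grid, vectors = vectors, scores = scores,
                 valid = valid, level = level, t = t, reference = reference),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "displacement_field (%s): %d x %d grid, tile %d px, %d/%d valid\n",
    x$level, length(x$grid$rows), length(x$grid$cols), x$grid$tile,
    sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Match one tile by exhaustive integer-shift search
#'
#' Scans shifts within `+/- search_radius` of the predicted position and
#' returns the shift minimizing the Euclidean distance between the reference
#' tile and the shifted window of the moving frame. Ties are broken by the
#' smallest displacement magnitude, then lexicographically by (drow, dcol).
#' Candidate shifts whose window leaves the frame are skipped; if none is
#' in bounds the result is flagged invalid rather than an error.
#'
#' @param reference,moving numeric frames of identical shape.
#' @param origin 1-based (row, col) top-left corner of the tile in the
#'   reference frame.
#' @param tile tile width in pixels.
#' @param search_radius maximum shift per component, pixels.
#' @param predicted integer (drow, dcol) shift at which the search window is
#'   centered; the returned `shift` is relative to it.
#' @return list with `shift` (integer drow, dcol relative to `predicted`),
#'   `score` (Euclidean intensity distance) and `valid`.
#' @export
match_tile <- function(reference, moving, origin, tile, search_radius,
                       predicted = c(0L, 0L)) {
  res <- match_tiles_cpp(reference, moving,
                         matrix(as.integer(origin), 1),
                         matrix(as.integer(round(predicted)), 1),
                         as.integer(tile), as.integer(search_radius))
  list(shift = as.integer(res[1, 1:2]), score = res[1, 3],
       valid = res[1, 4] == 1)
}

#' Coarse displacement field by tile matching
#'
#' Stage one of the two-stage flow: every (by default 64-px, half-
#' overlapping) tile of the reference frame is located in the moving frame
#' by exhaustive Euclidean-distance search within `search_radius` pixels.
#'
#' @param reference,moving numeric frames of identical shape.
#' @param tile_size tile width, pixels (default 64).
#' @param step tile spacing, pixels (default half the tile: 50% overlap).
#' @param search_radius search extent per component, pixels.
#' @param grid optional pre-built [tile_grid()] (overrides
#'   `tile_size`/`step`).
#' @param normalize standardize both frames (global zero mean, unit sd)
#'   before matching; off by default so raw intensities are compared.
#' @return A `displacement_field` with `level = "coarse"`.
#' @export
coarse_field <- function(reference, moving, tile_size = 64,
                         step = tile_size / 2, search_radius = 16,
                         grid = NULL, normalize = FALSE) {
  if (!all(dim(reference) == dim(moving)))
    stopf("frames must share one shape")
  if (is.null(grid)) grid <- tile_grid(dim(reference), tile_size, step)
  if (normalize) {
    reference <- (reference - mean(reference)) / sd(reference)
    moving <- (moving - mean(moving)) / sd(moving)
  }
  n <- nrow(grid$origins)
  res <- match_tiles_cpp(reference, moving, grid$origins,
                         matrix(0L, n, 2), grid$tile,
                         as.integer(search_radius))
  new_displacement_field(grid, res[, 1:2, drop = FALSE], res[, 3],
                         res[, 4] == 1, "coarse")
}

#' Smooth and interpolate a displacement field with a thin-plate spline
#'
#' Fits one thin-plate spline per displacement component to the valid
#' vectors (invalid tiles are excluded) and evaluates it back on the grid;
#' the fit is also attached as an evaluator for arbitrary positions. The
#' smoothed vectors are real-valued, which is where sub-pixel structure
#' enters an otherwise integer-valued matching pipeline.
#'
#' @param field a `displacement_field`.
#' @param lambda smoothing parameter `>= 0`, or `"gcv"` (default) to choose
#'   it by generalized cross-validation.
#' @return A `displacement_field` with `level = "smoothed"`, an
#'   `"evaluator"` attribute (`function(x)` returning `n x 2` displacements)
#'   and a `"lambda"` attribute recording the value used.
#' @export
tps_smooth <- function(field, lambda = "gcv") {
  stopifnot(inherits(field, "displacement_field"))
  ok <- field$valid
  if (sum(ok) < 3) stopf("need at least 3 valid tiles to fit a spline")
  fit <- tps_fit(field$grid$centers[ok, , drop = FALSE],
                 field$vectors[ok, , drop = FALSE], lambda = lambda)
  vec <- predict(fit, field$grid$centers)
  out <- new_displacement_field(field$grid, vec, field$scores,
                                rep(TRUE, length(field$valid)), "smoothed",
                                field$t, field$reference)
  attr(out, "evaluator") <- function(x) predict(fit, x)
  attr(out, "lambda") <- fit$lambda
  attr(out, "fitted_from") <- ok
  out
}

#' Fine displacement field refined around a coarse prediction
#'
#' Stage two of the flow: smaller tiles (default 32 px) are matched in a
#' narrow window (`fine_radius`, default 4 px) centered on the rounded
#' coarse prediction at each fine tile center. The final vector is the
#' rounded prediction plus the residual shift, so displacements well beyond
#' `fine_radius` are recovered when the coarse stage predicts them.
#'
#' @param reference,moving numeric frames of identical shape.
#' @param coarse_smoothed smoothed field from [tps_smooth()] (its evaluator
#'   provides predictions at the fine tile centers).
#' @param tile_size fine tile width, pixels (default 32).
#' @param step fine tile spacing (default half the tile).
#' @param fine_radius residual search radius, pixels (default 4).
#' @param grid optional pre-built fine [tile_grid()].
#' @param normalize as in [coarse_field()].
#' @return A `displacement_field` with `level = "fine"`; the integer
#'   predictions used are attached as attribute `"prediction"`.
#' @export
fine_field <- function(reference, moving, coarse_smoothed, tile_size = 32,
                       step = tile_size / 2, fine_radius = 4, grid = NULL,
                       normalize = FALSE) {
  stopifnot(inherits(coarse_smoothed, "displacement_field"))
  evaluator <- attr(coarse_smoothed, "evaluator")
  if (is.null(evaluator)) stopf("coarse field must come from tps_smooth()")
  if (is.null(grid)) grid <- tile_grid(dim(reference), tile_size, step)
  if (normalize) {
    reference <- (reference - mean(reference)) / sd(reference)
    moving <- (moving - mean(moving)) / sd(moving)
  }
  pred <- round(evaluator(grid$centers))
  storage.mode(pred) <- "integer"
  res <- match_tiles_cpp(reference, moving, grid$origins, pred, grid$tile,
                         as.integer(fine_radius))
  vec <- pred + res[, 1:2, drop = FALSE]
  out <- new_displacement_field(grid, vec, res[, 3], res[, 4] == 1, "fine")
  attr(out, "prediction") <- pred
  out
}

#' Two-stage displacement fields relative to a reference frame
#'
#' Runs the coarse / thin-plate-spline / fine pipeline between the reference
#' frame and every frame of the sequence. Each frame is processed
#' independently, so the result does not depend on processing order; the
#' field for the reference frame itself is identically zero.
#'
#' @param sequence an [image_sequence()].
#' @param reference_index reference frame `t*` (1-based); if `NULL`, chosen
#'   by [frame_motion()] + [select_reference()].
#' @param tile_size,step_frac,search_radius coarse-stage parameters
#'   (tile width, spacing as a fraction of the tile, search radius).
#' @param fine_tile,fine_radius fine-stage parameters.
#' @param lambda thin-plate-spline smoothing (see [tps_smooth()]).
#' @param margin border kept free of tiles (see [tile_grid()]).
#' @param normalize standardize frames before matching.
#' @param motion_args list of arguments passed to [frame_motion()] when the
#'   reference is selected automatically.
#' @return An object of class `flow_result`: list with `fields` (one fine
#'   `displacement_field` per frame), `grid`, `reference_index`,
#'   `frame_interval` and (when computed) `motion`.
#' @export
compute_flow <- function(sequence, reference_index = NULL,
                         tile_size = 64, step_frac = 0.5, search_radius = 16,
                         fine_tile = 32, fine_radius = 4, lambda = "gcv",
                         margin = 0, normalize = FALSE, motion_args = list()) {
  stopifnot(inherits(sequence, "image_sequence"))
  nf <- length(sequence$frames)
  motion <- NULL
  if (is.null(reference_index)) {
    motion <- do.call(frame_motion, c(list(sequence), motion_args))
    reference_index <- select_reference(motion)
  }
  if (reference_index < 1 || reference_index > nf)
    stopf("reference_index %d outside 1..%d", reference_index, nf)

  shape <- dim(sequence$frames[[1]])
  cgrid <- tile_grid(shape, tile_size, tile_size * step_frac, margin)
  fgrid <- tile_grid(shape, fine_tile, fine_tile * step_frac, margin)
  ref <- sequence$frames[[reference_index]]

  fields <- vector("list", nf)
  for (t in seq_len(nf)) {
    cf <- coarse_field(ref, sequence$frames[[t]], grid = cgrid,
                       search_radius = search_radius, normalize = normalize)
    sm <- tps_smooth(cf, lambda = lambda)
    ff <- fine_field(ref, sequence$frames[[t]], sm, grid = fgrid,
                     fine_radius = fine_radius, normalize = normalize)
    ff$t <- t
    ff$reference <- reference_index
    fields[[t]] <- ff
  }
  structure(list(fields = fields, grid = fgrid,
                 reference_index = reference_index,
                 frame_interval = sequence$frame_interval,
                 motion = motion),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result: %d frames, reference t* = %d, %d fine tiles\n",
              length(x$fields), x$reference_index, nrow(x$grid$origins)))
  invisible(x)
}
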