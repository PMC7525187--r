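#' Convergence map (negative divergence) of a displacement field
#'
#' The divergence `d(drow)/d(row) + d(dcol)/d(col)` is estimated by
#' second-order central differences on the regular tile grid (spacing =
#' grid step); convergence is its negative, so inward flow toward a
#' contractile center is positive. Uniform translation has zero divergence,
#' which is what lets the map separate active contraction from passive
#' drift. Border centers use one-sided differences and are flagged.
#' Values are per frame interval (the field is a displacement relative to
#' the reference state, not a velocity).
#'
#' @param field a `displacement_field` on a regular grid with at least a
#'   2 x 2 layout.
#' @param smooth smooth the field with [tps_smooth()] first (suppresses
#'   integer-matching noise); default `FALSE` so closed-form inputs are
#'   differentiated as given.
#' @param lambda smoothing parameter when `smooth = TRUE`.
#' @return An object of class `convergence_map`: list with `values`
#'   (`nr x nc` matrix), `border` (logical matrix flagging one-sided
#'   stencils), `grid`, `t`.
#' @export
divergence_map <- function(field, smooth = FALSE, lambda = "gcv") {
  stopifnot(inherits(field, "displacement_field"))
  g <- field$grid
  nr <- length(g$rows); nc <- length(g$cols)
  if (nr < 2 || nc < 2) stopf("divergence needs at least a 2 x 2 grid")
  if (nr * nc != nrow(field$vectors)) stopf("grid is not a regular lattice")
  hr <- diff(g$rows); hc <- diff(g$cols)
  if (any(abs(hr - hr[1]) > 1e-9) || any(abs(hc - hc[1]) > 1e-9))
    stopf("grid spacing must be constant")
  if (smooth) field <- tps_smooth(field, lambda = lambda)
  h <- g$step

  Vr <- matrix(field$vectors[, 1], nr, nc)
  Vc <- matrix(field$vectors[, 2], nr, nc)

  ddr <- matrix(NA_real_, nr, nc)
  if (nr > 2) ddr[2:(nr - 1), ] <- (Vr[3:nr, ] - Vr[1:(nr - 2), ]) / (2 * h)
  ddr[1, ] <- (Vr[2, ] - Vr[1, ]) / h
  ddr[nr, ] <- (Vr[nr, ] - Vr[nr - 1, ]) / h

  ddc <- matrix(NA_real_, nr, nc)
  if (nc > 2) ddc[, 2:(nc - 1)] <- (Vc[, 3:nc] - Vc[, 1:(nc - 2)]) / (2 * h)
  ddc[, 1] <- (Vc[, 2] - Vc[, 1]) / h
  ddc[, nc] <- (Vc[, nc] - Vc[, nc - 1]) / h

  border <- matrix(FALSE, nr, nc)
  border[c(1, nr), ] <- TRUE
  border[, c(1, nc)] <- TRUE

  structure(list(values = -(ddr + ddc), border = border, grid = g,
                 t = field$t),
            class = "convergence_map")
}

#' Convergence maps for a whole recording
#'
#' One map per frame plus the per-frame maximum interior convergence, a
#' contraction-strength trace whose oscillation follows the beat. By
#' default each field is thin-plate-spline smoothed before
#' differentiation.
#'
#' @param fields a `flow_result` or list of `displacement_field`s sharing a
#'   grid.
#' @param smooth,lambda see [divergence_map()]; smoothing defaults ON here.
#' @return An object of class `convergence_series`: list with `maps`,
#'   `max_convergence` (per frame, interior centers only), and `grid`.
#' @export
convergence_series <- function(fields, smooth = TRUE, lambda = "gcv") {
  if (inherits(fields, "flow_result")) fields <- fields$fields
  maps <- lapply(fields, divergence_map, smooth = smooth, lambda = lambda)
  mx <- vapply(maps, function(m) {
    v <- m$values[!m$border]
    if (length(v) == 0) max(m$values) else max(v)
  }, numeric(1))
  structure(list(maps = maps, max_convergence = mx, grid = maps[[1]]$grid),
            class = "convergence_series")
}

#' Reduce a convergence series over time
#'
#' @param series a `convergence_series`.
#' @param reduction `"max"` (default), `"mean"`, or a single frame index.
#' @return list with `values` (`nr x nc`), `frame_of_peak` (index matrix for
#'   the max reduction, else `NULL`), `border`, `grid`.
#' @export
reduce_convergence <- function(series, reduction = "max") {
  stopifnot(inherits(series, "convergence_series"))
  arr <- vapply(series$maps, function(m) m$values,
                matrix(0, nrow(series$maps[[1]]$values),
                       ncol(series$maps[[1]]$values)))
  frame_of_peak <- NULL
  if (identical(reduction, "max")) {
    values <- apply(arr, c(1, 2), max)
    frame_of_peak <- apply(arr, c(1, 2), which.max)
  } else if (identical(reduction, "mean")) {
    values <- apply(arr, c(1, 2), mean)
  } else if (is.numeric(reduction) && length(reduction) == 1) {
    values <- arr[, , reduction]
  } else stopf("reduction must be 'max', 'mean', or a frame index")
  list(values = values, frame_of_peak = frame_of_peak,
       border = series$maps[[1]]$border, grid = series$grid)
}

#' Detection threshold from resting frames
#'
#' Three times the median absolute convergence over the given rest frames:
#' a scale for the discretization/matching noise floor.
#'
#' @param series a `convergence_series`.
#' @param rest_frames indices of frames in a resting state.
#' @return numeric threshold.
#' @export
convergence_threshold <- function(series, rest_frames) {
  stopifnot(inherits(series, "convergence_series"))
  3 * median(abs(unlist(lapply(series$maps[rest_frames],
                               function(m) m$values[!m$border]))))
}

#' Locate contractile centers in a convergence series
#'
#' Local maxima (8-neighborhood) of the time-maximum convergence map that
#' exceed `threshold`, greedily pruned so calls are at least
#' `min_separation` pixels apart, sorted by peak convergence descending.
#' Border centers (one-sided stencils) are excluded.
#'
#' @param series a `convergence_series` (or list of `convergence_map`s).
#' @param threshold minimum peak convergence; see [convergence_threshold()].
#' @param min_separation minimum distance between calls, pixels.
#' @return data.frame with `row`, `col` (pixel position of the grid
#'   center), `peak_convergence` and `frame` (frame attaining the peak);
#'   zero rows when nothing exceeds the threshold.
#' @export
locate_centers <- function(series, threshold, min_separation = 0) {
  if (!inherits(series, "convergence_series"))
    series <- structure(list(maps = series, grid = series[[1]]$grid),
                        class = "convergence_series")
  red <- reduce_convergence(series, "max")
  vals <- red$values
  nr <- nrow(vals); nc <- ncol(vals)
  g <- series$grid

  calls <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (red$border[i, j]) next
    v <- vals[i, j]
    if (!(v > threshold)) next
    nb <- vals[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    if (v < max(nb)) next
    calls[[length(calls) + 1]] <- c(i, j, v)
  }
  if (length(calls) == 0)
    return(data.frame(row = numeric(0), col = numeric(0),
                      peak_convergence = numeric(0), frame = integer(0)))
  m <- do.call(rbind, calls)
  ord <- order(-m[, 3], m[, 1], m[, 2])
  m <- m[ord, , drop = FALSE]

  kept <- integer(0)
  pos_r <- g$rows + (g$tile - 1) / 2
  pos_c <- g$cols + (g$tile - 1) / 2
  for (k in seq_len(nrow(m))) {
    pr <- pos_r[m[k, 1]]; pc <- pos_c[m[k, 2]]
    ok <- TRUE
    for (q in kept) {
      qr <- pos_r[m[q, 1]]; qc <- pos_c[m[q, 2]]
      if (sqrt((pr - qr)^2 + (pc - qc)^2) < min_separation) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, k)
  }
  m <- m[kept, , drop = FALSE]
  fop <- red$frame_of_peak
  data.frame(row = pos_r[m[, 1]], col = pos_c[m[, 2]],
             peak_convergence = m[, 3],
             frame = vapply(seq_len(nrow(m)),
                            function(k) fop[m[k, 1], m[k, 2]], numeric(1)))
}
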