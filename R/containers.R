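#' Landmark series container
#'
#' Holds per-frame 2-D landmark coordinates (in pixels) for a digitized
#' swimming sequence, together with the calibration needed to convert to
#' physical units. The three body landmarks — the two frontal-horn tips
#' (`Fh_left`, `Fh_right`) and the dorsal-thoracic-spine tip (`Dts`) — are
#' mandatory: the body centroid is the mean of the three, and the tail vector
#' CT runs from that centroid to `Dts`. Appendage-tip landmarks (`ant1`
#' antennule, `ant2` antenna, `mand` mandible; right side) are optional but
#' required for angle-based kinematics.
#'
#' @param coords numeric array `[n_frames, n_landmarks, 2]`; the landmark
#'   dimension must carry dimnames naming each landmark.
#' @param frame_rate frames per second (> 0).
#' @param pixel_scale physical size of one pixel, in micrometres (> 0).
#' @param view_plane `"xy"` (dorsal/ventral view) or `"yz"` (lateral view).
#' @param times optional frame times in seconds (strictly increasing);
#'   defaults to `(0:(n-1)) / frame_rate`.
#' @return an object of class `landmark_series`.
#' @export
landmark_series <- function(coords, frame_rate, pixel_scale,
                            view_plane = c("xy", "yz"), times = NULL) {
  view_plane <- match.arg(view_plane)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 2L)
    stopf("coords must be an [n_frames, n_landmarks, 2] array")
  ids <- dimnames(coords)[[2]]
  if (is.null(ids)) stopf("coords must carry landmark names on dimension 2")
  body <- c("Fh_left", "Fh_right", "Dts")
  missing_body <- setdiff(body, ids)
  if (length(missing_body))
    stopf("missing mandatory body landmark(s): %s",
          paste(missing_body, collapse = ", "))
  if (!is.numeric(frame_rate) || frame_rate <= 0) stopf("frame_rate must be > 0")
  if (!is.numeric(pixel_scale) || pixel_scale <= 0) stopf("pixel_scale must be > 0")
  n <- dim(coords)[1]
  if (is.null(times)) times <- (seq_len(n) - 1) / frame_rate
  if (length(times) != n || any(diff(times) <= 0))
    stopf("times must be strictly increasing, one per frame")
  structure(
    list(coords = coords, landmark_ids = ids, times = times,
         frame_rate = frame_rate, pixel_scale = pixel_scale,
         view_plane = view_plane),
    class = "landmark_series")
}

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf("<landmark_series> %d frames, %d landmarks (%s)\n",
              dim(x$coords)[1], dim(x$coords)[2],
              paste(x$landmark_ids, collapse = ", ")))
  cat(sprintf("  frame rate %g fps, pixel scale %g um/px, view %s\n",
              x$frame_rate, x$pixel_scale, x$view_plane))
  invisible(x)
}

n_frames <- function(lm) dim(lm$coords)[1]

#' Gridded 2-D velocity field container
#'
#' A single PIV-style velocity field on a uniform `n_x` by `n_y` grid of
#' square cells. `v1`/`v2` are the two in-plane velocity components in
#' m s^-1 — (u, v) for the dorsal (`xy`) plane, (v, w) for the lateral
#' (`yz`) plane. Cell `[i, j]` is centred at physical position
#' `((i - 0.5) * cell_pitch, (j - 0.5) * cell_pitch)`. Cells flagged in
#' `mask` lie inside the larval body: their velocities are set to `NA` and
#' they are excluded from every downstream fluid statistic.
#'
#' @param v1,v2 numeric matrices `[n_x, n_y]`, velocity components (m s^-1).
#' @param cell_pitch physical size of one cell, metres (> 0).
#' @param mask logical matrix `[n_x, n_y]`, `TRUE` = inside the body;
#'   defaults to all-`FALSE`.
#' @param time frame time in seconds.
#' @return an object of class `velocity_field`.
#' @export
velocity_field <- function(v1, v2, cell_pitch, mask = NULL, time = 0) {
  if (!is.matrix(v1) || !is.matrix(v2) || !all(dim(v1) == dim(v2)))
    stopf("v1 and v2 must be matrices of identical shape")
  if (any(dim(v1) < 2L)) stopf("grid must be at least 2 x 2")
  if (!is.numeric(cell_pitch) || cell_pitch <= 0) stopf("cell_pitch must be > 0")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(v1), ncol(v1))
  if (!all(dim(mask) == dim(v1))) stopf("mask shape must match the grid")
  mask <- mask | is.na(v1) | is.na(v2)  # missing cells are treated as masked
  v1[mask] <- NA_real_
  v2[mask] <- NA_real_
  structure(
    list(v1 = v1, v2 = v2, mask = mask, cell_pitch = cell_pitch, time = time),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- field_speed(x)
  cat(sprintf(
    "<velocity_field> %d x %d cells, pitch %.3g m, t = %.4g s\n",
    nrow(x$v1), ncol(x$v1), x$cell_pitch, x$time))
  cat(sprintf("  %d masked cells; max speed %.3g m/s\n",
              sum(x$mask), suppressWarnings(max(sp, na.rm = TRUE))))
  invisible(x)
}

#' Per-cell flow speed of a velocity field
#'
#' @param field a [velocity_field()].
#' @return matrix of speeds (m s^-1), `NA` in masked cells.
#' @export
field_speed <- function(field) sqrt(field$v1^2 + field$v2^2)

# physical coordinates of cell centres (metres)
cell_centers <- function(field) {
  list(x = (seq_len(nrow(field$v1)) - 0.5) * field$cell_pitch,
       y = (seq_len(ncol(field$v1)) - 0.5) * field$cell_pitch)
}

#' Time-resolved velocity field sequence
#'
#' Pairs a time-ordered list of [velocity_field()] frames (uniform grid
#' geometry) with an optional Lagrangian body track giving, per frame, the
#' body centroid position and tail (CT) vector in metres. The body track is
#' what lets flux be computed in the body frame of reference
#' ([relative_flux()]) and flux lines be re-anchored to the moving larva.
#'
#' @param fields list of [velocity_field()] with strictly increasing times
#'   and identical grid geometry.
#' @param body_track optional `data.frame` with columns `time`, `x`, `y`
#'   (centroid, m) and `ct_x`, `ct_y` (tail vector, m), one row per frame.
#' @return an object of class `velocity_field_sequence`.
#' @seealso [body_track_from_landmarks()]
#' @export
velocity_field_sequence <- function(fields, body_track = NULL) {
  if (!length(fields)) stopf("need at least one field")
  if (!all(vapply(fields, inherits, TRUE, "velocity_field")))
    stopf("fields must all be velocity_field objects")
  dims <- vapply(fields, function(f) dim(f$v1), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all fields must share the same grid shape")
  pitches <- vapply(fields, function(f) f$cell_pitch, 0)
  if (any(abs(pitches - pitches[1]) > 1e-12 * pitches[1]))
    stopf("all fields must share the same cell pitch")
  times <- vapply(fields, function(f) f$time, 0)
  if (length(times) > 1 && any(diff(times) <= 0))
    stopf("field times must be strictly increasing")
  if (!is.null(body_track)) {
    need <- c("time", "x", "y", "ct_x", "ct_y")
    if (!all(need %in% names(body_track)))
      stopf("body_track needs columns: %s", paste(need, collapse = ", "))
    if (nrow(body_track) != length(fields))
      stopf("body_track must have one row per field")
  }
  structure(list(fields = fields, times = times, body_track = body_track),
            class = "velocity_field_sequence")
}

#' @export
print.velocity_field_sequence <- function(x, ...) {
  cat(sprintf("<velocity_field_sequence> %d frames, %d x %d cells, t in [%.4g, %.4g] s%s\n",
              length(x$fields), nrow(x$fields[[1]]$v1), ncol(x$fields[[1]]$v1),
              min(x$times), max(x$times),
              if (is.null(x$body_track)) "" else ", with body track"))
  invisible(x)
}

#' Derive a physical-unit body track from a landmark series
#'
#' Converts the per-frame body centroid (mean of the `Fh_left`, `Fh_right`
#' and `Dts` landmarks) and the CT tail vector from pixels to metres, for
#' attachment to a [velocity_field_sequence()].
#'
#' @param lm a [landmark_series()].
#' @return `data.frame` with columns `time`, `x`, `y`, `ct_x`, `ct_y` (m).
#' @export
body_track_from_landmarks <- function(lm) {
  st <- body_states(lm)           # positions in micrometres
  data.frame(time = st$time,
             x = st$cx * 1e-6, y = st$cy * 1e-6,
             ct_x = st$ct_x * 1e-6, ct_y = st$ct_y * 1e-6)
}
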