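#' Reference line for flux computation
#'
#' A straight segment through the flow field, with a unit normal defining
#' the positive flux direction. By convention the normal is oriented toward
#' the larva's food-capture side, so positive flux means flow toward the
#' body.
#'
#' @param start,end segment endpoints `c(x, y)`, metres.
#' @param normal optional normal vector (normalized internally); defaults
#'   to the left normal of the segment direction, `(-dy, dx) / L`.
#' @param n_samples number of sample points along the segment (>= 2).
#' @return an object of class `flux_line`.
#' @export
flux_line <- function(start, end, normal = NULL, n_samples = 51L) {
  d <- end - start
  len <- sqrt(sum(d^2))
  if (len <= 0) stopf("flux line must have positive length")
  if (n_samples < 2) stopf("need at least 2 sample points")
  if (is.null(normal)) normal <- c(-d[2], d[1]) / len
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stopf("normal must be nonzero")
  structure(list(start = start, end = end, length = len,
                 normal = normal / nn, n_samples = as.integer(n_samples)),
            class = "flux_line")
}

#' Body-anchored flux line
#'
#' Builds the conventional flux lines used for feeding-current analysis:
#' in the dorsal (`xy`) view a segment of length equal to the carapace
#' width W, perpendicular to the tail vector CT and centred on the body
#' axis at an offset along +CT (the posterior carapace margin); in the
#' lateral (`yz`) view a segment of length 1.5 x the carapace height H,
#' parallel to the body axis, displaced perpendicular to CT on the ventral
#' side. The normal points from the line toward the body centroid
#' (anteriorly in xy, dorsally in yz), so positive flux is flow toward the
#' food-capture region.
#'
#' @param centroid body centroid `c(x, y)`, m.
#' @param ct tail vector CT `c(x, y)`, m.
#' @param body_size carapace width W (`xy`) or height H (`yz`), m.
#' @param view `"xy"` or `"yz"`.
#' @param offset distance of the line from the centroid, m: along +CT for
#'   `xy`, perpendicular (ventral) for `yz`. Defaults to `0.5 * body_size`.
#' @param n_samples passed to [flux_line()].
#' @return a [flux_line()].
#' @export
body_flux_line <- function(centroid, ct, body_size, view = c("xy", "yz"),
                           offset = NULL, n_samples = 51L) {
  view <- match.arg(view)
  ct_hat <- ct / sqrt(sum(ct^2))
  perp <- c(-ct_hat[2], ct_hat[1])
  offset <- offset %||% (0.5 * body_size)
  if (view == "xy") {
    len <- body_size
    center <- centroid + offset * ct_hat
    along <- perp
    normal <- -ct_hat               # toward the body (anterior)
  } else {
    len <- 1.5 * body_size
    center <- centroid + offset * perp
    along <- ct_hat
    normal <- -perp                 # back toward the body axis
  }
  flux_line(center - along * len / 2, center + along * len / 2,
            normal = normal, n_samples = n_samples)
}

# shift a flux line rigidly by a displacement vector
translate_line <- function(line, delta) {
  flux_line(line$start + delta, line$end + delta, normal = line$normal,
            n_samples = line$n_samples)
}

#' Flux of a velocity field through a reference line
#'
#' The 2-D analogue of a surface flux: the line integral
#' `Phi = sum (v . n_hat) dl` of the normal velocity component along the
#' segment, evaluated by bilinear interpolation at `n_samples` points and
#' trapezoidal quadrature (exact for fields linear along the line — a
#' uniform flow U aligned with the normal gives exactly `U * L`).
#'
#' Samples falling on masked cells are dropped from the quadrature with a
#' warning; a line lying entirely inside the mask is an error.
#'
#' @param field a [velocity_field()].
#' @param line a [flux_line()].
#' @return flux in m^2 s^-1 (multiply by 1e6 for mm^2 s^-1).
#' @export
flux_through_line <- function(field, line) {
  stopifnot(inherits(field, "velocity_field"), inherits(line, "flux_line"))
  s <- seq(0, 1, length.out = line$n_samples)
  xs <- line$start[1] + s * (line$end[1] - line$start[1])
  ys <- line$start[2] + s * (line$end[2] - line$start[2])
  v1 <- bilinear_sample(field$v1, field$cell_pitch, xs, ys)
  v2 <- bilinear_sample(field$v2, field$cell_pitch, xs, ys)
  vn <- v1 * line$normal[1] + v2 * line$normal[2]
  if (all(is.na(vn)))
    stopf("degenerate line: every sample point is masked or outside the grid")
  w <- rep(1, line$n_samples); w[c(1, line$n_samples)] <- 0.5
  if (anyNA(vn)) {
    warnf("%d of %d flux samples masked; dropped from the quadrature",
          sum(is.na(vn)), length(vn))
    w[is.na(vn)] <- 0
    vn[is.na(vn)] <- 0
  }
  dl <- line$length / (line$n_samples - 1)
  sum(w * vn) * dl
}

#' Absolute and relative flux over a field sequence
#'
#' Computes, per frame, the flux through a reference line in the
#' laboratory frame ("absolute flux") and in the larva's frame of
#' reference ("relative flux": the flux of the field after subtracting the
#' body centroid velocity from every cell — equivalently the absolute flux
#' minus `(v_body . n_hat) * L`). Relative flux is what decides whether
#' water carrying food approaches or leaves the capture region of a moving
#' animal: fluid comoving with the body has zero relative flux.
#'
#' The body velocity is obtained by central differences of the body track.
#' With `anchor = "body"` the line is rigidly re-anchored each frame to
#' follow the body centroid from its first-frame pose.
#'
#' @param seq a [velocity_field_sequence()] with a body track.
#' @param line a [flux_line()] defined for the first frame's body pose.
#' @param anchor `"body"` (line follows the larva, default) or `"fixed"`.
#' @return an object of class `flux_series`: `data.frame` with columns
#'   `time`, `absolute`, `relative` (mm^2 s^-1) and `body_speed` (m s^-1).
#' @export
relative_flux <- function(seq, line, anchor = c("body", "fixed")) {
  stopifnot(inherits(seq, "velocity_field_sequence"))
  anchor <- match.arg(anchor)
  bt <- seq$body_track
  if (is.null(bt)) stopf("sequence has no body track")
  n <- length(seq$fields)
  vbx <- central_diff(bt$x, bt$time)
  vby <- central_diff(bt$y, bt$time)
  out <- data.frame(time = seq$times, absolute = NA_real_,
                    relative = NA_real_, body_speed = NA_real_)
  for (k in seq_len(n)) {
    if (anyNA(c(bt$x[k], bt$y[k], vbx[k], vby[k]))) {
      warnf("frame %d: missing body pose; skipped", k)
      next
    }
    lk <- if (anchor == "body")
      translate_line(line, c(bt$x[k] - bt$x[1], bt$y[k] - bt$y[1]))
    else line
    f <- seq$fields[[k]]
    phi_abs <- flux_through_line(f, lk)
    rel_field <- velocity_field(f$v1 - vbx[k], f$v2 - vby[k],
                                cell_pitch = f$cell_pitch, mask = f$mask,
                                time = f$time)
    phi_rel <- flux_through_line(rel_field, lk)
    out$absolute[k] <- phi_abs * 1e6
    out$relative[k] <- phi_rel * 1e6
    out$body_speed[k] <- sqrt(vbx[k]^2 + vby[k]^2)
  }
  class(out) <- c("flux_series", "data.frame")
  out
}
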