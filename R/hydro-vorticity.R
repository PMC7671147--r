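#' Out-of-plane vorticity of a velocity field
#'
#' `omega = dv2/dx - dv1/dy` by central differences, falling back to
#' one-sided differences at grid edges and next to masked cells; cells with
#' no usable neighbour in a direction, and masked cells, carry `NA`.
#' Central differencing is exact for fields linear in position, so a linear
#' shear `v1 = k * y` returns exactly `-k` and solid-body rotation at rate
#' `omega0` returns exactly `2 * omega0` in the patch interior.
#'
#' @param field a [velocity_field()].
#' @return an object of class `vorticity_field`: list with `omega`
#'   (matrix, s^-1), `mask`, `cell_pitch`, `time`.
#' @export
vorticity <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  valid <- !field$mask
  if (!any(valid)) stopf("field is fully masked")
  h <- field$cell_pitch
  shift_x <- function(m, s, fill = NA) {       # value at (i + s, j)
    nx <- nrow(m)
    out <- matrix(fill, nx, ncol(m))
    if (s > 0) out[1:(nx - s), ] <- m[(1 + s):nx, ]
    else out[(1 - s):nx, ] <- m[1:(nx + s), ]
    out
  }
  shift_y <- function(m, s, fill = NA) {
    ny <- ncol(m)
    out <- matrix(fill, nrow(m), ny)
    if (s > 0) out[, 1:(ny - s)] <- m[, (1 + s):ny]
    else out[, (1 - s):ny] <- m[, 1:(ny + s)]
    out
  }
  deriv <- function(F, along = c("x", "y")) {
    along <- match.arg(along)
    sh <- if (along == "x") shift_x else shift_y
    Fp <- sh(F, 1); Vp <- sh(valid, 1, fill = FALSE)
    Fm <- sh(F, -1); Vm <- sh(valid, -1, fill = FALSE)
    d <- matrix(NA_real_, nrow(F), ncol(F))
    both <- valid & Vp & Vm
    d[both] <- (Fp[both] - Fm[both]) / (2 * h)
    fwd <- valid & Vp & !Vm
    d[fwd] <- (Fp[fwd] - F[fwd]) / h
    bwd <- valid & !Vp & Vm
    d[bwd] <- (F[bwd] - Fm[bwd]) / h
    d
  }
  omega <- deriv(field$v2, "x") - deriv(field$v1, "y")
  omega[field$mask] <- NA_real_
  structure(list(omega = omega, mask = field$mask,
                 cell_pitch = field$cell_pitch, time = field$time),
            class = "vorticity_field")
}

#' Find vortex regions and their circulation
#'
#' Delimits vortices as connected components (4-connectivity) of cells
#' whose |vorticity| reaches `threshold_fraction` of the field's peak
#' |vorticity|, split by vorticity sign so every region is single-signed.
#' Each region's circulation is the discrete area integral
#' `Gamma = sum(omega) * dx * dy`. When a body state is supplied each
#' region is assigned to the left or right of the body axis by the sign of
#' the cross product of the tail vector CT with the centroid-to-region
#' vector (`"right"` when `ct_x * ry - ct_y * rx < 0`, i.e. starboard of an
#' animal whose CT points along +y in a y-up frame).
#'
#' @param vort a `vorticity_field` from [vorticity()].
#' @param threshold_fraction fraction of peak |omega| in (0, 1).
#' @param body_centroid,body_ct optional body centroid position and CT
#'   vector (metres) for side assignment.
#' @return list of vortex regions, each a list with `cells` (two-column
#'   index matrix), `sign`, `circulation` (mm^2 s^-1), `area` (mm^2),
#'   `peak_omega` (s^-1), `centroid` (m) and `side` (`"left"`, `"right"`
#'   or `NA`). Empty list when the field has no nonzero vorticity.
#' @export
find_vortices <- function(vort, threshold_fraction = 0.1,
                          body_centroid = NULL, body_ct = NULL) {
  stopifnot(inherits(vort, "vorticity_field"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stopf("threshold_fraction must lie in (0, 1)")
  om <- vort$omega
  peak <- suppressWarnings(max(abs(om), na.rm = TRUE))
  if (!is.finite(peak) || peak == 0) return(list())
  h <- vort$cell_pitch
  regions <- list()
  for (sgn in c(1, -1)) {
    sel <- !is.na(om) & sgn * om >= threshold_fraction * peak
    if (!any(sel)) next
    labels <- EBImage::bwlabel(sel * 1)
    for (lab in seq_len(max(labels))) {
      cells <- which(labels == lab, arr.ind = TRUE)
      omv <- om[cells]
      gamma <- sum(omv) * h^2
      cen <- c((mean(cells[, 1]) - 0.5) * h, (mean(cells[, 2]) - 0.5) * h)
      side <- NA_character_
      if (!is.null(body_centroid) && !is.null(body_ct)) {
        r <- cen - body_centroid
        cr <- body_ct[1] * r[2] - body_ct[2] * r[1]
        side <- if (cr < 0) "right" else if (cr > 0) "left" else "on_axis"
      }
      regions[[length(regions) + 1]] <- list(
        cells = cells, sign = sgn,
        circulation = gamma * 1e6,             # mm^2 s^-1
        area = nrow(cells) * h^2 * 1e6,        # mm^2
        peak_omega = sgn * max(sgn * omv),
        centroid = cen, side = side)
    }
  }
  regions[order(-vapply(regions, function(r) abs(r$circulation), 0))]
}

#' Hydrodynamic area of influence
#'
#' The fluid area where the induced flow speed reaches a perceptual
#' threshold — a proxy for how detectable the swimmer is to rheotactic
#' predators. Counts unmasked cells with speed greater than or equal to the
#' threshold and multiplies by the cell area.
#'
#' @param field a [velocity_field()].
#' @param threshold flow-speed cutoff, m s^-1 (default 0.0005, the
#'   detectability threshold used for nauplius-scale disturbances).
#' @return area in mm^2.
#' @export
area_of_influence <- function(field, threshold = 5e-4) {
  stopifnot(inherits(field, "velocity_field"))
  if (threshold <= 0) stopf("threshold must be > 0")
  sp <- field_speed(field)
  sum(sp >= threshold, na.rm = TRUE) * field$cell_pitch^2 * 1e6
}
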