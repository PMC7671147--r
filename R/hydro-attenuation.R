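#' Fit the spatial attenuation power of a flow field
#'
#' Quantifies how fast the flow disturbance decays with distance from the
#' swimmer, assuming a power law `|V| ~ r^n`. The procedure mirrors the
#' standard threshold-binning approach: speed thresholds `U*` are log-spaced
#' between a noise floor and the field's maximum speed; for each threshold
#' the area `S(U*)` covered by flow at or above `U*` is converted to an
#' equivalent-circle radius `r = sqrt(S / pi)`; and `n` is the slope of the
#' ordinary least-squares regression of `ln U*` on `ln r`.
#'
#' Cells inside the body mask, and a one-cell ring around it, are excluded
#' from the speed data (PIV vectors at the body edge are unreliable), but
#' their total area is added back to every `S(U*)`: the excluded region
#' sits at the flow source, where the speed certainly exceeds any
#' threshold, so each iso-speed disc that encloses it must count it.
#' Two kinds of unresolvable bins are then dropped before the regression:
#' thresholds whose equivalent radius exceeds the largest circle fully
#' contained in the grid around the flow source (once the iso-speed
#' contour is clipped by the field of view, `r = sqrt(S / pi)` understates
#' the true radius), and thresholds whose equivalent radius does not
#' exceed the equivalent radius of the excluded region by at least
#' `min_radius_cells` grid cells (the cell-counted area of a contour
#' hugging the hole or spanning a couple of cells carries an O(h/r)
#' perimeter error). The source is taken as the location of peak speed
#' unless given.
#'
#' @param field a [velocity_field()].
#' @param cfg a [run_config()] supplying `attenuation_bins` and
#'   `attenuation_noise_floor`.
#' @param source optional flow source position `c(x, y)` in metres.
#' @param min_radius_cells smallest usable equivalent radius, in cells.
#' @return an object of class `attenuation_fit`: list with `power` (the
#'   fitted n), `intercept`, `r_squared`, and the `(thresholds, areas,
#'   radii)` triples actually used (SI units).
#' @export
attenuation_fit <- function(field, cfg = run_config(), source = NULL,
                            min_radius_cells = 2) {
  stopifnot(inherits(field, "velocity_field"))
  sp <- field_speed(field)
  h <- field$cell_pitch
  # exclude the mask and a 1-cell dilation ring around it from the speed
  # data; their area (the body-occluded hole at the source) is added back
  # to every S(U*) below
  excluded <- matrix(FALSE, nrow(sp), ncol(sp))
  if (any(field$mask))
    excluded <- sliding_extremum(field$mask * 1, 1, "max") > 0
  sp[excluded] <- NA_real_
  if (all(is.na(sp))) stopf("no usable cells after masking")
  hole_area <- sum(excluded) * h^2
  hole_radius <- sqrt(hole_area / pi)
  max_sp <- max(sp, na.rm = TRUE)
  floor_sp <- cfg$attenuation_noise_floor
  if (max_sp <= floor_sp)
    stopf("insufficient data: peak speed %.3g m/s is below the noise floor",
          max_sp)
  thresholds <- exp(seq(log(floor_sp), log(max_sp),
                        length.out = cfg$attenuation_bins))
  areas <- hole_area +
    vapply(thresholds, function(u) sum(sp >= u, na.rm = TRUE) * h^2, 0)
  radii <- sqrt(areas / pi)
  if (is.null(source)) {
    peak_cell <- which(sp == max_sp, arr.ind = TRUE)[1, ]
    source <- (peak_cell - 0.5) * h
  }
  extent <- dim(sp) * h
  r_max <- min(source[1], extent[1] - source[1],
               source[2], extent[2] - source[2])
  keep <- areas > hole_area & radii <= r_max &
    radii >= hole_radius + min_radius_cells * h
  if (sum(keep) < 3)
    stopf("insufficient data: fewer than 3 usable threshold bins")
  lr <- log(radii[keep]); lu <- log(thresholds[keep])
  if (diff(range(lr)) < 1e-9)
    stopf("insufficient data: no decay structure (iso-speed area does not shrink)")
  fit <- lm(lu ~ lr)
  structure(list(power = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 thresholds = thresholds[keep], areas = areas[keep],
                 radii = radii[keep], n_bins_used = sum(keep)),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf("<attenuation_fit> power n = %.3f (r^2 = %.3f, %d bins)\n",
              x$power, x$r_squared, x$n_bins_used))
  invisible(x)
}

#' Per-frame attenuation power of a field sequence
#'
#' Convenience wrapper running [attenuation_fit()] on every frame; the
#' frame of peak flow speed (the peak of the power stroke) is flagged,
#' since that frame's power is the conventional summary value.
#'
#' @param seq a [velocity_field_sequence()].
#' @param cfg a [run_config()].
#' @return `data.frame` with columns `time`, `power`, `r_squared`,
#'   `max_speed`, `is_peak`; frames where the fit fails carry `NA`.
#' @export
attenuation_series <- function(seq, cfg = run_config()) {
  stopifnot(inherits(seq, "velocity_field_sequence"))
  rows <- lapply(seq$fields, function(f) {
    ms <- suppressWarnings(max(field_speed(f), na.rm = TRUE))
    fit <- tryCatch(attenuation_fit(f, cfg), error = function(e) NULL)
    data.frame(time = f$time,
               power = if (is.null(fit)) NA_real_ else fit$power,
               r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
               max_speed = ms)
  })
  out <- do.call(rbind, rows)
  out$is_peak <- seq_len(nrow(out)) == which.max(out$max_speed)
  out
}
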