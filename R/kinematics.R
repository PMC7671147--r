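#' Per-frame body state from a landmark series
#'
#' The body centroid is the mean of the three body landmarks (both
#' frontal-horn tips and the dorsal-thoracic-spine tip); the tail vector CT
#' runs from the centroid to the Dts tip. Coordinates are converted to
#' micrometres here — the single px-to-physical conversion point of the
#' pipeline.
#'
#' @param lm a [landmark_series()].
#' @return `data.frame` with columns `time` (s), `cx`, `cy` (centroid, um),
#'   `ct_x`, `ct_y` (CT vector, um).
#' @export
body_states <- function(lm) {
  um <- lm$coords * lm$pixel_scale
  body <- c("Fh_left", "Fh_right", "Dts")
  cx <- rowMeans(um[, body, 1, drop = FALSE][, , 1])
  cy <- rowMeans(um[, body, 2, drop = FALSE][, , 1])
  ct_x <- um[, "Dts", 1] - cx
  ct_y <- um[, "Dts", 2] - cy
  if (any(ct_x == 0 & ct_y == 0))
    stopf("degenerate geometry: CT vector is zero in some frame")
  data.frame(time = lm$times, cx = cx, cy = cy, ct_x = ct_x, ct_y = ct_y)
}

#' Angle between an appendage and the tail vector
#'
#' The appendage angle theta is the angle between CA (centroid to appendage
#' tip) and CT (centroid to tail-spine tip):
#' `theta = acos(CA . CT / (|CA| |CT|))`, in `[0, 180]` degrees. 0 means
#' the tip points along the tail; 180 means it points directly forward.
#'
#' @param centroid,tip,tail_tip 2-vectors (same units; any consistent
#'   Cartesian frame — the angle is invariant under rigid motions).
#' @return angle in degrees.
#' @export
appendage_angle <- function(centroid, tip, tail_tip) {
  ca <- tip - centroid
  ct <- tail_tip - centroid
  na <- sqrt(sum(ca^2)); nt <- sqrt(sum(ct^2))
  if (na == 0 || nt == 0)
    stopf("degenerate geometry: zero-length CA or CT vector")
  rad2deg(acos(clamp(sum(ca * ct) / (na * nt), -1, 1)))
}

#' Classify a displacement step as forward, backward or neutral
#'
#' Sign-of-dot-product rule: a displacement whose dot product with the tail
#' vector CT is negative points away from the tail, i.e. the animal moved
#' forward; positive means backward; zero means no displacement component
#' along the body axis.
#'
#' @param disp displacement 2-vector.
#' @param ct_vector tail vector CT (nonzero).
#' @return `"forward"`, `"backward"` or `"neutral"`.
#' @export
classify_displacement <- function(disp, ct_vector) {
  if (all(ct_vector == 0)) stopf("CT vector must be nonzero")
  d <- sum(disp * ct_vector)
  if (d < 0) "forward" else if (d > 0) "backward" else "neutral"
}

# 3-point moving average with replicated ends
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  c(x[1], (x[-c(1, 2)] + x[-c(1, n)] + x[-c(n - 1, n)]) / 3, x[n])
}

# central-difference derivative (one-sided at the ends), per second
central_diff <- function(x, times) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (times[2] - times[1])
  d[n] <- (x[n] - x[n - 1]) / (times[n] - times[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (times[i + 1] - times[i - 1])
  }
  d
}

#' Segment an antenna angle series into stroke cycles
#'
#' Cycle boundaries sit at successive minima of the (3-point smoothed)
#' antenna angle. Within each cycle the power stroke is the set of frames
#' where the smoothed angular velocity carries the power-stroke sign
#' (negative — appendage sweeping toward the tail — when
#' `power_stroke_decreasing`, the default), the recovery stroke is the
#' complement, and the mid-stroke frames are the frames of highest
#' unsmoothed angular speed within each interval (ties broken toward the
#' earlier frame).
#'
#' @param theta antenna angle series, degrees.
#' @param frame_rate frames s^-1 (used to build time stamps; may be
#'   overridden by `times`).
#' @param times optional explicit frame times, s.
#' @param power_stroke_decreasing see [run_config()].
#' @return list of cycles, each a list with `start_frame`, `end_frame`
#'   (boundary indices; the cycle spans `start_frame:(end_frame - 1)`),
#'   `power`, `recovery` (frame index vectors), `mid_power`,
#'   `mid_recovery`.
#' @export
segment_cycles <- function(theta, frame_rate, times = NULL,
                           power_stroke_decreasing = TRUE) {
  n <- length(theta)
  if (is.null(times)) times <- (seq_len(n) - 1) / frame_rate
  s <- smooth3(theta)
  i <- 2:(n - 1)
  is_min <- s[i] < s[i - 1] & s[i] <= s[i + 1]
  bounds <- i[is_min]
  if (length(bounds) < 2)
    stopf("insufficient data: fewer than one complete stroke cycle detected")
  v_smooth <- central_diff(s, times)
  v_raw <- central_diff(theta, times)
  lapply(seq_len(length(bounds) - 1), function(k) {
    frames <- bounds[k]:(bounds[k + 1] - 1)
    in_power <- if (power_stroke_decreasing) v_smooth[frames] < 0
    else v_smooth[frames] > 0
    power <- frames[in_power]
    recovery <- frames[!in_power]
    pick_mid <- function(fr) if (length(fr)) fr[which.max(abs(v_raw[fr]))]
    else NA_integer_
    list(start_frame = bounds[k], end_frame = bounds[k + 1],
         power = power, recovery = recovery,
         mid_power = pick_mid(power), mid_recovery = pick_mid(recovery))
  })
}

#' Reynolds number of a swimming larva
#'
#' `Re = U * L / nu` with U the average swimming speed, L the larval
#' (carapace) length and nu the kinematic viscosity of the medium.
#'
#' @param speed average swimming speed U, m s^-1.
#' @param length larval length L, m.
#' @param viscosity kinematic viscosity nu, m^2 s^-1 (default: seawater at
#'   25 degrees C, 33 psu).
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(speed, length, viscosity = 9.5e-7) {
  speed * length / viscosity
}

#' Swimming speed in body lengths per second
#'
#' @param speed_mm_s speed in mm s^-1.
#' @param body_length_um body (carapace) length in micrometres.
#' @return speed in body lengths s^-1.
#' @export
speed_in_body_lengths <- function(speed_mm_s, body_length_um) {
  speed_mm_s * 1000 / body_length_um
}

#' Measure swimming and appendage-beat kinematics
#'
#' Computes the full kinematic profile of a digitized swimming bout:
#'
#' \itemize{
#'   \item average swimming speed U (path length / elapsed time by default,
#'     see `speed_mode` in [run_config()]), in mm s^-1 and body lengths
#'     s^-1, and the Reynolds number U L / nu;
#'   \item the forward:backward displacement ratio — per cycle, the summed
#'     magnitude of forward steps over the summed magnitude of backward
#'     steps (dot-product classification against CT), averaged across
#'     cycles; `Inf` with `fwd_bwd_infinite = TRUE` when a cycle has no
#'     backward displacement;
#'   \item beat frequency (detected cycles / elapsed time between first and
#'     last cycle boundary);
#'   \item per-appendage beat amplitude (per-cycle angular range, averaged);
#'   \item per-appendage angular speed at the mid-power and mid-recovery
#'     frames (frames of peak antenna angular speed in each half-stroke),
#'     degrees ms^-1;
#'   \item percent in phase per appendage pair — the percentage of frames
#'     where both appendages' angular velocities carry the same sign
#'     (frames with exactly zero velocity excluded);
#'   \item angular separation per pair at the mid-stroke frames, degrees;
#'   \item the cumulative along-axis displacement curve (forward positive),
#'     micrometres.
#' }
#'
#' @param lm a [landmark_series()] containing at least the body landmarks
#'   and the `ant2` (antenna) tip; `ant1`/`mand` are used when present.
#' @param cfg a [run_config()].
#' @return an object of class `kinematics_result`.
#' @export
measure_kinematics <- function(lm, cfg = run_config()) {
  st <- body_states(lm)
  times <- st$time
  M <- nrow(st)
  if (!"ant2" %in% lm$landmark_ids)
    stopf("ant2 landmark is required for cycle segmentation")
  apps <- intersect(c("ant1", "ant2", "mand"), lm$landmark_ids)
  um <- lm$coords * lm$pixel_scale
  theta <- sapply(apps, function(a) {
    ca_x <- um[, a, 1] - st$cx
    ca_y <- um[, a, 2] - st$cy
    dot <- ca_x * st$ct_x + ca_y * st$ct_y
    den <- sqrt(ca_x^2 + ca_y^2) * sqrt(st$ct_x^2 + st$ct_y^2)
    if (any(den == 0)) stopf("degenerate geometry: zero-length CA vector")
    rad2deg(acos(clamp(dot / den, -1, 1)))
  })
  # --- translation ---------------------------------------------------------
  dx <- diff(st$cx); dy <- diff(st$cy)
  step_len <- sqrt(dx^2 + dy^2)                     # um
  elapsed <- times[M] - times[1]
  path_len <- sum(step_len)
  net_len <- sqrt((st$cx[M] - st$cx[1])^2 + (st$cy[M] - st$cy[1])^2)
  U_um_s <- (if (cfg$speed_mode == "path") path_len else net_len) / elapsed
  L_um <- cfg$body_length %||% {
    fh_x <- (um[, "Fh_left", 1] + um[, "Fh_right", 1]) / 2
    fh_y <- (um[, "Fh_left", 2] + um[, "Fh_right", 2]) / 2
    mean(sqrt((um[, "Dts", 1] - fh_x)^2 + (um[, "Dts", 2] - fh_y)^2))
  }
  speed_mm_s <- U_um_s * 1e-3
  # dot-product direction classification, CT taken at the step's start frame
  dot_ct <- dx * st$ct_x[-M] + dy * st$ct_y[-M]
  step_class <- ifelse(dot_ct < 0, "forward",
                       ifelse(dot_ct > 0, "backward", "neutral"))
  ct_norm <- sqrt(st$ct_x^2 + st$ct_y^2)
  along <- -(dx * st$ct_x[-M] + dy * st$ct_y[-M]) / ct_norm[-M]
  cumulative <- cumsum(c(0, along))
  # --- cycles --------------------------------------------------------------
  cycles <- segment_cycles(theta[, "ant2"], lm$frame_rate, times = times,
                           power_stroke_decreasing = cfg$power_stroke_decreasing)
  n_cyc <- length(cycles)
  bounds <- c(vapply(cycles, `[[`, 0L, "start_frame"),
              cycles[[n_cyc]]$end_frame)
  frequency_hz <- n_cyc / (times[bounds[n_cyc + 1]] - times[bounds[1]])
  per_cycle_ratio <- vapply(cycles, function(cy) {
    steps <- cy$start_frame:(cy$end_frame - 1)   # steps starting in cycle
    fwd <- sum(step_len[steps][step_class[steps] == "forward"])
    bwd <- sum(step_len[steps][step_class[steps] == "backward"])
    if (bwd == 0) Inf else fwd / bwd
  }, 0)
  fwd_bwd_ratio <- mean(per_cycle_ratio)
  # --- angles --------------------------------------------------------------
  v_raw <- apply(theta, 2, central_diff, times = times)   # deg s^-1
  amplitude <- vapply(apps, function(a) {
    if (cfg$amplitude_mode == "grand_max") return(diff(range(theta[, a])))
    mean(vapply(cycles, function(cy)
      diff(range(theta[cy$start_frame:cy$end_frame, a])), 0))
  }, 0)
  mid_speed <- function(which_mid) {
    sapply(apps, function(a) mean(vapply(cycles, function(cy) {
      f <- cy[[which_mid]]
      if (is.na(f)) NA_real_ else abs(v_raw[f, a]) / 1000   # deg ms^-1
    }, 0), na.rm = TRUE))
  }
  angular_speed <- cbind(mid_power = mid_speed("mid_power"),
                         mid_recovery = mid_speed("mid_recovery"))
  pairs <- utils::combn(apps, 2)
  pair_names <- apply(pairs, 2, paste, collapse = "_")
  percent_in_phase <- setNames(apply(pairs, 2, function(p) {
    sa <- sign(v_raw[, p[1]]); sb <- sign(v_raw[, p[2]])
    ok <- sa != 0 & sb != 0
    if (!any(ok)) return(NA_real_)
    100 * mean(sa[ok] == sb[ok])
  }), pair_names)
  sep_at <- function(which_mid) {
    setNames(apply(pairs, 2, function(p) mean(vapply(cycles, function(cy) {
      f <- cy[[which_mid]]
      if (is.na(f)) NA_real_ else abs(theta[f, p[1]] - theta[f, p[2]])
    }, 0), na.rm = TRUE)), pair_names)
  }
  angular_separation <- cbind(mid_power = sep_at("mid_power"),
                              mid_recovery = sep_at("mid_recovery"))
  structure(list(
    speed_mm_s = speed_mm_s,
    speed_bl_s = speed_in_body_lengths(speed_mm_s, L_um),
    reynolds = reynolds_number(speed_mm_s * 1e-3, L_um * 1e-6,
                               cfg$kinematic_viscosity),
    fwd_bwd_ratio = fwd_bwd_ratio,
    fwd_bwd_infinite = !is.finite(fwd_bwd_ratio),
    frequency_hz = frequency_hz,
    amplitude_deg = amplitude,
    angular_speed_deg_ms = angular_speed,
    percent_in_phase = percent_in_phase,
    angular_separation_deg = angular_separation,
    cumulative_displacement_um = cumulative,
    body_length_um = L_um,
    n_cycles = n_cyc,
    theta_deg = theta,
    cycles = cycles), class = "kinematics_result")
}

#' @export
print.kinematics_result <- function(x, ...) {
  cat("<kinematics_result>\n")
  cat(sprintf("  speed       %.3g mm/s (%.3g BL/s), Re = %.3g\n",
              x$speed_mm_s, x$speed_bl_s, x$reynolds))
  cat(sprintf("  frequency   %.3g Hz over %d cycles; fwd:bwd = %.3g\n",
              x$frequency_hz, x$n_cycles, x$fwd_bwd_ratio))
  cat(sprintf("  amplitude   %s\n",
              paste(sprintf("%s %.1f", names(x$amplitude_deg),
                            x$amplitude_deg), collapse = ", ")))
  cat(sprintf("  %% in phase  %s\n",
              paste(sprintf("%s %.0f", names(x$percent_in_phase),
                            x$percent_in_phase), collapse = ", ")))
  invisible(x)
}

#' Flatten a kinematics result to a named metric vector
#'
#' Scalar metrics (plus the per-appendage and per-pair values, one name
#' each) in Table-style naming, suitable as a row for [build_summary()].
#'
#' @param res a `kinematics_result`.
#' @return named numeric vector.
#' @export
kinematics_metrics <- function(res) {
  stopifnot(inherits(res, "kinematics_result"))
  out <- c(speed_mm_s = res$speed_mm_s, speed_bl_s = res$speed_bl_s,
           reynolds = res$reynolds,
           fwd_bwd_ratio = if (res$fwd_bwd_infinite) NA_real_
           else res$fwd_bwd_ratio,
           frequency_hz = res$frequency_hz)
  out <- c(out, setNames(res$amplitude_deg,
                         paste0("amplitude_", names(res$amplitude_deg))))
  out <- c(out, setNames(res$percent_in_phase,
                         paste0("in_phase_", names(res$percent_in_phase))))
  for (m in colnames(res$angular_speed_deg_ms))
    out <- c(out, setNames(res$angular_speed_deg_ms[, m],
                           paste0("angspeed_", m, "_",
                                  rownames(res$angular_speed_deg_ms))))
  for (m in colnames(res$angular_separation_deg))
    out <- c(out, setNames(res$angular_separation_deg[, m],
                           paste0("sep_", m, "_",
                                  rownames(res$angular_separation_deg))))
  out
}
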