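#' Specification for a synthetic swimming landmark series
#'
#' Defines the ground truth from which [make_landmarks()] builds a landmark
#' series: appendage angles follow phase-lagged oscillations about
#' per-appendage mean angles, and the body alternates a forward step during
#' the power stroke with a backward step during the recovery stroke.
#'
#' The angle waveform for appendage i is
#' `theta_i(t) = mean_i + (amplitude_i / 2) * cos(psi(u_i))`, where
#' `u_i = frac(f * t + phase_lag_i / 360)` is the cycle phase and `psi` maps
#' the power fraction of the cycle to the decreasing half of the cosine
#' (angle sweeping toward the tail) and the remainder to the increasing
#' half. With `power_fraction = 0.5` this is a pure sinusoid; other values
#' give the asymmetric strokes real nauplii show.
#'
#' @param beat_frequency beat frequency f, Hz.
#' @param amplitude_deg named vector `c(ant1=, ant2=, mand=)`, peak-to-peak
#'   angular amplitude in degrees, each in (0, 180).
#' @param phase_lag_deg named per-appendage phase offsets in degrees of
#'   cycle (antenna conventionally 0); the pairwise lag between a and b is
#'   `phase_lag_a - phase_lag_b`.
#' @param mean_angle_deg named per-appendage mean angle to the tail vector,
#'   degrees; `mean +/- amplitude/2` must stay inside (0, 180).
#' @param forward_step body advance per power stroke, micrometres (> 0).
#' @param backward_step body retreat per recovery stroke, micrometres (>= 0).
#' @param n_cycles number of complete beat cycles.
#' @param frames_per_cycle video frames per cycle (>= 8).
#' @param noise_sd_px s.d. of Gaussian digitizing noise added to every
#'   landmark coordinate, pixels.
#' @param power_fraction fraction of the cycle occupied by the power stroke.
#' @param rng_seed integer seed; generation is deterministic given the seed.
#' @return an object of class `kinematics_spec`.
#' @export
kinematics_spec <- function(beat_frequency,
                            amplitude_deg,
                            phase_lag_deg = c(ant1 = 0, ant2 = 0, mand = 0),
                            mean_angle_deg = c(ant1 = 110, ant2 = 90, mand = 70),
                            forward_step = 100,
                            backward_step = 20,
                            n_cycles = 3L,
                            frames_per_cycle = 40L,
                            noise_sd_px = 0.5,
                            power_fraction = 0.5,
                            rng_seed = 1L) {
  apps <- c("ant1", "ant2", "mand")
  for (v in list(amplitude_deg, phase_lag_deg, mean_angle_deg))
    if (!all(apps %in% names(v)))
      stopf("amplitude, phase lag and mean angle must name ant1, ant2, mand")
  amplitude_deg <- amplitude_deg[apps]
  phase_lag_deg <- phase_lag_deg[apps]
  mean_angle_deg <- mean_angle_deg[apps]
  if (beat_frequency <= 0) stopf("beat_frequency must be > 0")
  if (any(amplitude_deg <= 0 | amplitude_deg >= 180))
    stopf("amplitudes must lie in (0, 180) degrees")
  if (any(mean_angle_deg - amplitude_deg / 2 <= 0 |
          mean_angle_deg + amplitude_deg / 2 >= 180))
    stopf("mean angle +/- amplitude/2 must stay inside (0, 180) degrees")
  if (frames_per_cycle < 8) stopf("frames_per_cycle must be >= 8")
  if (forward_step <= 0 || backward_step < 0)
    stopf("forward_step must be > 0 and backward_step >= 0")
  if (power_fraction <= 0 || power_fraction >= 1)
    stopf("power_fraction must lie in (0, 1)")
  structure(list(beat_frequency = beat_frequency,
                 amplitude_deg = amplitude_deg,
                 phase_lag_deg = phase_lag_deg,
                 mean_angle_deg = mean_angle_deg,
                 forward_step = forward_step,
                 backward_step = backward_step,
                 n_cycles = as.integer(n_cycles),
                 frames_per_cycle = as.integer(frames_per_cycle),
                 noise_sd_px = noise_sd_px,
                 power_fraction = power_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "kinematics_spec")
}

#' Species-level kinematics presets
#'
#' Ready-made [kinematics_spec()]s for the two study morphotypes: the fast
#' lecithotrophic (non-feeding) nauplius and the slower planktotrophic
#' (feeding) nauplius. Beat frequency, per-appendage amplitudes, swimming
#' speed and forward:backward displacement ratio are the group means for
#' *Polyascus planus* and *Tetraclita japonica* stage-II nauplii; the phase
#' lags are chosen so the fraction of time each appendage pair moves in the
#' same direction matches the reported percent-in-phase values
#' (`lag = (1 - p/100) * 180` degrees), giving the metachronal,
#' near-synchronous pattern of the lecithotroph and the anti-phase
#' antennule of the planktotroph. Step sizes derive from speed and ratio:
#' path per cycle = U / f, split fwd:bwd in the reported ratio.
#'
#' @param species `"lecithotroph"` (Polyascus-like) or `"planktotroph"`
#'   (Tetraclita-like).
#' @param ... overrides passed on to [kinematics_spec()].
#' @return a [kinematics_spec()].
#' @export
species_kinematics_spec <- function(species = c("lecithotroph",
                                                "planktotroph"), ...) {
  species <- match.arg(species)
  p <- if (species == "lecithotroph") {
    list(f = 35.7, amp = c(ant1 = 50.8, ant2 = 94.8, mand = 79.0),
         in_phase = c(ant1_ant2 = 67, ant2_mand = 69),
         speed_um_s = 7700, ratio = 6.2)
  } else {
    list(f = 11.4, amp = c(ant1 = 48.9, ant2 = 90.5, mand = 56.5),
         in_phase = c(ant1_ant2 = 52, ant2_mand = 71),
         speed_um_s = 4500, ratio = 9.3)
  }
  path_per_cycle <- p$speed_um_s / p$f
  bwd <- path_per_cycle / (p$ratio + 1)
  fwd <- path_per_cycle - bwd
  lags <- c(ant1 = unname((1 - p$in_phase["ant1_ant2"] / 100) * 180),
            ant2 = 0,
            mand = unname(-(1 - p$in_phase["ant2_mand"] / 100) * 180))
  args <- list(beat_frequency = p$f, amplitude_deg = p$amp,
               phase_lag_deg = lags, forward_step = fwd,
               backward_step = bwd)
  args[names(list(...))] <- list(...)
  do.call(kinematics_spec, args)
}

# piecewise-linear phase warp: power fraction pf of the cycle covers the
# decreasing cosine half [0, pi), the rest the increasing half [pi, 2 pi)
warp_phase <- function(u, pf) {
  ifelse(u < pf, pi * u / pf, pi + pi * (u - pf) / (1 - pf))
}

# appendage angle (deg) at cycle phase u in [0, 1)
synth_theta <- function(u, mean_deg, amp_deg, pf) {
  mean_deg + (amp_deg / 2) * cos(warp_phase(u %% 1, pf))
}

# cumulative along-axis body position (um, forward negative) at continuous
# cycle count U; forward during the power fraction, backward during recovery
synth_body_pos <- function(U, fwd, bwd, pf) {
  ncyc <- floor(U)
  u <- U - ncyc
  within <- ifelse(u < pf, -fwd * u / pf, -fwd + bwd * (u - pf) / (1 - pf))
  (-fwd + bwd) * ncyc + within
}

#' Generate a synthetic landmark series with known ground truth
#'
#' Builds a [landmark_series()] realizing a [kinematics_spec()]: the three
#' body landmarks ride rigidly on a centroid that steps forward (against
#' the tail vector CT) during the power stroke and backward during
#' recovery, and each right-side appendage tip is placed at its prescribed
#' angle to CT. The generator's exact parameter values are attached as
#' `attr(x, "truth")` (frequency, amplitudes, phase lags, expected
#' percent-in-phase, forward:backward ratio, mean path speed) so tests can
#' compare recovered metrics against ground truth.
#'
#' The series spans `n_cycles` complete cycles (`n_cycles *
#' frames_per_cycle + 1` frames), with CT pointing in +y, so forward motion
#' is toward -y and the dot-product displacement rule classifies power-
#' stroke steps as forward.
#'
#' @param spec a [kinematics_spec()].
#' @param pixel_scale micrometres per pixel of the synthetic camera
#'   (default 1, i.e. pixel coordinates are micrometres).
#' @param view_plane recorded in the output series.
#' @return a [landmark_series()] with a `truth` attribute.
#' @export
make_landmarks <- function(spec, pixel_scale = 1, view_plane = "xy") {
  stopifnot(inherits(spec, "kinematics_spec"))
  set.seed(spec$rng_seed)
  N <- spec$frames_per_cycle
  M <- spec$n_cycles * N + 1L
  fps <- spec$beat_frequency * N
  t <- (seq_len(M) - 1) / fps
  pf <- spec$power_fraction
  # body geometry in px, chosen so the centroid is the mean of the three
  # body landmarks and CT = centroid -> Dts points along +y
  offsets <- rbind(Fh_left = c(-60, -100), Fh_right = c(60, -100),
                   Dts = c(0, 200)) / pixel_scale
  tip_radius <- c(ant1 = 80, ant2 = 120, mand = 100) / pixel_scale
  # body track: ant2 phase drives the power/recovery alternation
  U_body <- spec$beat_frequency * t + spec$phase_lag_deg["ant2"] / 360
  y_c <- synth_body_pos(U_body, spec$forward_step, spec$backward_step, pf) /
    pixel_scale
  x_c <- rep(1000 / pixel_scale, M)
  y_c <- y_c + 2000 / pixel_scale
  ids <- c(rownames(offsets), names(tip_radius))
  coords <- array(NA_real_, c(M, length(ids), 2),
                  dimnames = list(NULL, ids, c("x", "y")))
  for (b in rownames(offsets)) {
    coords[, b, 1] <- x_c + offsets[b, 1]
    coords[, b, 2] <- y_c + offsets[b, 2]
  }
  for (a in names(tip_radius)) {
    u <- (spec$beat_frequency * t + spec$phase_lag_deg[a] / 360)
    th <- deg2rad(synth_theta(u, spec$mean_angle_deg[a],
                              spec$amplitude_deg[a], pf))
    # right-side tip: rotate the CT direction (0, 1) by theta
    coords[, a, 1] <- x_c + tip_radius[a] * sin(th)
    coords[, a, 2] <- y_c + tip_radius[a] * cos(th)
  }
  if (spec$noise_sd_px > 0)
    coords <- coords + rnorm(length(coords), sd = spec$noise_sd_px)
  out <- landmark_series(coords, frame_rate = fps, pixel_scale = pixel_scale,
                         view_plane = view_plane)
  pair_lag <- function(a, b) {
    d <- abs(spec$phase_lag_deg[a] - spec$phase_lag_deg[b]) %% 360
    min(d, 360 - d)
  }
  pairs <- rbind(ant1_ant2 = c("ant1", "ant2"),
                 ant1_mand = c("ant1", "mand"),
                 ant2_mand = c("ant2", "mand"))
  in_phase <- vapply(rownames(pairs), function(p)
    100 * (1 - pair_lag(pairs[p, 1], pairs[p, 2]) / 180), 0)
  attr(out, "truth") <- list(
    frequency_hz = spec$beat_frequency,
    amplitude_deg = spec$amplitude_deg,
    phase_lag_deg = spec$phase_lag_deg,
    percent_in_phase = in_phase,
    fwd_bwd_ratio = if (spec$backward_step > 0)
      spec$forward_step / spec$backward_step else Inf,
    speed_um_s = (spec$forward_step + spec$backward_step) *
      spec$beat_frequency,
    power_fraction = pf)
  out
}
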