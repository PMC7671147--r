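test_that("appendage angle follows the arccos dot-product definition", {
  c0 <- c(0, 0)
  tail <- c(0, 1)
  expect_equal(appendage_angle(c0, c(0, 2), tail), 0)
  expect_equal(appendage_angle(c0, c(0, -1), tail), 180)
  expect_equal(appendage_angle(c0, c(1, 1), c(1, 0)), 45)
  expect_error(appendage_angle(c0, c0, tail), "degenerate")
})

test_that("displacement classification follows the sign of the CT dot product", {
  ct <- c(0, 1)
  expect_identical(classify_displacement(c(0, -1), ct), "forward")
  expect_identical(classify_displacement(c(1, 0), ct), "neutral")
  expect_identical(classify_displacement(c(0, 0.1), ct), "backward")
})

test_that("cycle segmentation finds cycles and mid-stroke frames of a sinusoid", {
  fps <- 400; f <- 10; N <- 40   # 40 frames per cycle
  t <- (0:160) / fps             # 4 full cycles
  theta <- 90 + 40 * cos(2 * pi * f * t)
  cyc <- segment_cycles(theta, fps)
  expect_equal(length(cyc), 3L)
  lens <- vapply(cyc, function(c) c$end_frame - c$start_frame, 0L)
  expect_true(all(abs(lens - N) <= 1))
  for (c in cyc) {
    # |d theta/dt| peaks a quarter period after each boundary (minimum)
    expect_lte(abs(c$mid_recovery - (c$start_frame + N / 4)), 1)
    expect_lte(abs(c$mid_power - (c$start_frame + 3 * N / 4)), 1)
    expect_setequal(c(c$power, c$recovery),
                    c$start_frame:(c$end_frame - 1))
  }
  expect_error(segment_cycles(rep(90, 100), fps), "insufficient")
})

test_that("kinematics are invariant under rigid rotation and translation", {
  lm <- clean_swimmer(frames_per_cycle = 40L, n_cycles = 3L)
  a <- pi / 5
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  rot <- lm
  for (k in seq_len(dim(lm$coords)[1])) {
    rot$coords[k, , ] <- sweep(lm$coords[k, , ] %*% t(R), 2, c(-310, 5200),
                               `+`)
  }
  cfg <- run_config(body_length = 265)
  r0 <- measure_kinematics(lm, cfg)
  r1 <- measure_kinematics(rot, cfg)
  expect_equal(r1$theta_deg, r0$theta_deg, tolerance = 1e-9)
  expect_equal(r1$amplitude_deg, r0$amplitude_deg, tolerance = 1e-9)
  expect_equal(r1$speed_mm_s, r0$speed_mm_s, tolerance = 1e-9)
  expect_equal(r1$fwd_bwd_ratio, r0$fwd_bwd_ratio, tolerance = 1e-9)
})

test_that("phase metrics behave as expected for identical series", {
  lm <- make_landmarks(kinematics_spec(
    beat_frequency = 10,
    amplitude_deg = c(ant1 = 60, ant2 = 60, mand = 60),
    phase_lag_deg = c(ant1 = 0, ant2 = 0, mand = 0),
    mean_angle_deg = c(ant1 = 90, ant2 = 90, mand = 90),
    noise_sd_px = 0))
  res <- measure_kinematics(lm, run_config(body_length = 265))
  expect_equal(unname(res$percent_in_phase), rep(100, 3))
  expect_equal(unname(res$angular_separation_deg[, "mid_power"]),
               rep(0, 3), tolerance = 1e-9)
})

test_that("percent-in-phase is symmetric in its arguments", {
  # swapping which appendage carries which series must not change the metric
  spec_ab <- kinematics_spec(
    beat_frequency = 10,
    amplitude_deg = c(ant1 = 40, ant2 = 70, mand = 50),
    phase_lag_deg = c(ant1 = 120, ant2 = 0, mand = 60),
    noise_sd_px = 0)
  spec_ba <- kinematics_spec(
    beat_frequency = 10,
    amplitude_deg = c(ant1 = 70, ant2 = 40, mand = 50),
    phase_lag_deg = c(ant1 = 0, ant2 = 120, mand = 60),
    noise_sd_px = 0)
  cfg <- run_config(body_length = 265)
  p1 <- measure_kinematics(make_landmarks(spec_ab), cfg)$percent_in_phase
  p2 <- measure_kinematics(make_landmarks(spec_ba), cfg)$percent_in_phase
  expect_equal(unname(p1["ant1_ant2"]), unname(p2["ant1_ant2"]))
})

test_that("cumulative displacement telescopes to the net axial displacement", {
  lm <- clean_swimmer()
  res <- measure_kinematics(lm, run_config(body_length = 265))
  st <- body_states(lm)
  M <- nrow(st)
  # motion is purely axial here, so the telescoped sum equals the net
  # centroid displacement projected on the (constant) forward direction
  net_forward <- -( (st$cx[M] - st$cx[1]) * st$ct_x[1] +
                      (st$cy[M] - st$cy[1]) * st$ct_y[1]) /
    sqrt(st$ct_x[1]^2 + st$ct_y[1]^2)
  cum <- res$cumulative_displacement_um
  expect_equal(cum[length(cum)], net_forward, tolerance = 1e-9)
})

test_that("printed morphometrics reproduce the reported derived quantities", {
  # speed 4.5 mm/s at carapace length 447.4 um is about 10 BL/s and Re 2.1
  expect_equal(speed_in_body_lengths(4.5, 447.4), 10.06, tolerance = 1e-3)
  expect_equal(reynolds_number(4.5e-3, 447.4e-6, 9.5e-7), 2.12,
               tolerance = 1e-2)
})
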