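# shared fixture builders; everything is generated in code at test time

# noise-free synthetic swimmer at a convenient resolution
clean_swimmer <- function(frames_per_cycle = 50L, n_cycles = 4L, ...) {
  make_landmarks(species_kinematics_spec(
    "lecithotroph", noise_sd_px = 0,
    frames_per_cycle = as.integer(frames_per_cycle),
    n_cycles = as.integer(n_cycles), ...))
}

# uniform field expressed in px/frame units on a pixel-sized grid, for
# driving the particle-image generator
px_uniform_field <- function(dx, dy = 0, cells = c(16L, 16L), cell_px = 16) {
  make_field(field_spec("uniform", v1 = dx, v2 = dy,
                        grid_shape = cells, cell_pitch = cell_px))
}

# steady sequence: the same field at two times, optionally with a linearly
# moving body track
steady_sequence <- function(field, t1 = 1, body_xy0 = NULL, body_v = c(0, 0)) {
  f2 <- velocity_field(field$v1, field$v2, field$cell_pitch,
                       mask = field$mask, time = t1)
  bt <- NULL
  if (!is.null(body_xy0)) {
    bt <- data.frame(time = c(0, t1),
                     x = body_xy0[1] + c(0, t1) * body_v[1],
                     y = body_xy0[2] + c(0, t1) * body_v[2],
                     ct_x = 2e-4, ct_y = 0)
  }
  velocity_field_sequence(list(field, f2), body_track = bt)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
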