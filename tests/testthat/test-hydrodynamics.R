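test_that("vorticity is exact on uniform, shear, and solid-rotation fields", {
  u <- make_field(field_spec("uniform", v1 = 2e-3, v2 = 1e-3,
                             grid_shape = c(12L, 10L)))
  expect_true(all(abs(vorticity(u)$omega) < 1e-12, na.rm = TRUE))

  # linear shear v1 = k * y has omega = -k, exactly, even at edges
  k <- 30
  nx <- 12L; ny <- 10L; h <- 25e-6
  Y <- matrix((seq_len(ny) - 0.5) * h, nx, ny, byrow = TRUE)
  sh <- velocity_field(k * Y, matrix(0, nx, ny), h)
  expect_equal(vorticity(sh)$omega, matrix(-k, nx, ny), tolerance = 1e-9,
               ignore_attr = TRUE)

  f <- make_field(field_spec("solid_rotation", omega0 = 7))
  om <- vorticity(f)$omega
  expect_equal(om[40, 32], 14, tolerance = 1e-9)
})

test_that("one-sided stencils next to masked cells keep shear vorticity exact", {
  k <- 30
  nx <- 12L; ny <- 10L; h <- 25e-6
  Y <- matrix((seq_len(ny) - 0.5) * h, nx, ny, byrow = TRUE)
  mask <- matrix(FALSE, nx, ny); mask[5:6, 4:6] <- TRUE
  sh <- velocity_field(k * Y, matrix(0, nx, ny), h, mask = mask)
  om <- vorticity(sh)$omega
  expect_true(all(is.na(om[mask])))
  expect_equal(om[!mask], rep(-k, sum(!mask)), tolerance = 1e-9)
})

test_that("vortex regions recover circulation, signs, additivity, and mirroring", {
  f <- make_field(field_spec("solid_rotation", omega0 = 10,
                             patch_radius = 3e-4))
  truth <- attr(f, "truth")$circulation * 1e6   # mm^2/s
  regs <- find_vortices(vorticity(f), 0.1)
  expect_equal(length(regs), 1L)
  expect_rel_equal(regs[[1]]$circulation, truth, 0.05)
  expect_equal(regs[[1]]$sign, 1)

  vp <- make_field(field_spec("vortex_pair"))
  rp <- find_vortices(vorticity(vp), 0.1)
  expect_equal(length(rp), 2L)
  expect_setequal(vapply(rp, `[[`, 0, "sign"), c(1, -1))
  # disjoint-region additivity: total circulation is the sum of the parts
  om <- vorticity(vp)
  h2 <- vp$cell_pitch^2 * 1e6
  for (r in rp) {
    expect_equal(r$circulation, sum(om$omega[r$cells]) * h2,
                 tolerance = 1e-12)
  }
  # mirroring the field in x negates every circulation
  mir <- velocity_field(-vp$v1[nrow(vp$v1):1, ], vp$v2[nrow(vp$v2):1, ],
                        vp$cell_pitch)
  rm_ <- find_vortices(vorticity(mir), 0.1)
  expect_equal(sort(vapply(rm_, `[[`, 0, "circulation")),
               sort(-vapply(rp, `[[`, 0, "circulation")),
               tolerance = 1e-6)
  expect_length(find_vortices(vorticity(
    make_field(field_spec("uniform", v1 = 0, v2 = 0))), 0.1), 0)
})

test_that("vortex side assignment splits a pair across the body axis", {
  vp <- make_field(field_spec("vortex_pair"))
  ctr <- c(40, 32) * vp$cell_pitch
  regs <- find_vortices(vorticity(vp), 0.1,
                        body_centroid = ctr, body_ct = c(0, 1e-4))
  sides <- vapply(regs, `[[`, "", "side")
  expect_setequal(sides, c("left", "right"))
})

test_that("area of influence counts thresholded cells and shrinks with the cutoff", {
  u <- make_field(field_spec("uniform", v1 = 1e-3, v2 = 0))
  full <- 80 * 64 * (25e-6)^2 * 1e6
  expect_equal(area_of_influence(u, 5e-4), full)
  expect_equal(area_of_influence(velocity_field(
    matrix(1e-4, 8, 8), matrix(0, 8, 8), 25e-6), 5e-4), 0)
  pd <- make_field(field_spec("power_decay", n = -2))
  areas <- vapply(c(2e-4, 5e-4, 1e-3), function(thr)
    area_of_influence(pd, thr), 0)
  expect_true(all(diff(areas) < 0))
})

test_that("attenuation fit recovers the decay power across n and pitch", {
  for (n in c(-1, -1.5, -2, -3)) {
    fit <- attenuation_fit(make_field(field_spec("power_decay", n = n)))
    expect_lt(abs(fit$power - n), 0.05)
    expect_gt(fit$r_squared, 0.95)
    expect_true(all(diff(fit$radii) < 0))  # radii shrink as U* grows
  }
  fine <- make_field(field_spec("power_decay", n = -2,
                                grid_shape = c(160L, 128L),
                                cell_pitch = 12.5e-6))
  expect_lt(abs(attenuation_fit(fine)$power + 2), 0.05)
  expect_error(
    attenuation_fit(make_field(field_spec("uniform", v1 = 1e-3, v2 = 0))),
    "insufficient|no decay")
})

test_that("line flux is exact for uniform and linear-shear flows and linear in the field", {
  L <- 1e-3
  ln <- flux_line(c(5e-4, 1e-3), c(5e-4 + L, 1e-3), normal = c(0, -1))
  u <- make_field(field_spec("uniform", v1 = 0, v2 = -2e-3))
  expect_equal(flux_through_line(u, ln), 2e-3 * L, tolerance = 1e-14)
  ortho <- make_field(field_spec("uniform", v1 = 3e-3, v2 = 0))
  expect_equal(flux_through_line(ortho, ln), 0, tolerance = 1e-16)

  # shear v2 = k * x: trapezoid quadrature is exact, flux = -k * mean(x) * L
  nx <- 80L; ny <- 64L; h <- 25e-6
  X <- matrix((seq_len(nx) - 0.5) * h, nx, ny)
  k <- 2
  shear <- velocity_field(matrix(0, nx, ny), k * X, h)
  expected <- -k * (5e-4 + L / 2) * L
  expect_equal(flux_through_line(shear, ln), expected, tolerance = 1e-12)

  set.seed(9)
  A <- velocity_field(matrix(rnorm(80 * 64), 80), matrix(rnorm(80 * 64), 80),
                      h)
  B <- velocity_field(matrix(rnorm(80 * 64), 80), matrix(rnorm(80 * 64), 80),
                      h)
  comb <- velocity_field(2.5 * A$v1 - 0.7 * B$v1, 2.5 * A$v2 - 0.7 * B$v2, h)
  expect_equal(flux_through_line(comb, ln),
               2.5 * flux_through_line(A, ln) - 0.7 * flux_through_line(B, ln),
               tolerance = 1e-12)
  masked <- velocity_field(matrix(NA_real_, 8, 8), matrix(NA_real_, 8, 8),
                           25e-6)
  expect_error(flux_through_line(masked, flux_line(c(1e-5, 1e-4),
                                                   c(1.9e-4, 1e-4))),
               "degenerate line")
})

test_that("relative flux vanishes for comoving fluid and matches the frame-change identity", {
  vb <- c(1.5e-3, -0.5e-3)
  ln <- flux_line(c(5e-4, 8e-4), c(1.5e-3, 8e-4), normal = c(0, -1))
  co <- make_field(field_spec("comoving", body_velocity = vb))
  seq_co <- steady_sequence(co, body_xy0 = c(1e-3, 1e-3), body_v = vb)
  fs <- relative_flux(seq_co, ln, anchor = "fixed")
  expect_true(all(abs(fs$relative) < 1e-9))

  # still fluid, moving body: relative flux = -(v_body . n) * L
  still <- make_field(field_spec("uniform", v1 = 0, v2 = 0))
  seq_still <- steady_sequence(still, body_xy0 = c(1e-3, 1e-3), body_v = vb)
  fs2 <- relative_flux(seq_still, ln, anchor = "fixed")
  expect_equal(fs2$relative,
               rep(-sum(vb * c(0, -1)) * 1e-3 * 1e6, 2), tolerance = 1e-9)
  expect_equal(fs2$absolute, c(0, 0))
  # zero body velocity: relative equals absolute (line placed clear of the
  # masked source cell)
  pd <- make_field(field_spec("power_decay", n = -2))
  seq_pd <- steady_sequence(pd, body_xy0 = c(1e-3, 8e-4), body_v = c(0, 0))
  ln_off <- flux_line(c(5e-4, 5e-4), c(1.5e-3, 5e-4), normal = c(0, -1))
  fs3 <- relative_flux(seq_pd, ln_off, anchor = "body")
  expect_equal(fs3$relative, fs3$absolute, tolerance = 1e-12)
  # the definitional identity holds on every frame
  vbn <- sum(vb * c(0, -1))
  expect_equal(fs2$relative, fs2$absolute - vbn * 1e-3 * 1e6,
               tolerance = 1e-12)
})

test_that("particle tracing advects exactly in uniform flow and conserves orbit radius", {
  U <- c(2e-4, -1e-4)
  uni <- make_field(field_spec("uniform", v1 = U[1], v2 = U[2]))
  sq <- steady_sequence(uni, t1 = 2)
  tr <- trace_particles(sq, c(5e-4, 1.2e-3), 0, 2, dt = 0.05)
  expect_identical(tr[[1]]$status, "completed")
  endp <- tr[[1]]$path[nrow(tr[[1]]$path), c("x", "y")]
  expect_equal(unname(endp), c(5e-4, 1.2e-3) + U * 2, tolerance = 1e-9)

  rot <- make_field(field_spec("solid_rotation", omega0 = 10,
                               patch_radius = 4e-4))
  ctr <- c(40, 32) * rot$cell_pitch
  T_rev <- 2 * pi / 10
  sq2 <- steady_sequence(rot, t1 = T_rev)
  r0 <- 1.5e-4
  tr2 <- trace_particles(sq2, ctr + c(r0, 0), 0, T_rev, dt = T_rev / 400)
  expect_identical(tr2[[1]]$status, "completed")
  rads <- sqrt((tr2[[1]]$path[, "x"] - ctr[1])^2 +
                 (tr2[[1]]$path[, "y"] - ctr[2])^2)
  expect_lt(max(abs(rads - r0)) / r0, 0.001)

  # a seed inside the body mask is rejected up front
  msk <- make_field(field_spec("uniform", v1 = 1e-3, v2 = 0,
                               mask_center = c(1e-3, 8e-4),
                               mask_radii = c(2e-4, 1e-4)))
  sq3 <- steady_sequence(msk)
  tr3 <- trace_particles(sq3, c(1e-3, 8e-4), 0, 1)
  expect_identical(tr3[[1]]$status, "rejected")
  # a particle carried off the grid is flagged
  tr4 <- trace_particles(sq, c(1.9e-3, 1.5e-3), 0, 10, dt = 0.1)
  expect_identical(tr4[[1]]$status, "left_grid")
})
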