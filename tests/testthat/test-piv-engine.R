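make_ellipse_frame <- function(W = 256, H = 192, xc = 130, yc = 90,
                               a = 40, b = 24, seed = 3) {
  X <- matrix(seq_len(W), W, H)
  Y <- matrix(seq_len(H), W, H, byrow = TRUE)
  truth <- ((X - xc) / a)^2 + ((Y - yc) / b)^2 <= 1
  speck <- make_particle_images(px_uniform_field(0, 0), density = 0.02,
                                n_frames = 1, image_size = c(W, H),
                                rng_seed = seed)[[1]]
  set.seed(seed + 1)
  frame <- 0.9 * truth + 0.5 * speck + matrix(rnorm(W * H, sd = 0.02), W, H)
  list(frame = frame, truth = truth)
}

test_that("larva masking recovers a bright body against particle speckle", {
  fx <- make_ellipse_frame()
  m <- mask_larva(fx$frame)
  expect_false(attr(m, "empty"))
  iou <- sum(m & fx$truth) / sum(m | fx$truth)
  expect_gte(iou, 0.8)
})

test_that("blank frames yield a flagged empty mask, and mask area shrinks with threshold", {
  m0 <- mask_larva(matrix(0, 64, 64))
  expect_true(attr(m0, "empty"))
  expect_false(any(m0))
  fx <- make_ellipse_frame()
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8), function(lev)
    sum(mask_larva(fx$frame, threshold_level = lev)), 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("identical frames give zero displacement everywhere", {
  imgs <- make_particle_images(px_uniform_field(0, 0), density = 0.02,
                               n_frames = 2, image_size = c(128, 128),
                               rng_seed = 2)
  vf <- piv_multipass(imgs[[1]], imgs[[2]],
                      piv_settings(initial_window = 64, final_window = 32))
  expect_true(all(abs(vf$v1) < 1e-6, na.rm = TRUE))
  expect_true(all(abs(vf$v2) < 1e-6, na.rm = TRUE))
})

test_that("uniform shifts across the working range are recovered to 0.1 px RMS", {
  for (shift in c(0.5, 3.0, 8.0)) {
    imgs <- make_particle_images(px_uniform_field(shift, 0.3 * shift),
                                 density = 0.02, n_frames = 2,
                                 image_size = c(256, 256), rng_seed = 7)
    vf <- piv_multipass(imgs[[1]], imgs[[2]])
    err <- sqrt(mean((vf$v1[!vf$mask] - shift)^2 +
                       (vf$v2[!vf$mask] - 0.3 * shift)^2))
    expect_lt(err, 0.1)
  }
})

test_that("rotational flow yields a uniform curl sign and a null centre vector", {
  rotfield <- make_field(field_spec("solid_rotation", omega0 = 0.02,
                                    patch_radius = 1e6,
                                    center = c(128, 128),
                                    grid_shape = c(16L, 16L),
                                    cell_pitch = 16))
  imgs <- make_particle_images(rotfield, density = 0.02, n_frames = 2,
                               image_size = c(256, 256), rng_seed = 11)
  vf <- piv_multipass(imgs[[1]], imgs[[2]])
  om <- vorticity(vf)$omega
  interior <- om[3:14, 3:14]
  expect_gt(mean(interior > 0), 0.95)
  # velocity interpolated at the rotation axis itself should vanish
  cu <- naupflow:::bilinear_sample(vf$v1, vf$cell_pitch, 128, 128)
  cv <- naupflow:::bilinear_sample(vf$v2, vf$cell_pitch, 128, 128)
  expect_lt(sqrt(cu^2 + cv^2), 0.15)
})

test_that("an implanted spurious vector is rejected and refilled near its neighbours", {
  set.seed(5)
  u <- matrix(1, 9, 9) + 0.05 * matrix(rnorm(81), 9, 9)
  v <- matrix(0.5, 9, 9) + 0.05 * matrix(rnorm(81), 9, 9)
  u0 <- u; v0 <- v
  u[5, 5] <- 10 * u[5, 5]
  out <- piv_remove_outliers(u, v)
  expect_true(out$rejected[5, 5])
  nbr_mean <- mean(u0[4:6, 4:6][-5])
  expect_lt(abs(out$u[5, 5] - nbr_mean) / nbr_mean, 0.2)
  expect_false(any(out$rejected[-41]))
})

test_that("masked windows are nulled in the exported grid", {
  imgs <- make_particle_images(px_uniform_field(2, 0), density = 0.02,
                               n_frames = 2, image_size = c(128, 128),
                               rng_seed = 4)
  mask <- matrix(FALSE, 128, 128)
  mask[1:40, 1:40] <- TRUE
  vf <- piv_multipass(imgs[[1]], imgs[[2]],
                      piv_settings(initial_window = 64, final_window = 32),
                      mask = mask)
  expect_true(all(vf$mask[1:2, 1:2]))
  expect_true(all(is.na(vf$v1[vf$mask])))
  expect_true(all(abs(vf$v1[!vf$mask] - 2) < 0.15))
})

test_that("common-grid interpolation is exact on uniform and linear fields", {
  u <- make_field(field_spec("uniform", v1 = 3e-3, v2 = -1e-3,
                             grid_shape = c(10L, 8L), cell_pitch = 5e-5))
  fine <- interpolate_to_common_grid(u, 2.5e-5)
  expect_equal(dim(fine$v1), c(20L, 16L))
  expect_true(all(abs(fine$v1 - 3e-3) < 1e-15))

  nx <- 10L; ny <- 8L; h <- 5e-5
  Y <- matrix((seq_len(ny) - 0.5) * h, nx, ny, byrow = TRUE)
  k <- 20
  shear <- velocity_field(k * Y, matrix(0, nx, ny), h)
  fine2 <- interpolate_to_common_grid(shear, 2.5e-5)
  Yf <- matrix((seq_len(16L) - 0.5) * 2.5e-5, 20L, 16L, byrow = TRUE)
  expect_equal(fine2$v1, k * Yf, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("refine-then-coarsen deviations stay within the field's curvature scale", {
  nx <- 20L; ny <- 16L; h <- 5e-5
  X <- matrix((seq_len(nx) - 0.5) * h, nx, ny)
  Y <- matrix((seq_len(ny) - 0.5) * h, nx, ny, byrow = TRUE)
  v1 <- sin(X / (4 * h)) * cos(Y / (5 * h)) * 1e-3
  f <- velocity_field(v1, matrix(0, nx, ny), h)
  back <- interpolate_to_common_grid(
    interpolate_to_common_grid(f, h / 2), h)
  curv <- max(abs(diff(diff(v1))), abs(t(diff(diff(t(v1))))))
  expect_lt(max(abs(back$v1 - f$v1)), curv)
})

test_that("the conservative mask dilates onto every touched target cell", {
  u <- make_field(field_spec("uniform", v1 = 1e-3, v2 = 0,
                             grid_shape = c(10L, 8L), cell_pitch = 5e-5,
                             mask_center = c(2.5e-4, 2e-4),
                             mask_radii = c(6e-5, 6e-5)))
  fine <- interpolate_to_common_grid(u, 2.5e-5)
  # every target cell whose bilinear stencil touches a masked source cell
  # must be masked: compare against the source mask dilated by one cell
  src_masked <- which(u$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(src_masked))) {
    i2 <- 2 * src_masked[r, 1]; j2 <- 2 * src_masked[r, 2]
    expect_true(fine$mask[i2 - 1, j2 - 1] && fine$mask[i2, j2])
  }
})
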