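#' Generate synthetic PIV particle image sequences
#'
#' Renders Gaussian-spot tracer particles and advects them exactly with the
#' supplied velocity field between frames, giving the PIV engine inputs
#' with a known displacement field. Particle displacement per frame at
#' position x is `v(x) * dt / m_per_px` pixels, with `v` sampled
#' bilinearly from the field; with the defaults (`dt = 1`, `m_per_px = 1`)
#' the field's `v1`/`v2` are read directly as pixel displacements per
#' frame, which is the convenient convention for engine validation.
#'
#' @param flow a [velocity_field()].
#' @param density mean particle count per square pixel; seeding aims at
#'   more than 15 particles per interrogation window, so e.g. 0.02 px^-2
#'   gives about 20 per 32 x 32 window.
#' @param diameter_px particle image diameter in pixels (Gaussian spots of
#'   s.d. `diameter_px / 4`).
#' @param n_frames number of frames to render.
#' @param image_size `c(width, height)` in pixels; defaults to the field's
#'   physical extent divided by `m_per_px`.
#' @param dt time between frames, seconds.
#' @param m_per_px physical size of one image pixel, metres.
#' @param noise_sd s.d. of additive Gaussian pixel noise (default 0).
#' @param check_window_px reference window size used to warn when seeding
#'   is too sparse (fewer than one particle expected per window).
#' @param rng_seed integer seed; particle placement is deterministic given
#'   the seed.
#' @return list of `n_frames` grayscale matrices `[width, height]` in
#'   `[0, 1]`, with the particle trajectories attached as
#'   `attr(x, "tracks")`.
#' @export
make_particle_images <- function(flow, density = 0.02, diameter_px = 3,
                                 n_frames = 2L, image_size = NULL,
                                 dt = 1, m_per_px = 1, noise_sd = 0,
                                 check_window_px = 32L, rng_seed = 1L) {
  stopifnot(inherits(flow, "velocity_field"))
  set.seed(rng_seed)
  if (is.null(image_size)) {
    image_size <- round(c(nrow(flow$v1), ncol(flow$v1)) * flow$cell_pitch /
                          m_per_px)
  }
  W <- image_size[1]; H <- image_size[2]
  if (density * check_window_px^2 < 1)
    warnf("seeding density %.2g px^-2 yields < 1 particle per %d px window",
          density, check_window_px)
  margin <- 16
  n_p <- round(density * (W + 2 * margin) * (H + 2 * margin))
  px <- stats::runif(n_p, -margin, W + margin)
  py <- stats::runif(n_p, -margin, H + margin)
  sigma <- diameter_px / 4
  half <- max(2L, ceiling(3 * sigma))
  render <- function(px, py) {
    img <- matrix(0, W, H)
    for (p in seq_along(px)) {
      x0 <- px[p]; y0 <- py[p]
      xlo <- max(1L, floor(x0) - half); xhi <- min(W, floor(x0) + half + 1L)
      ylo <- max(1L, floor(y0) - half); yhi <- min(H, floor(y0) + half + 1L)
      if (xlo > xhi || ylo > yhi) next
      xi <- xlo:xhi; yi <- ylo:yhi
      gx <- exp(-((xi - 0.5) - x0)^2 / (2 * sigma^2))
      gy <- exp(-((yi - 0.5) - y0)^2 / (2 * sigma^2))
      img[xi, yi] <- img[xi, yi] + outer(gx, gy)
    }
    img
  }
  frames <- vector("list", n_frames)
  tracks <- array(NA_real_, c(n_frames, n_p, 2))
  for (f in seq_len(n_frames)) {
    tracks[f, , 1] <- px; tracks[f, , 2] <- py
    img <- render(px, py)
    if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
    frames[[f]] <- clamp(img, 0, 1)
    if (f < n_frames) {
      vx <- bilinear_sample(flow$v1, flow$cell_pitch,
                            px * m_per_px, py * m_per_px)
      vy <- bilinear_sample(flow$v2, flow$cell_pitch,
                            px * m_per_px, py * m_per_px)
      vx[is.na(vx)] <- 0; vy[is.na(vy)] <- 0
      px <- px + vx * dt / m_per_px
      py <- py + vy * dt / m_per_px
    }
  }
  attr(frames, "tracks") <- tracks
  frames
}
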