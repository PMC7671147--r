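#' Lagrangian particle tracing through a field sequence
#'
#' Advects seed points through the time-resolved velocity field with
#' classical 4th-order Runge-Kutta integration, interpolating the field
#' bilinearly in space and linearly in time between frames (held constant
#' beyond the first/last frame). A path terminates early — and is flagged —
#' when the particle enters the body mask or leaves the grid, the same
#' bookkeeping used when real tracked tracer particles are lost. Seeds
#' starting inside the mask are rejected.
#'
#' @param seq a [velocity_field_sequence()].
#' @param seeds numeric matrix `[n, 2]` of seed positions, metres.
#' @param t0,t1 trace interval, seconds (`t0 < t1`).
#' @param dt integration step, seconds; default 1/10 of the smallest frame
#'   interval (or `(t1 - t0) / 100` for single-frame sequences).
#' @return list of traces, one per seed: each a list with `path` (matrix
#'   with columns `time`, `x`, `y`) and `status` (`"completed"`,
#'   `"left_grid"`, `"entered_mask"` or `"rejected"`).
#' @export
trace_particles <- function(seq, seeds, t0, t1, dt = NULL) {
  stopifnot(inherits(seq, "velocity_field_sequence"))
  if (t0 >= t1) stopf("need t0 < t1")
  seeds <- matrix(seeds, ncol = 2)
  f1 <- seq$fields[[1]]
  h <- f1$cell_pitch
  nx <- nrow(f1$v1); ny <- ncol(f1$v1)
  if (is.null(dt)) {
    dt <- if (length(seq$times) > 1) min(diff(seq$times)) / 10
    else (t1 - t0) / 100
  }
  in_mask <- function(x, y) {
    i <- clamp(ceiling(x / h), 1, nx)
    j <- clamp(ceiling(y / h), 1, ny)
    f1$mask[cbind(i, j)]   # geometry is shared; mask taken from frame 1
  }
  vel_at <- function(t, x, y) {
    tt <- clamp(t, seq$times[1], seq$times[length(seq$times)])
    k <- findInterval(tt, seq$times, all.inside = TRUE)
    fa <- seq$fields[[k]]
    if (k < length(seq$fields)) {
      fb <- seq$fields[[k + 1]]
      w <- (tt - seq$times[k]) / (seq$times[k + 1] - seq$times[k])
    } else {
      fb <- fa; w <- 0
    }
    va1 <- bilinear_sample(fa$v1, h, x, y); va2 <- bilinear_sample(fa$v2, h, x, y)
    vb1 <- bilinear_sample(fb$v1, h, x, y); vb2 <- bilinear_sample(fb$v2, h, x, y)
    c((1 - w) * va1 + w * vb1, (1 - w) * va2 + w * vb2)
  }
  lapply(seq_len(nrow(seeds)), function(s) {
    x <- seeds[s, 1]; y <- seeds[s, 2]
    if (x < 0 || x > nx * h || y < 0 || y > ny * h)
      return(list(path = NULL, status = "rejected"))
    if (in_mask(x, y))
      return(list(path = NULL, status = "rejected"))
    ts <- seq(t0, t1, by = dt)
    if (ts[length(ts)] < t1) ts <- c(ts, t1)
    path <- matrix(NA_real_, length(ts), 3,
                   dimnames = list(NULL, c("time", "x", "y")))
    path[1, ] <- c(t0, x, y)
    status <- "completed"
    for (k in seq_len(length(ts) - 1)) {
      step <- ts[k + 1] - ts[k]
      k1 <- vel_at(ts[k], x, y)
      k2 <- vel_at(ts[k] + step / 2, x + step / 2 * k1[1], y + step / 2 * k1[2])
      k3 <- vel_at(ts[k] + step / 2, x + step / 2 * k2[1], y + step / 2 * k2[2])
      k4 <- vel_at(ts[k] + step, x + step * k3[1], y + step * k3[2])
      if (anyNA(c(k1, k2, k3, k4))) {
        # NA arises from leaving the grid or touching NA (masked) cells
        status <- if (in_mask(x, y)) "entered_mask" else "left_grid"
        break
      }
      x <- x + step / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      y <- y + step / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      if (x < 0 || x > nx * h || y < 0 || y > ny * h) {
        status <- "left_grid"; break
      }
      if (in_mask(x, y)) { status <- "entered_mask"; break }
      path[k + 1, ] <- c(ts[k + 1], x, y)
    }
    list(path = path[!is.na(path[, 1]), , drop = FALSE], status = status)
  })
}
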