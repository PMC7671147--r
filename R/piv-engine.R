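#' PIV engine settings
#'
#' Parameters of the multi-pass cross-correlation engine and of the larva
#' masking pipeline. Interrogation windows halve from `initial_window` to
#' `final_window` over the passes (64 to 32 px suits small larvae at high
#' seeding density; 96 to 64 px larger ones), with 50% overlap by default.
#' Outlier vectors are removed with the normalized median test
#' (threshold 2.0, epsilon 0.1 px — the universal defaults). The final
#' vectors are exported on a grid of `export_cell_px`-pixel cells.
#'
#' The masking pipeline applies, in order, the named background-removal
#' filters (`"smoothing"` = Gaussian blur of s.d. `mask_smooth_sigma`;
#' `"sliding_min_subtract"` / `"sliding_max_subtract"` = subtraction of a
#' running minimum/maximum over a window of half-width
#' `mask_background_half_width`), then thresholds at
#' `mask_threshold_level` times the filtered maximum and keeps the largest
#' connected component.
#'
#' @param initial_window,final_window interrogation window sizes, px; both
#'   even, `final_window <= initial_window`.
#' @param overlap_fraction window overlap in `[0, 1)`.
#' @param outlier_threshold normalized-median-test rejection threshold.
#' @param outlier_eps normalization floor, px.
#' @param peak_ratio_floor minimum first-to-second correlation peak ratio
#'   for a vector to be accepted.
#' @param export_cell_px export grid cell size, px.
#' @param mask_pipeline ordered character vector of filter names.
#' @param mask_smooth_sigma,mask_background_half_width,mask_threshold_level
#'   masking parameters, see above.
#' @return an object of class `piv_settings`.
#' @export
piv_settings <- function(initial_window = 64L, final_window = 32L,
                         overlap_fraction = 0.5,
                         outlier_threshold = 2.0, outlier_eps = 0.1,
                         peak_ratio_floor = 1.1,
                         export_cell_px = 16L,
                         mask_pipeline = c("smoothing",
                                           "sliding_min_subtract"),
                         mask_smooth_sigma = 4,
                         mask_background_half_width = 31L,
                         mask_threshold_level = 0.4) {
  if (final_window > initial_window)
    stopf("final_window must not exceed initial_window")
  if (initial_window %% 2 || final_window %% 2)
    stopf("window sizes must be even")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stopf("overlap_fraction must lie in [0, 1)")
  ok <- c("smoothing", "sliding_min_subtract", "sliding_max_subtract")
  if (length(bad <- setdiff(mask_pipeline, ok)))
    stopf("unknown mask filter(s): %s", paste(bad, collapse = ", "))
  structure(list(initial_window = as.integer(initial_window),
                 final_window = as.integer(final_window),
                 overlap_fraction = overlap_fraction,
                 outlier_threshold = outlier_threshold,
                 outlier_eps = outlier_eps,
                 peak_ratio_floor = peak_ratio_floor,
                 export_cell_px = as.integer(export_cell_px),
                 mask_pipeline = mask_pipeline,
                 mask_smooth_sigma = mask_smooth_sigma,
                 mask_background_half_width =
                   as.integer(mask_background_half_width),
                 mask_threshold_level = mask_threshold_level),
            class = "piv_settings")
}

#' Segment the larva body in a raw frame
#'
#' Runs the configured background-removal filters, thresholds relative to
#' the filtered image maximum, and keeps the largest connected component —
#' the bright larva body against the particle speckle. An image with
#' nothing above threshold yields an all-`FALSE` mask flagged with
#' `attr(x, "empty") = TRUE` rather than an error, so batch processing can
#' skip empty frames.
#'
#' @param frame grayscale matrix `[width, height]`, any nonnegative range.
#' @param settings a [piv_settings()].
#' @param threshold_level optional override of the relative threshold.
#' @return logical matrix, `TRUE` inside the larva, with attribute
#'   `empty`.
#' @export
mask_larva <- function(frame, settings = piv_settings(),
                       threshold_level = NULL) {
  x <- frame
  k <- settings$mask_background_half_width
  for (step in settings$mask_pipeline) {
    x <- switch(step,
      smoothing = as.matrix(EBImage::gblur(x, sigma = settings$mask_smooth_sigma)),
      sliding_min_subtract = x - sliding_extremum(x, k, "min"),
      sliding_max_subtract = x - sliding_extremum(x, k, "max"))
  }
  level <- (threshold_level %||% settings$mask_threshold_level) *
    max(x, 0)
  sel <- x >= level & x > 0
  if (!any(sel)) {
    out <- matrix(FALSE, nrow(frame), ncol(frame))
    attr(out, "empty") <- TRUE
    return(out)
  }
  labels <- EBImage::bwlabel(sel * 1)
  counts <- tabulate(labels[labels > 0])
  out <- labels == which.max(counts)
  attr(out, "empty") <- FALSE
  out
}

# --- correlation internals ---------------------------------------------------

# circular cross-correlation plane of two equal windows, zero-lag centred
corr_plane <- function(a, b) {
  A <- fft(a - mean(a))
  B <- fft(b - mean(b))
  fftshift2(Re(fft(Conj(A) * B, inverse = TRUE))) / length(a)
}

# 3-point Gaussian sub-pixel interpolation along one axis
subpixel_gauss <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && (2 * log(cm) - 4 * log(c0) + 2 * log(cp)) < 0)
    (log(cm) - log(cp)) / (2 * log(cm) - 4 * log(c0) + 2 * log(cp))
  else if ((cm - 2 * c0 + cp) < 0)   # parabolic fallback
    (cm - cp) / (2 * (cm - 2 * c0 + cp))
  else 0
}

# locate the correlation peak within +/- search cells of the centre;
# returns c(dx, dy, peak_ratio) or NULL when no usable peak exists
find_peak <- function(cp, search) {
  n <- nrow(cp)
  c0 <- n / 2 + 1
  lo <- c0 - search; hi <- c0 + search
  sub <- cp[lo:hi, lo:hi]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  i <- pk[1] + lo - 1; j <- pk[2] + lo - 1
  if (i <= 1 || i >= n || j <= 1 || j >= n) return(NULL)
  peak <- cp[i, j]
  if (!is.finite(peak) || peak <= 0) return(NULL)
  # second peak outside the 3x3 neighbourhood of the first
  sub2 <- sub
  bi <- pk[1] + (-1:1); bj <- pk[2] + (-1:1)
  bi <- bi[bi >= 1 & bi <= nrow(sub2)]; bj <- bj[bj >= 1 & bj <= ncol(sub2)]
  sub2[bi, bj] <- -Inf
  second <- max(sub2)
  ratio <- if (is.finite(second) && second > 0) peak / second else Inf
  dx <- (i - c0) + subpixel_gauss(cp[i - 1, j], peak, cp[i + 1, j])
  dy <- (j - c0) + subpixel_gauss(cp[i, j - 1], peak, cp[i, j + 1])
  c(dx, dy, ratio)
}

#' Normalized median test with local-mean replacement
#'
#' Flags displacement vectors whose deviation from the median of their 3x3
#' neighbourhood, normalized by the median neighbourhood fluctuation plus
#' `eps`, exceeds `threshold`; flagged and missing vectors are replaced by
#' the mean of their valid neighbours (iterated until none remain).
#'
#' @param u,v displacement component matrices (px); `NA` marks vectors
#'   already invalid.
#' @param threshold,eps test parameters (defaults 2.0 and 0.1 px).
#' @return list with replaced `u`, `v` and logical `rejected`.
#' @export
piv_remove_outliers <- function(u, v, threshold = 2.0, eps = 0.1) {
  nx <- nrow(u); ny <- ncol(u)
  rejected <- matrix(FALSE, nx, ny)
  resid <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (is.na(u[i, j])) next
    ni <- max(1, i - 1):min(nx, i + 1)
    nj <- max(1, j - 1):min(ny, j + 1)
    nu <- u[ni, nj]; nv <- v[ni, nj]
    keep <- !is.na(nu)
    keep[which(ni == i) + (which(nj == j) - 1) * length(ni)] <- FALSE
    if (sum(keep) < 3) next
    mu <- median(nu[keep]); mv <- median(nv[keep])
    fluct <- sqrt((nu[keep] - mu)^2 + (nv[keep] - mv)^2)
    r <- sqrt((u[i, j] - mu)^2 + (v[i, j] - mv)^2) / (median(fluct) + eps)
    resid[i, j] <- r
    if (r > threshold) rejected[i, j] <- TRUE
  }
  u[rejected] <- NA_real_
  v[rejected] <- NA_real_
  # fill rejected/invalid vectors from valid neighbours, iterating so that
  # holes larger than one cell are filled from the outside in
  for (pass in 1:10) {
    holes <- which(is.na(u), arr.ind = TRUE)
    if (!nrow(holes)) break
    newu <- u; newv <- v
    for (r in seq_len(nrow(holes))) {
      i <- holes[r, 1]; j <- holes[r, 2]
      ni <- max(1, i - 1):min(nx, i + 1)
      nj <- max(1, j - 1):min(ny, j + 1)
      nb <- u[ni, nj]
      if (any(!is.na(nb))) {
        newu[i, j] <- mean(u[ni, nj], na.rm = TRUE)
        newv[i, j] <- mean(v[ni, nj], na.rm = TRUE)
      }
    }
    if (identical(newu, u)) break
    u <- newu; v <- newv
  }
  list(u = u, v = v, rejected = rejected)
}

#' Multi-pass cross-correlation PIV
#'
#' Estimates the displacement field between two frames by windowed
#' cross-correlation with a shrinking interrogation window: each pass
#' offsets the second frame's windows by the previous pass's (integer)
#' prediction, computes the FFT cross-correlation plane, and refines the
#' peak with a 3-point Gaussian sub-pixel fit. After the final pass,
#' outliers are removed with the normalized median test and filled by
#' local-mean interpolation, and the vectors are resampled to the export
#' grid. Windows dominated by the body mask, with negligible signal, or
#' with an ambiguous correlation peak are marked invalid and interpolated.
#'
#' @param frame_a,frame_b grayscale matrices of identical size.
#' @param settings a [piv_settings()].
#' @param mask optional logical body mask (pixels `TRUE` are excluded).
#' @param frame_interval time between the frames, s.
#' @param m_per_px physical pixel size, m. With the defaults (both 1) the
#'   returned "velocities" are pixel displacements per frame.
#' @return a [velocity_field()] on the export grid; the final-pass raw
#'   vector grid is attached as `attr(x, "pass_grid")`.
#' @export
piv_multipass <- function(frame_a, frame_b, settings = piv_settings(),
                          mask = NULL, frame_interval = 1, m_per_px = 1) {
  stopifnot(all(dim(frame_a) == dim(frame_b)))
  W <- nrow(frame_a); H <- ncol(frame_a)
  if (is.null(mask)) mask <- matrix(FALSE, W, H)
  sizes <- settings$initial_window
  while (tail(sizes, 1) / 2 >= settings$final_window)
    sizes <- c(sizes, tail(sizes, 1) / 2)
  sizes[length(sizes)] <- settings$final_window
  pred <- NULL   # list(cx, cy, u, v) from the previous pass
  for (win in sizes) {
    step <- max(1L, as.integer(round(win * (1 - settings$overlap_fraction))))
    xs <- seq(1L, W - win + 1L, by = step)
    ys <- seq(1L, H - win + 1L, by = step)
    cx <- xs + win / 2 - 0.5
    cy <- ys + win / 2 - 0.5
    u <- matrix(NA_real_, length(xs), length(ys))
    v <- matrix(NA_real_, length(xs), length(ys))
    search <- win / 4
    for (ii in seq_along(xs)) for (jj in seq_along(ys)) {
      xi <- xs[ii]:(xs[ii] + win - 1L)
      yi <- ys[jj]:(ys[jj] + win - 1L)
      if (mean(mask[xi, yi]) > 0.5) next
      off <- c(0L, 0L)
      if (!is.null(pred)) {
        pu <- interp_grid(pred$u, pred$cx, pred$cy, cx[ii], cy[jj])
        pv <- interp_grid(pred$v, pred$cx, pred$cy, cx[ii], cy[jj])
        if (is.finite(pu) && is.finite(pv)) off <- as.integer(round(c(pu, pv)))
      }
      xb <- clamp(xi + off[1], 1L, W)
      yb <- clamp(yi + off[2], 1L, H)
      a <- frame_a[xi, yi]; b <- frame_b[xb, yb]
      if (sd(a) < 1e-10 || sd(b) < 1e-10) next
      pk <- find_peak(corr_plane(a, b), search)
      if (is.null(pk)) next
      if (is.finite(pk[3]) && pk[3] < settings$peak_ratio_floor) next
      u[ii, jj] <- off[1] + pk[1]
      v[ii, jj] <- off[2] + pk[2]
    }
    pred <- list(cx = cx, cy = cy, u = u, v = v)
  }
  cleaned <- piv_remove_outliers(pred$u, pred$v,
                                 threshold = settings$outlier_threshold,
                                 eps = settings$outlier_eps)
  # resample to the export grid
  ex <- settings$export_cell_px
  nex <- floor(W / ex); ney <- floor(H / ex)
  ex_cx <- (seq_len(nex) - 0.5) * ex
  ex_cy <- (seq_len(ney) - 0.5) * ex
  uo <- matrix(NA_real_, nex, ney)
  vo <- matrix(NA_real_, nex, ney)
  mo <- matrix(FALSE, nex, ney)
  for (i in seq_len(nex)) for (j in seq_len(ney)) {
    px <- ((i - 1) * ex + 1):(i * ex)
    py <- ((j - 1) * ex + 1):(j * ex)
    if (mean(mask[px, py]) > 0.5) { mo[i, j] <- TRUE; next }
    uo[i, j] <- interp_grid(cleaned$u, pred$cx, pred$cy, ex_cx[i], ex_cy[j])
    vo[i, j] <- interp_grid(cleaned$v, pred$cx, pred$cy, ex_cx[i], ex_cy[j])
  }
  out <- velocity_field(uo * m_per_px / frame_interval,
                        vo * m_per_px / frame_interval,
                        cell_pitch = ex * m_per_px, mask = mo)
  attr(out, "pass_grid") <- c(pred[c("cx", "cy")], cleaned[c("u", "v")],
                              list(rejected = cleaned$rejected))
  out
}

# bilinear interpolation on a grid with arbitrary (uniform) centre
# coordinates, linearly extrapolating beyond the outermost centres
interp_grid <- function(z, cx, cy, x, y) {
  nx <- length(cx); ny <- length(cy)
  if (nx == 1 && ny == 1) return(z[1, 1])
  sx <- if (nx > 1) cx[2] - cx[1] else 1
  sy <- if (ny > 1) cy[2] - cy[1] else 1
  gi <- if (nx > 1) clamp(floor((x - cx[1]) / sx) + 1, 1, nx - 1) else 1
  gj <- if (ny > 1) clamp(floor((y - cy[1]) / sy) + 1, 1, ny - 1) else 1
  tx <- if (nx > 1) (x - cx[gi]) / sx else 0
  ty <- if (ny > 1) (y - cy[gj]) / sy else 0
  i1 <- min(gi + 1, nx); j1 <- min(gj + 1, ny)
  (1 - tx) * (1 - ty) * z[gi, gj] + tx * (1 - ty) * z[i1, gj] +
    (1 - tx) * ty * z[gi, j1] + tx * ty * z[i1, j1]
}

#' Interpolate a velocity field onto a common grid
#'
#' Bilinear interpolation of both velocity components onto a grid of the
#' requested cell pitch covering the same physical extent — used to bring
#' coarser fields (larger interrogation windows) to a common vector
#' density before comparison. Refining (the usual direction) and
#' coarsening are both supported. The mask is dilated conservatively: a
#' target cell is masked when any source cell contributing to its
#' interpolation is masked.
#'
#' @param field a [velocity_field()].
#' @param target_cell_pitch desired pitch, m.
#' @return a [velocity_field()] at the target pitch.
#' @export
interpolate_to_common_grid <- function(field, target_cell_pitch) {
  stopifnot(inherits(field, "velocity_field"))
  if (target_cell_pitch <= 0) stopf("target pitch must be > 0")
  nx <- nrow(field$v1); ny <- ncol(field$v1)
  h <- field$cell_pitch
  nex <- max(2L, round(nx * h / target_cell_pitch))
  ney <- max(2L, round(ny * h / target_cell_pitch))
  xs <- (seq_len(nex) - 0.5) * target_cell_pitch
  ys <- (seq_len(ney) - 0.5) * target_cell_pitch
  pts <- expand.grid(x = xs, y = ys)
  # fill masked source cells with 0 for interpolation; the conservative
  # mask below hides every affected target cell anyway
  z1 <- field$v1; z2 <- field$v2
  z1[field$mask] <- 0; z2[field$mask] <- 0
  v1 <- matrix(bilinear_sample(z1, h, pts$x, pts$y), nex, ney)
  v2 <- matrix(bilinear_sample(z2, h, pts$x, pts$y), nex, ney)
  src_mask_num <- field$mask * 1
  near_mask <- matrix(bilinear_sample(src_mask_num, h, pts$x, pts$y) > 0,
                      nex, ney)
  velocity_field(v1, v2, cell_pitch = target_cell_pitch,
                 mask = near_mask, time = field$time)
}
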