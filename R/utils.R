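# shared numerical helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Bilinear sample of a cell-centred scalar grid at physical points.
# Grid value z[i, j] sits at ((i - 0.5) * pitch, (j - 0.5) * pitch).
# Points beyond the outermost cell centres are linearly extrapolated from the
# edge cell pair, so fields that are linear in x and y are reproduced exactly
# everywhere inside the grid extent. Returns NA outside the grid extent.
bilinear_sample <- function(z, pitch, x, y) {
  nx <- nrow(z); ny <- ncol(z)
  gx <- x / pitch + 0.5
  gy <- y / pitch + 0.5
  out <- rep(NA_real_, length(x))
  inside <- !is.na(x) & !is.na(y) &
    x >= 0 & x <= nx * pitch & y >= 0 & y <= ny * pitch
  if (!any(inside)) return(out)
  i0 <- clamp(floor(gx[inside]), 1, nx - 1)
  j0 <- clamp(floor(gy[inside]), 1, ny - 1)
  tx <- gx[inside] - i0
  ty <- gy[inside] - j0
  idx <- function(i, j) cbind(i, j)
  v00 <- z[idx(i0, j0)]
  v10 <- z[idx(i0 + 1, j0)]
  v01 <- z[idx(i0, j0 + 1)]
  v11 <- z[idx(i0 + 1, j0 + 1)]
  out[inside] <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  out
}

# 2-D fftshift: move zero-lag of a circular correlation plane to the centre
fftshift2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  sx <- floor(nx / 2); sy <- floor(ny / 2)
  m[c((sx + 1):nx, 1:sx), c((sy + 1):ny, 1:sy)]
}

# grayscale sliding maximum / minimum over a (2k+1)-square window, computed
# separably by folding shifted copies; edges are handled by replication
sliding_extremum <- function(m, half_width, which = c("max", "min")) {
  which <- match.arg(which)
  fun <- if (which == "max") pmax else pmin
  shift_rows <- function(x, s) {
    n <- nrow(x)
    if (s == 0) return(x)
    if (s > 0) x[clamp(seq_len(n) - s, 1, n), , drop = FALSE]
    else x[clamp(seq_len(n) - s, 1, n), , drop = FALSE]
  }
  shift_cols <- function(x, s) {
    n <- ncol(x)
    if (s == 0) return(x)
    x[, clamp(seq_len(n) - s, 1, n), drop = FALSE]
  }
  out <- m
  for (s in seq_len(half_width)) {
    out <- fun(out, shift_rows(m, s), shift_rows(m, -s))
  }
  m2 <- out
  for (s in seq_len(half_width)) {
    out <- fun(out, shift_cols(m2, s), shift_cols(m2, -s))
  }
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
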