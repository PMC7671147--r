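#' Read a tpsDIG landmark file
#'
#' Parses the TPS landmark dialect produced by tpsDIG: one specimen record
#' per digitized video frame, each starting with an `LM=k` line (the key is
#' accepted case-insensitively) followed by `k` lines of `x y` coordinates
#' and optional `IMAGE=`, `ID=` and `SCALE=` trailers (trailers are carried
#' along but not interpreted).
#'
#' tpsDIG stores coordinates with a bottom-left origin. Image-processing
#' conventions (and this package's velocity grids) use a top-left origin, so
#' by default the y axis is flipped on read via `y -> image_height - y`;
#' pass `flip_y = FALSE` for data already in image convention.
#'
#' The digitizing order of landmarks is not encoded in the file, so
#' `landmark_map` — the landmark ids in file order — is a required argument,
#' not a default.
#'
#' @param path path to the TPS file.
#' @param frame_rate video frame rate, frames s^-1.
#' @param pixel_scale micrometres per pixel.
#' @param landmark_map character vector of landmark ids in the order they
#'   were digitized, e.g. `c("Fh_left", "Fh_right", "Dts", "ant1", "ant2",
#'   "mand")`; must include the three body landmarks.
#' @param view_plane `"xy"` or `"yz"`.
#' @param flip_y flip the y axis to top-left image convention (default TRUE;
#'   requires `image_height`).
#' @param image_height image height in pixels, needed when `flip_y = TRUE`.
#' @return a [landmark_series()].
#' @export
read_tps <- function(path, frame_rate, pixel_scale, landmark_map,
                     view_plane = c("xy", "yz"),
                     flip_y = TRUE, image_height = NULL) {
  view_plane <- match.arg(view_plane)
  if (!file.exists(path)) stopf("TPS file not found: %s", path)
  if (flip_y && is.null(image_height))
    stopf("image_height is required when flip_y = TRUE")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lm_at <- grep("^[Ll][Mm]=", lines)
  if (!length(lm_at)) stopf("no LM= records found in %s", path)
  counts <- as.integer(sub("^[Ll][Mm]=", "", lines[lm_at]))
  if (any(is.na(counts))) stopf("unparseable LM= count in %s", path)
  if (any(counts != counts[1]))
    stopf("inconsistent landmark counts: record %d has LM=%d, expected %d",
          which(counts != counts[1])[1], counts[counts != counts[1]][1],
          counts[1])
  k <- counts[1]
  if (k < 3) stopf("insufficient landmarks: LM=%d, need at least 3", k)
  if (length(landmark_map) != k)
    stopf("landmark_map names %d landmarks but records have LM=%d",
          length(landmark_map), k)
  n <- length(lm_at)
  coords <- array(NA_real_, c(n, k, 2),
                  dimnames = list(NULL, landmark_map, c("x", "y")))
  for (r in seq_len(n)) {
    block <- lines[(lm_at[r] + 1):(lm_at[r] + k)]
    xy <- suppressWarnings(
      matrix(as.numeric(unlist(strsplit(block, "[ \t]+"))), ncol = 2,
             byrow = TRUE))
    if (nrow(xy) != k || anyNA(xy))
      stopf("record %d: expected %d coordinate lines of 'x y'", r, k)
    if (flip_y) xy[, 2] <- image_height - xy[, 2]
    coords[r, , ] <- xy
  }
  landmark_series(coords, frame_rate = frame_rate, pixel_scale = pixel_scale,
                  view_plane = view_plane)
}

#' Write a landmark series as a TPS file
#'
#' One specimen record per frame, in the stored landmark order, with an
#' `ID=` trailer carrying the frame index. Coordinates are written with six
#' decimals, so `read_tps(write_tps(x))` round-trips to that precision.
#' No axis flip is applied on write; pair with `read_tps(..., flip_y =
#' FALSE)` to round-trip.
#'
#' @param lm a [landmark_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(lm, path) {
  k <- dim(lm$coords)[2]
  out <- character(0)
  for (r in seq_len(n_frames(lm))) {
    out <- c(out, sprintf("LM=%d", k),
             sprintf("%.6f %.6f", lm$coords[r, , 1], lm$coords[r, , 2]),
             sprintf("ID=%d", r - 1L))
  }
  writeLines(out, path)
  invisible(path)
}
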