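#' Read a velocity-field sequence from a directory
#'
#' The on-disk dialect is deliberately plain so that exports from any PIV
#' package can be converted to it: one whitespace-delimited text file per
#' frame named `frame_<index>.tsv` with header columns `x_index`, `y_index`,
#' `v1`, `v2`, `mask_flag` (velocities in m s^-1, `mask_flag` 1 = inside the
#' body), plus a JSON sidecar `fields.json` holding the shared geometry:
#' `n_x`, `n_y`, `cell_pitch` (m), `view_plane`, optionally `frame_rate`,
#' `pixel_scale` and explicit `times`. Cells absent from a frame file are
#' treated as masked. An optional `body_track.tsv` (columns `time x y ct_x
#' ct_y`, SI units) supplies the body track.
#'
#' Frames are ordered by the numeric index in the filename, so a shuffled
#' directory listing cannot reorder the sequence.
#'
#' @param dir directory containing the sidecar and frame files.
#' @return a [velocity_field_sequence()].
#' @export
read_field_sequence <- function(dir) {
  sidecar <- file.path(dir, "fields.json")
  if (!file.exists(sidecar))
    stopf("sidecar fields.json not found in %s", dir)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("n_x", "n_y", "cell_pitch"))
    if (is.null(meta[[key]])) stopf("sidecar missing required key '%s'", key)
  nx <- as.integer(meta$n_x); ny <- as.integer(meta$n_y)
  files <- list.files(dir, pattern = "^frame_[0-9]+\\.tsv$", full.names = TRUE)
  if (!length(files)) stopf("no frame_<index>.tsv files in %s", dir)
  idx <- as.integer(sub("^frame_([0-9]+)\\.tsv$", "\\1", basename(files)))
  files <- files[order(idx)]
  idx <- sort(idx)
  times <- if (!is.null(meta$times)) as.numeric(meta$times)
  else (seq_along(files) - 1) / (meta$frame_rate %||% 1)
  if (length(times) != length(files))
    stopf("sidecar lists %d times but %d frame files found",
          length(times), length(files))
  fields <- vector("list", length(files))
  for (f in seq_along(files)) {
    tab <- utils::read.table(files[f], header = TRUE)
    need <- c("x_index", "y_index", "v1", "v2", "mask_flag")
    if (!all(need %in% names(tab)))
      stopf("frame %d (%s): missing column(s) %s", idx[f], basename(files[f]),
            paste(setdiff(need, names(tab)), collapse = ", "))
    if (any(tab$x_index < 1 | tab$x_index > nx |
            tab$y_index < 1 | tab$y_index > ny))
      stopf("frame %d: cell indices outside the %d x %d sidecar grid",
            idx[f], nx, ny)
    v1 <- matrix(NA_real_, nx, ny); v2 <- matrix(NA_real_, nx, ny)
    mask <- matrix(TRUE, nx, ny)   # absent cells stay masked
    at <- cbind(tab$x_index, tab$y_index)
    v1[at] <- tab$v1; v2[at] <- tab$v2
    mask[at] <- tab$mask_flag != 0
    fields[[f]] <- velocity_field(v1, v2, cell_pitch = meta$cell_pitch,
                                  mask = mask, time = times[f])
  }
  bt_path <- file.path(dir, "body_track.tsv")
  body_track <- if (file.exists(bt_path))
    utils::read.table(bt_path, header = TRUE) else NULL
  velocity_field_sequence(fields, body_track = body_track)
}

#' Write a velocity-field sequence to a directory
#'
#' Inverse of [read_field_sequence()]: emits `fields.json`, one
#' `frame_<index>.tsv` per frame (all cells listed, masked cells with
#' `mask_flag = 1` and zero velocity), and `body_track.tsv` when a body
#' track is present.
#'
#' @param seq a [velocity_field_sequence()].
#' @param dir output directory (created if needed).
#' @param view_plane recorded in the sidecar; `"xy"` or `"yz"`.
#' @return `dir`, invisibly.
#' @export
write_field_sequence <- function(seq, dir, view_plane = "xy") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- seq$fields[[1]]
  meta <- list(n_x = nrow(f1$v1), n_y = ncol(f1$v1),
               cell_pitch = f1$cell_pitch, view_plane = view_plane,
               times = seq$times)
  jsonlite::write_json(meta, file.path(dir, "fields.json"),
                       auto_unbox = TRUE, digits = NA)
  for (f in seq_along(seq$fields)) {
    fl <- seq$fields[[f]]
    grid <- expand.grid(x_index = seq_len(nrow(fl$v1)),
                        y_index = seq_len(ncol(fl$v1)))
    at <- cbind(grid$x_index, grid$y_index)
    tab <- data.frame(grid,
                      v1 = ifelse(fl$mask[at], 0, fl$v1[at]),
                      v2 = ifelse(fl$mask[at], 0, fl$v2[at]),
                      mask_flag = as.integer(fl$mask[at]))
    utils::write.table(tab, file.path(dir, sprintf("frame_%04d.tsv", f)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(seq$body_track))
    utils::write.table(seq$body_track, file.path(dir, "body_track.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
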