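#' Write keypoint tracks as a DeepLabCut-style CSV
#'
#' Three header rows (scorer / bodyparts / coords) with `x`, `y`,
#' `likelihood` columns per keypoint and the frame index as first column.
#' Bodyparts are named `<mouse>_nose` and `<mouse>_tailbase`.  Coordinates
#' are written in the units of the bout (cm); apply `px_per_cm` to emit
#' pixel units.
#'
#' @param bout A [tube_bout()].
#' @param path Output file.
#' @param scorer Scorer name for the first header row.
#' @param px_per_cm Pixels per cm (default 1: write cm).
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(bout, path, scorer = "synthetic", px_per_cm = 1) {
  stopifnot(inherits(bout, "tube_bout"))
  parts <- as.vector(vapply(bout$mice, function(m)
    paste0(m, c("_nose", "_tailbase")), character(2)))
  header1 <- c("scorer", rep(scorer, 3L * length(parts)))
  header2 <- c("bodyparts", rep(parts, each = 3L))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  cols <- list(0:(bout$n_frames - 1L))
  for (m in bout$mice) {
    tr <- bout_track(bout, m)
    cols <- c(cols, list(tr$nose_x * px_per_cm, tr$nose_y * px_per_cm,
                         tr$conf_nose, tr$tail_x * px_per_cm,
                         tr$tail_y * px_per_cm, tr$conf_tail))
  }
  body <- do.call(cbind, lapply(cols, function(x) format(x, trim = TRUE)))
  lines <- c(paste(header1, collapse = ","),
             paste(header2, collapse = ","),
             paste(header3, collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a DeepLabCut-style CSV into a tube bout
#'
#' Parses the three-row header (scorer / bodyparts / coords), converts
#' pixels to cm, and assembles a [tube_bout()] from the `<mouse>_nose` /
#' `<mouse>_tailbase` keypoints.
#'
#' @param path CSV file written by DeepLabCut or [write_dlc_csv()].
#' @param fps Frames per second of the video.
#' @param px_per_cm Pixel-to-cm calibration (default 1).
#' @param x0,x1,facing,cage_id,day,bout_id Passed to [tube_bout()].
#' @return A [tube_bout()].
#' @export
read_dlc_csv <- function(path, fps, px_per_cm = 1, x0 = 0, x1 = 30,
                         facing = NULL, cage_id = NA_character_,
                         day = NA_integer_, bout_id = NA_character_) {
  hdr <- readLines(path, n = 3L)
  bodyparts <- strsplit(hdr[2L], ",")[[1L]][-1L]
  coords <- strsplit(hdr[3L], ",")[[1L]][-1L]
  raw <- utils::read.csv(path, skip = 3L, header = FALSE)
  if (ncol(raw) != length(bodyparts) + 1L) {
    abort("column count does not match the bodyparts header")
  }
  part_names <- unique(bodyparts)
  mice <- unique(sub("_(nose|tailbase)$", "", part_names))
  if (length(mice) != 2L) abort("expected keypoints for exactly two mice")
  col_of <- function(part, coord) {
    1L + which(bodyparts == part & coords == coord)
  }
  tracks <- purrr::map_dfr(mice, function(m) {
    tibble::tibble(
      mouse = m,
      frame = as.integer(raw[[1L]]),
      nose_x = raw[[col_of(paste0(m, "_nose"), "x")]] / px_per_cm,
      nose_y = raw[[col_of(paste0(m, "_nose"), "y")]] / px_per_cm,
      tail_x = raw[[col_of(paste0(m, "_tailbase"), "x")]] / px_per_cm,
      tail_y = raw[[col_of(paste0(m, "_tailbase"), "y")]] / px_per_cm,
      conf_nose = raw[[col_of(paste0(m, "_nose"), "likelihood")]],
      conf_tail = raw[[col_of(paste0(m, "_tailbase"), "likelihood")]]
    )
  })
  tube_bout(tracks, fps = fps, x0 = x0, x1 = x1, facing = facing,
            cage_id = cage_id, day = day, bout_id = bout_id)
}

#' Write an ethogram as a BED-like interval CSV
#'
#' One row per event: `bout_id`, `start_frame`, `end_frame` (half-open),
#' `label`, `actor`, `start_s`, `duration_s`.
#'
#' @param ethogram A `cm_ethogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(ethogram, path) {
  df <- tibble::as_tibble(ethogram)
  df$bout_id <- attr(ethogram, "bout_id") %||% NA_character_
  readr::write_csv(df[, c("bout_id", "start_frame", "end_frame", "label",
                          "actor", "start_s", "duration_s")], path)
  invisible(path)
}

#' Read photometry from a CSV file
#'
#' Expects columns `time_s`, `signal` and optionally `control`.
#'
#' @param path CSV file.
#' @param mouse_id,session_id Optional metadata.
#' @return A [photometry_recording()].
#' @export
read_photometry_csv <- function(path, mouse_id = NA_character_,
                                session_id = NA_character_) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  photometry_recording(df$time_s, df$signal, df[["control"]],
                       mouse_id = mouse_id, session_id = session_id)
}

#' Write photometry to a CSV file
#'
#' @param rec A [photometry_recording()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_photometry_csv <- function(rec, path) {
  readr::write_csv(tibble::as_tibble(rec), path)
  invisible(path)
}
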