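#' Construct a tube-test bout
#'
#' Bundles the keypoint tracks of the two competing mice with the geometry of
#' the tube.  All coordinates are in centimetres in a calibrated tube frame:
#' `x` runs along the tube axis, `y` across it.  Each mouse has a `facing`
#' sign giving the direction of its own forward motion along `x` (`+1` if the
#' partner lies toward larger `x`, `-1` otherwise); velocities reported by
#' [compute_velocity()] are signed so that positive always means "toward the
#' partner".
#'
#' @param tracks A data frame with one row per mouse and frame and columns
#'   `mouse` (two distinct ids), `frame` (0-based), `nose_x`, `nose_y`,
#'   `tail_x`, `tail_y` (cm) and `conf_nose`, `conf_tail` in `[0, 1]`.
#' @param fps Frames per second (> 0).
#' @param x0,x1 Tube span along the axis, cm, with `x0 < x1`.
#' @param facing Named numeric vector (`+1`/`-1` per mouse id).
#' @param cage_id,day,bout_id Optional bout metadata.
#' @return An object of class `tube_bout`.
#' @export
tube_bout <- function(tracks, fps, x0 = 0, x1 = 30,
                      facing = NULL, cage_id = NA_character_,
                      day = NA_integer_, bout_id = NA_character_) {
  tracks <- tibble::as_tibble(tracks)
  need <- c("mouse", "frame", "nose_x", "nose_y", "tail_x", "tail_y",
            "conf_nose", "conf_tail")
  missing_cols <- setdiff(need, names(tracks))
  if (length(missing_cols)) {
    abort(paste0("tracks is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ids <- unique(tracks$mouse)
  if (length(ids) != 2L) abort("a tube bout needs exactly two mice")
  counts <- table(tracks$mouse)
  if (length(unique(counts)) != 1L) {
    abort("both tracks must have the same number of frames")
  }
  if (!fps > 0) abort("fps must be > 0")
  if (!x0 < x1) abort("tube span requires x0 < x1")
  if (is.null(facing)) facing <- setNames(c(1, -1), ids)
  if (!all(ids %in% names(facing)) || !all(facing[ids] %in% c(-1, 1))) {
    abort("facing must give +1 or -1 for each mouse id")
  }
  n_frames <- as.integer(counts[[1L]])
  structure(
    list(
      tracks = dplyr::arrange(tracks, .data$mouse, .data$frame),
      fps = fps, x0 = x0, x1 = x1,
      facing = facing[ids],
      mice = ids,
      n_frames = n_frames,
      duration_s = n_frames / fps,
      cage_id = cage_id, day = day, bout_id = bout_id
    ),
    class = "tube_bout"
  )
}

#' @export
print.tube_bout <- function(x, ...) {
  cat(sprintf("<tube_bout> %s vs %s: %d frames @ %g fps (%.1f s), tube [%g, %g] cm\n",
              x$mice[1], x$mice[2], x$n_frames, x$fps, x$duration_s,
              x$x0, x$x1))
  invisible(x)
}

# Per-mouse track as a frame-ordered tibble.
bout_track <- function(bout, mouse) {
  dplyr::filter(bout$tracks, .data$mouse == !!mouse)
}
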