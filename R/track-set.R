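#' Construct a track set
#'
#' A track set is the container for single-particle trajectories: a tibble
#' with one row per localization (`track_id`, `frame`, `x_um`, `y_um`) plus a
#' shared frame interval in seconds carried as an attribute. All diffusion
#' analyses operate on this object.
#'
#' @param data A data frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval Time between consecutive frames, in seconds (> 0).
#'
#' @return A `track_set` tibble.
#' @export
#' @examples
#' ts <- track_set(
#'   data.frame(track_id = 1, frame = 0:3, x_um = c(0, .1, .2, .3), y_um = 0),
#'   frame_interval = 0.03
#' )
#' frame_interval(ts)
track_set <- function(data, frame_interval = 0.03) {
  require_columns(data, c("track_id", "frame", "x_um", "y_um"), "track data")
  stop_if_not_scalar_number(frame_interval, "frame_interval", 0,
                            strict_lower = TRUE)
  out <- as_tibble(data) |>
    mutate(frame = as.integer(.data$frame)) |>
    arrange(.data$track_id, .data$frame)
  dup <- out |> dplyr::count(.data$track_id, .data$frame) |> filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate (track_id, frame) rows (e.g. track %s, frame %d)",
                  as.character(dup$track_id[1L]), dup$frame[1L]))
  }
  if (!all(is.finite(out$x_um)) || !all(is.finite(out$y_um))) {
    abort("positions must be finite")
  }
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("track_set", class(out))
  out
}

#' Frame interval of a track set
#' @param ts A `track_set`.
#' @return The frame interval in seconds.
#' @export
frame_interval <- function(ts) {
  dt <- attr(ts, "frame_interval")
  if (is.null(dt)) abort("not a track_set: no frame_interval attribute")
  dt
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d localizations, dt = %g s\n",
              dplyr::n_distinct(x$track_id), nrow(x), frame_interval(x)))
  NextMethod()
}

# Per-track consecutive-frame displacements (frame gap exactly 1).
# Returns a tibble: track_id, dx, dy.
track_steps <- function(ts) {
  as_tibble(ts) |>
    group_by(.data$track_id) |>
    mutate(
      dx = .data$x_um - dplyr::lag(.data$x_um),
      dy = .data$y_um - dplyr::lag(.data$y_um),
      gap = .data$frame - dplyr::lag(.data$frame)
    ) |>
    ungroup() |>
    filter(!is.na(.data$gap), .data$gap == 1L) |>
    select("track_id", "dx", "dy")
}
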