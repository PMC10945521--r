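#' Filter tracks by minimum step count
#'
#' Keeps only trajectories with at least `min_steps` consecutive-frame
#' displacements (frame gap exactly 1); the conventional single-particle
#' tracking filter, defaulting to the five-step threshold used for slimfield
#' data. Idempotent; track order is preserved.
#'
#' @param ts A [track_set].
#' @param min_steps Minimum number of valid steps (default 5).
#' @return A filtered `track_set` (possibly empty).
#' @export
filter_tracks <- function(ts, min_steps = 5L) {
  min_steps <- stop_if_not_count(min_steps, "min_steps")
  counts <- track_steps(ts) |> dplyr::count(.data$track_id)
  keep <- counts$track_id[counts$n >= min_steps]
  out <- as_tibble(ts) |> filter(.data$track_id %in% keep)
  track_set(out, frame_interval = frame_interval(ts))
}

#' Pool frame-to-frame displacements
#'
#' Extracts every consecutive-frame displacement and appends the x and the y
#' component as separate scalar samples, the input to the two-population
#' mixture fit. Steps spanning a frame gap are excluded (no gap closing):
#' the mixture variance 2*D*dt assumes unit frame separation.
#'
#' @param ts A [track_set].
#' @return A `displacement_sample` tibble with column `displacement_um`,
#'   carrying `frame_interval` and `n_tracks_contributing` attributes.
#'   Sample count = 2 x total steps.
#' @export
pooled_displacements <- function(ts) {
  steps <- track_steps(ts)
  if (nrow(steps) == 0L) abort("no valid consecutive-frame steps in input")
  out <- tibble(displacement_um = c(steps$dx, steps$dy))
  attr(out, "frame_interval") <- frame_interval(ts)
  attr(out, "n_tracks_contributing") <- dplyr::n_distinct(steps$track_id)
  class(out) <- c("displacement_sample", class(out))
  out
}

#' Mean-squared-displacement curve
#'
#' Time-averaged MSD per track at each lag (using position pairs separated by
#' exactly `k` frames), then ensemble-averaged across tracks. The spread
#' column is the across-track standard deviation, matching the error bars of
#' conventional MSD plots.
#'
#' @param ts A [track_set].
#' @param max_lag Largest lag in frames. Defaults to
#'   `min(10, floor(longest track / 4))`.
#' @return A tibble: `lag_s`, `msd_um2`, `sd_um2`, `n` (tracks per lag).
#' @export
msd_curve <- function(ts, max_lag = NULL) {
  df <- as_tibble(ts)
  if (nrow(df) == 0L) abort("empty track set")
  dt <- frame_interval(ts)
  tracks <- split(df[c("frame", "x_um", "y_um")], df$track_id)
  longest <- max(vapply(tracks, nrow, 1L)) - 1L
  if (is.null(max_lag)) max_lag <- max(1L, min(10L, longest %/% 4L))
  max_lag <- stop_if_not_count(max_lag, "max_lag")
  if (max_lag > longest) {
    abort(sprintf("max_lag = %d exceeds the longest track (%d steps)",
                  max_lag, longest))
  }

  per_track <- map(tracks, function(tr) {
    vapply(seq_len(max_lag), function(k) {
      i <- match(tr$frame + k, tr$frame)       # pairs separated by k frames
      ok <- !is.na(i)
      if (!any(ok)) return(NA_real_)
      mean((tr$x_um[i[ok]] - tr$x_um[ok])^2 +
           (tr$y_um[i[ok]] - tr$y_um[ok])^2)
    }, numeric(1))
  })
  m <- do.call(rbind, per_track)               # tracks x lags
  tibble(
    lag_s = seq_len(max_lag) * dt,
    msd_um2 = apply(m, 2L, mean, na.rm = TRUE),
    sd_um2 = apply(m, 2L, sd, na.rm = TRUE),
    n = apply(m, 2L, function(v) sum(!is.na(v)))
  )
}

#' Localization heat map
#'
#' 2D histogram of all recorded particle positions, the "sum of
#' single-particle positions" image used to visualize assembly sites.
#'
#' @param ts A [track_set].
#' @param bin_size Bin edge length in um.
#' @return A `loc_heatmap`: an integer count matrix (rows = y bins, columns =
#'   x bins) with `origin` (xmin, ymin) and `bin_size` attributes. Total
#'   count equals the number of localizations.
#' @export
localization_heatmap <- function(ts, bin_size = 0.05) {
  stop_if_not_scalar_number(bin_size, "bin_size", 0, strict_lower = TRUE)
  df <- as_tibble(ts)
  if (nrow(df) == 0L) abort("empty track set")
  ix <- floor((df$x_um - min(df$x_um)) / bin_size)
  iy <- floor((df$y_um - min(df$y_um)) / bin_size)
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  counts <- matrix(0L, nrow = ny, ncol = nx)
  tab <- table(factor(iy, levels = 0:(ny - 1L)),
               factor(ix, levels = 0:(nx - 1L)))
  counts[] <- as.integer(tab)
  structure(counts,
            origin = c(min(df$x_um), min(df$y_um)),
            bin_size = bin_size,
            class = c("loc_heatmap", "matrix", "array"))
}

#' @export
print.loc_heatmap <- function(x, ...) {
  cat(sprintf("<loc_heatmap> %d x %d bins of %g um, %d localizations\n",
              nrow(x), ncol(x), attr(x, "bin_size"), sum(x)))
  invisible(x)
}

#' @rdname localization_heatmap
#' @param object,... A `loc_heatmap`, further arguments (ignored).
#' @method autoplot loc_heatmap
#' @export
autoplot.loc_heatmap <- function(object, ...) {
  bs <- attr(object, "bin_size"); orig <- attr(object, "origin")
  df <- expand.grid(y = seq_len(nrow(object)), x = seq_len(ncol(object)))
  df$count <- as.vector(object)
  df$x_um <- orig[1L] + (df$x - 0.5) * bs
  df$y_um <- orig[2L] + (df$y - 0.5) * bs
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "counts")
}
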