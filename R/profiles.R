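#' Fluorescence profiles along the outer and inner curve
#'
#' Resamples each edge path to `n_points` equally spaced in arc length and
#' reads, at every sample, the mean intensity of image pixels within
#' `band_width_px` of the sample point, restricted to the cell mask. This
#' yields the outer- and inner-curve fluorescence profiles that, after
#' concatenation, form curved-cell demographs.
#'
#' @param image Intensity matrix.
#' @param edges A `cell_edges` from [split_edges()].
#' @param mask Binary cell mask (same shape as `image`).
#' @param n_points Samples per edge (>= 10; default 50).
#' @param band_width_px Sampling band radius in px (default 3).
#'
#' @return An `edge_profiles` tibble: `side` ("outer"/"inner"), `position`
#'   (1..n_points, pole A -> pole B), `intensity`; attributes
#'   `outer_arc_length_um`, `inner_arc_length_um`, `n_points`.
#' @export
edge_profiles <- function(image, edges, mask, n_points = 50L,
                          band_width_px = 3) {
  stopifnot(inherits(edges, "cell_edges"))
  n_points <- stop_if_not_count(n_points, "n_points", min = 10L)
  stop_if_not_scalar_number(band_width_px, "band_width_px", 0,
                            strict_lower = TRUE)
  prof <- function(path, side) {
    pts <- resample_polyline(as.matrix(path[, c("row", "col")]), n_points)
    tibble(side = side, position = seq_len(n_points),
           intensity = band_means(image, mask, pts, band_width_px))
  }
  out <- bind_rows(prof(edges$outer, "outer"), prof(edges$inner, "inner"))
  attr(out, "outer_arc_length_um") <- edges$outer_length_um
  attr(out, "inner_arc_length_um") <- edges$inner_length_um
  attr(out, "n_points") <- n_points
  class(out) <- c("edge_profiles", class(out))
  out
}

# Mean intensity within `band` px of each sample point, mask-restricted.
band_means <- function(image, mask, pts, band) {
  if (is.logical(mask)) mask <- mask * 1L
  stopifnot(all(dim(image) == dim(mask)))
  if (any(pts[, 1L] - band < 0.5) || any(pts[, 2L] - band < 0.5) ||
      any(pts[, 1L] + band > nrow(image) + 0.5) ||
      any(pts[, 2L] + band > ncol(image) + 0.5)) {
    abort("sampling band extends beyond the image")
  }
  px <- which(mask == 1L, arr.ind = TRUE)
  vals <- image[px]
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (px[, 1L] - pts[i, 1L])^2 + (px[, 2L] - pts[i, 2L])^2
    sel <- d2 <= band^2
    if (!any(sel)) return(NA_real_)
    mean(vals[sel])
  }, numeric(1))
}

#' Concatenate outer and inner profiles
#'
#' Joins the outer-curve profile and the inner-curve profile of one cell
#' into a single combined profile (outer first), recording the transition
#' index — the boundary drawn as a dashed line on curved-cell demographs.
#'
#' @param ep An `edge_profiles` tibble.
#' @return A tibble `index`, `side`, `intensity` with attribute
#'   `transition_index` (= n_points); length is always `2 * n_points`.
#' @export
concat_profile <- function(ep) {
  stopifnot(inherits(ep, "edge_profiles"))
  n <- attr(ep, "n_points")
  outer <- ep |> filter(.data$side == "outer") |> arrange(.data$position)
  inner <- ep |> filter(.data$side == "inner") |> arrange(.data$position)
  out <- tibble(
    index = seq_len(2L * n),
    side = rep(c("outer", "inner"), each = n),
    intensity = c(outer$intensity, inner$intensity)
  )
  attr(out, "transition_index") <- n
  attr(out, "arc_length_um") <- attr(ep, "outer_arc_length_um") +
    attr(ep, "inner_arc_length_um")
  out
}

#' Intensity profile along the medial axis
#'
#' Band-averaged intensity sampled at `n_points` along the pole-to-pole
#' medial axis; the per-cell profile stacked into straight-cell demographs.
#'
#' @param image Intensity matrix.
#' @param geom A `cell_geometry`.
#' @param mask Binary cell mask.
#' @param n_points Number of samples (default 50).
#' @param band_width_px Band radius in px (default 3).
#' @return A tibble `position`, `intensity` with attribute `arc_length_um`.
#' @export
axis_profile <- function(image, geom, mask, n_points = 50L,
                         band_width_px = 3) {
  stopifnot(inherits(geom, "cell_geometry"))
  n_points <- stop_if_not_count(n_points, "n_points", min = 2L)
  pts <- resample_polyline(as.matrix(geom$axis[, c("row", "col")]), n_points)
  out <- tibble(position = seq_len(n_points),
                intensity = band_means(image, mask, pts, band_width_px))
  attr(out, "arc_length_um") <- geom$length_um
  out
}

#' Inner-curve enrichment ratio
#'
#' Mean inner-curve intensity divided by mean outer-curve intensity;
#' values > 1 indicate enrichment at the inner (concave) side of the cell.
#' Because the inner/outer labels are re-detected from the geometry, the
#' ratio is invariant under mirroring of the cell.
#'
#' @param ep An `edge_profiles` tibble.
#' @return A single positive number.
#' @export
inner_enrichment <- function(ep) {
  stopifnot(inherits(ep, "edge_profiles"))
  m_in <- mean(ep$intensity[ep$side == "inner"], na.rm = TRUE)
  m_out <- mean(ep$intensity[ep$side == "outer"], na.rm = TRUE)
  if (!is.finite(m_out) || abs(m_out) < .Machine$double.eps) {
    abort("outer-curve mean intensity is zero; enrichment undefined")
  }
  m_in / m_out
}

#' Pearson colocalization coefficient
#'
#' Standard Pearson correlation of two fluorescence channels over the mask
#' pixels — the colocalization measure reported for dual-colour imaging.
#'
#' @param channel_a,channel_b Intensity matrices of equal dimensions.
#' @param mask Binary mask selecting the pixels to correlate (>= 2 pixels).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_colocalization <- function(channel_a, channel_b, mask) {
  if (is.logical(mask)) mask <- mask * 1L
  stopifnot(all(dim(channel_a) == dim(channel_b)),
            all(dim(channel_a) == dim(mask)))
  sel <- mask == 1L
  if (sum(sel) < 2L) abort("mask must contain at least 2 pixels")
  a <- channel_a[sel]; b <- channel_b[sel]
  if (sd(a) == 0 || sd(b) == 0) {
    abort("zero variance in a channel over the mask; PCC undefined")
  }
  stats::cor(a, b)
}
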