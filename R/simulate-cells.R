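#' Render a synthetic curved (arc-shaped) cell
#'
#' Draws an arc-shaped cell — a band of width `cell_width` along a circular
#' centerline — as a binary mask plus two fluorescence channels, emulating a
#' crescent/spiral bacterium imaged in two colours. Channel A is uniform over
#' the cell; channel B is brighter on the inner (concave) half of the band by
#' the factor `inner_enrichment`, the pattern produced by proteins enriched
#' at the inner curve. Gaussian read noise can be added to both channels.
#'
#' The arc is centred in the image. Pixel centres are at integer (row, col)
#' coordinates; a pixel belongs to the mask when its centre lies within the
#' band and the arc's angular span.
#'
#' @param centerline_radius Radius of the circular centerline, px.
#' @param arc_angle Angular span of the arc in radians, in (0, 2*pi).
#' @param cell_width Band width, px.
#' @param image_shape `c(rows, cols)` of the rendered images.
#' @param channel_a_level Mean intensity of channel A over the cell.
#' @param inner_enrichment Ratio (>= 1) of inner-half to outer-half mean
#'   intensity in channel B.
#' @param channel_b_level Outer-half mean intensity of channel B.
#' @param noise_sd Gaussian noise SD added to both channels (default 0).
#' @param seed Integer seed.
#'
#' @return A list of class `curved_cell`: `mask` (0/1 matrix), `channel_a`,
#'   `channel_b` (numeric matrices), and `truth` with the true `centerline`,
#'   `inner_edge`, `outer_edge` polylines (n x 2, row/col), their arc
#'   lengths (px), `enrichment`, `radius`, `arc_angle`, `cell_width`.
#' @export
#' @examples
#' cc <- render_curved_cell(centerline_radius = 40, arc_angle = pi, seed = 1)
#' cc$truth$centerline_length       # ~ pi * 40
render_curved_cell <- function(centerline_radius = 40,
                               arc_angle = pi,
                               cell_width = 10,
                               image_shape = NULL,
                               channel_a_level = 100,
                               inner_enrichment = 1,
                               channel_b_level = 100,
                               noise_sd = 0,
                               seed = 1L) {
  stop_if_not_scalar_number(centerline_radius, "centerline_radius", 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(arc_angle, "arc_angle", 0, 2 * pi,
                            strict_lower = TRUE)
  if (arc_angle >= 2 * pi) abort("`arc_angle` must be < 2*pi")
  stop_if_not_scalar_number(cell_width, "cell_width", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(inner_enrichment, "inner_enrichment", 1)
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0)
  if (cell_width / 2 >= centerline_radius) {
    abort("`cell_width`/2 must be smaller than `centerline_radius`")
  }
  set.seed(new_seed(seed))

  # Arc symmetric about angle pi/2 (bulging toward +row): theta in
  # [pi/2 - a/2, pi/2 + a/2] around a centre placed so the arc is centred.
  half <- arc_angle / 2
  theta <- seq(pi / 2 - half, pi / 2 + half, length.out = 2048L)
  r_out <- centerline_radius + cell_width / 2
  r_in <- centerline_radius - cell_width / 2

  # Bounding box of the band (outer edge spans the extremes).
  pr <- c(r_out * sin(theta), r_in * sin(theta))
  pc <- c(r_out * cos(theta), r_in * cos(theta))
  pad <- 4
  need_rows <- diff(range(pr)) + 2 * pad
  need_cols <- diff(range(pc)) + 2 * pad
  if (is.null(image_shape)) {
    image_shape <- c(ceiling(need_rows) + 2, ceiling(need_cols) + 2)
  }
  rows <- image_shape[1L]; cols <- image_shape[2L]
  if (need_rows > rows || need_cols > cols) {
    abort(sprintf(
      "cell (%.0f x %.0f px with margin) does not fit image_shape (%d x %d)",
      need_rows, need_cols, rows, cols))
  }
  centre <- c(
    (rows + 1) / 2 - (min(pr) + max(pr)) / 2,
    (cols + 1) / 2 - (min(pc) + max(pc)) / 2
  )

  rc <- matrix(rep(seq_len(rows), cols), rows, cols)
  cc <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  dr <- rc - centre[1L]; dc <- cc - centre[2L]
  rad <- sqrt(dr^2 + dc^2)
  ang <- atan2(dr, dc)                       # in (-pi, pi], 0 along +col
  in_band <- rad >= r_in & rad <= r_out
  in_arc <- ang >= (pi / 2 - half) & ang <= (pi / 2 + half)
  mask <- (in_band & in_arc) * 1L

  channel_a <- matrix(0, rows, cols)
  channel_a[mask == 1L] <- channel_a_level
  channel_b <- matrix(0, rows, cols)
  inner_half <- mask == 1L & rad < centerline_radius
  outer_half <- mask == 1L & rad >= centerline_radius
  channel_b[outer_half] <- channel_b_level
  channel_b[inner_half] <- channel_b_level * inner_enrichment
  if (noise_sd > 0) {
    channel_a <- channel_a + matrix(rnorm(rows * cols, 0, noise_sd), rows)
    channel_b <- channel_b + matrix(rnorm(rows * cols, 0, noise_sd), rows)
  }

  arc_points <- function(r) cbind(centre[1L] + r * sin(theta),
                                  centre[2L] + r * cos(theta))
  truth <- list(
    centerline = arc_points(centerline_radius),
    inner_edge = arc_points(r_in),
    outer_edge = arc_points(r_out),
    centerline_length = centerline_radius * arc_angle,
    inner_length = r_in * arc_angle,
    outer_length = r_out * arc_angle,
    enrichment = inner_enrichment,
    radius = centerline_radius,
    arc_angle = arc_angle,
    cell_width = cell_width,
    centre = centre
  )
  structure(list(mask = mask, channel_a = channel_a, channel_b = channel_b,
                 truth = truth),
            class = "curved_cell")
}

#' @export
print.curved_cell <- function(x, ...) {
  cat(sprintf(
    "<curved_cell> %d x %d px, R = %g px, arc = %.2f rad, enrichment = %g\n",
    nrow(x$mask), ncol(x$mask), x$truth$radius, x$truth$arc_angle,
    x$truth$enrichment))
  invisible(x)
}
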