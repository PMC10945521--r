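#' Extract cell outline and medial axis from a binary mask
#'
#' Computes the closed boundary polygon of a single-cell mask (contour
#' tracing via EBImage) and its pole-to-pole medial axis: the Zhang-Suen
#' topological skeleton pruned to its single longest path (which removes
#' spurs), lightly smoothed, and extended along its end tangents to the cell
#' poles. The medial axis is the coordinate system for cell length,
#' sinuosity and axial profiles.
#'
#' @param mask Binary matrix (0/1); must contain exactly one connected
#'   component and no holes.
#' @param pixel_size Physical pixel edge length, um/px (default 1: lengths
#'   in px).
#'
#' @return A list of class `cell_geometry`: `outline` (closed polygon
#'   tibble, columns `row`, `col`), `axis` (pole-to-pole polyline tibble),
#'   `length_um` (axis arc length x pixel_size), `pixel_size`.
#' @export
#' @examples
#' m <- matrix(0L, 20, 70); m[6:15, 6:65] <- 1L
#' g <- extract_geometry(m)
#' g$length_um     # ~ 60 px
extract_geometry <- function(mask, pixel_size = 1) {
  stop_if_not_scalar_number(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  mask <- validate_single_component_mask(mask)

  contour <- EBImage::ocontour(mask)[[1L]] + 1L   # 0-based -> (row, col)
  skel <- zhang_suen_thin(mask)
  path <- skeleton_longest_path(skel)
  if (nrow(path) < 2L) abort("mask skeleton is a single point; no axis")
  dm <- as.matrix(EBImage::distmap(mask))
  # drop the skeleton's end branches (they run diagonally into the pole
  # corners for about one half-width) before re-growing the ends along the
  # distance-transform ridge
  path <- trim_polyline_ends(path, 1.5 * max(dm))
  axis <- smooth_polyline(path, window = 7L)
  axis <- extend_to_poles(axis, mask)

  # Degenerate-axis guard: a roughly isotropic blob (e.g. a disk) has an
  # axis no longer than its width; refuse to report one silently.
  width2 <- 2 * max(EBImage::distmap(mask))
  len <- polyline_length(axis)
  if (len < 1.2 * width2) {
    abort(sprintf(
      "degenerate medial axis: length %.1f px vs cell width %.1f px; mask is not elongated",
      len, width2))
  }

  structure(list(
    outline = tibble(row = contour[, 1L], col = contour[, 2L]),
    axis = tibble(row = axis[, 1L], col = axis[, 2L]),
    length_um = len * pixel_size,
    half_width_px = max(dm),
    pixel_size = pixel_size
  ), class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> axis length %.2f um (%d outline vertices)\n",
              x$length_um, nrow(x$outline)))
  invisible(x)
}

validate_single_component_mask <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    abort("`mask` must be a binary (0/1) matrix")
  }
  lab <- EBImage::bwlabel(mask)
  n_comp <- max(lab)
  if (n_comp == 0L) abort("`mask` is empty")
  if (n_comp > 1L) {
    abort(sprintf("`mask` has %d connected components (labels: %s); expected 1",
                  n_comp, paste(seq_len(n_comp), collapse = ", ")))
  }
  filled <- EBImage::fillHull(mask)
  if (sum(filled) != sum(mask)) {
    abort("`mask` contains holes; fill them before extraction")
  }
  mask
}

# Zhang-Suen binary thinning, vectorized over the image via shifted copies.
zhang_suen_thin <- function(mask) {
  img <- mask == 1
  pad <- function(m) {
    out <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
    out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    out
  }
  p <- pad(img)
  nr <- nrow(p); nc <- ncol(p)
  sh <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours P2..P9 clockwise from north (north = row - 1)
      n2 <- sh(p, 1, 0);  n3 <- sh(p, 1, -1); n4 <- sh(p, 0, -1)
      n5 <- sh(p, -1, -1); n6 <- sh(p, -1, 0); n7 <- sh(p, -1, 1)
      n8 <- sh(p, 0, 1);  n9 <- sh(p, 1, 1)
      b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      seqs <- list(n2, n3, n4, n5, n6, n7, n8, n9, n2)
      a <- Reduce(`+`, lapply(1:8, function(i) !seqs[[i]] & seqs[[i + 1L]]))
      if (phase == 1L) {
        cond <- p & b >= 2 & b <= 6 & a == 1 &
          !(n2 & n4 & n6) & !(n4 & n6 & n8)
      } else {
        cond <- p & b >= 2 & b <= 6 & a == 1 &
          !(n2 & n4 & n8) & !(n2 & n6 & n8)
      }
      if (any(cond)) {
        p[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  (p[2:(nr - 1L), 2:(nc - 1L)]) * 1L
}

# Longest geodesic path through the skeleton, as an ordered (row, col)
# matrix. Skeleton pixels become graph nodes (8-connectivity, Euclidean edge
# weights); the path between the two mutually farthest endpoints is taken,
# which also prunes side spurs.
skeleton_longest_path <- function(skel) {
  idx <- which(skel == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("empty skeleton")
  if (nrow(idx) == 1L) return(idx)
  key <- paste(idx[, 1L], idx[, 2L])
  lookup <- setNames(seq_len(nrow(idx)), key)
  edges <- NULL
  weights <- NULL
  offs <- rbind(c(0, 1), c(1, -1), c(1, 0), c(1, 1))  # half-neighbourhood
  for (k in seq_len(nrow(offs))) {
    nb <- cbind(idx[, 1L] + offs[k, 1L], idx[, 2L] + offs[k, 2L])
    j <- lookup[paste(nb[, 1L], nb[, 2L])]
    ok <- !is.na(j)
    if (any(ok)) {
      edges <- c(edges, rbind(which(ok), j[ok]))
      weights <- c(weights, rep(sqrt(sum(offs[k, ]^2)), sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
  g <- igraph::add_edges(g, edges)
  igraph::E(g)$weight <- weights
  d0 <- igraph::distances(g, v = 1L)[1L, ]
  d0[!is.finite(d0)] <- -1
  a <- which.max(d0)
  da <- igraph::distances(g, v = a)[1L, ]
  da[!is.finite(da)] <- -1
  b <- which.max(da)
  path <- igraph::shortest_paths(g, from = a, to = b)$vpath[[1L]]
  idx[as.integer(path), , drop = FALSE]
}

# Remove `trim` units of arc length from each end of a polyline, keeping at
# least 5 points (or the untrimmed polyline when it is too short).
trim_polyline_ends <- function(xy, trim) {
  n <- nrow(xy)
  if (n < 12L || trim <= 0) return(xy)
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  total <- s[n]
  if (total <= 2.5 * trim) return(xy)
  keep <- which(s >= trim & s <= total - trim)
  if (length(keep) < 5L) return(xy)
  xy[keep, , drop = FALSE]
}

# Running-mean smoothing of an open polyline (reduces staircase bias in the
# raster skeleton); endpoints use shrinking windows.
smooth_polyline <- function(xy, window = 7L) {
  n <- nrow(xy)
  if (n <= window) return(xy)
  h <- window %/% 2L
  out <- xy
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i, ] <- colMeans(xy[lo:hi, , drop = FALSE])
  }
  out
}

# Extend each axis end to the cell pole: a straight ray along the end
# tangent of the (trimmed, smoothed) skeleton path, in half-pixel steps,
# until the mask boundary.
extend_to_poles <- function(axis, mask, window_px = 14) {
  extend_one <- function(axis, from_end) {
    n <- nrow(axis)
    u <- if (from_end) axis else axis[n:1, , drop = FALSE]   # end last
    s <- c(0, cumsum(sqrt(rowSums(diff(u)^2))))
    total <- s[n]
    sel <- which(s >= total - min(window_px, total / 2))
    if (length(sel) < 3L) sel <- max(1L, n - 4L):n
    seg <- diff(u[sel, , drop = FALSE])
    keep <- rowSums(seg^2) > 1e-12
    if (sum(keep) < 2L) return(axis)
    ang_raw <- atan2(seg[keep, 1L], seg[keep, 2L])
    ang <- cumsum(c(ang_raw[1L], atan2(sin(diff(ang_raw)),
                                       cos(diff(ang_raw)))))  # unwrapped
    sm <- (s[sel[-length(sel)]] + s[sel[-1L]])[keep] / 2
    cf <- coef(lm(ang ~ sm))
    kappa <- cf[2L]                      # signed curvature, rad/px
    ang_tip <- cf[1L] + cf[2L] * total   # tangent angle at the very tip
    pt <- u[nrow(u), ]
    a <- ang_tip
    ext <- NULL
    for (step in seq_len(200L)) {
      a <- a + kappa * 0.5
      nxt <- pt + 0.5 * c(sin(a), cos(a))
      r <- round(nxt[1L]); c <- round(nxt[2L])
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask) ||
          mask[r, c] != 1L) break
      ext <- rbind(ext, nxt)
      pt <- nxt
    }
    if (is.null(ext)) return(axis)
    if (from_end) rbind(axis, ext) else rbind(ext[rev(seq_len(nrow(ext))), ,
                                                  drop = FALSE], axis)
  }
  axis <- extend_one(axis, TRUE)
  extend_one(axis, FALSE)
}

#' Split a cell outline into outer- and inner-curve paths
#'
#' Partitions the closed outline into the two lateral edge paths between
#' the cell poles by projecting every outline vertex onto the medial axis:
#' vertices whose nearest axis point is interior are assigned to the left
#' or right side of the axis (sign of the cross product with the local
#' tangent); vertices projecting onto an axis endpoint belong to the pole
#' caps and separate the two edges. Both paths are oriented pole A ->
#' pole B. For a cell curved in one direction the shorter edge is the inner
#' (concave) curve and the longer the outer (convex) curve; when the two
#' differ by less than 4% in arc length the cell is treated as straight, a
#' deterministic side-sign fallback assigns the labels, and the result is
#' flagged.
#'
#' @param geom A `cell_geometry` from [extract_geometry()].
#' @return A list of class `cell_edges`: `outer`, `inner` (tibbles `row`,
#'   `col`), `outer_length_um`, `inner_length_um`, `symmetric_flagged`.
#' @export
split_edges <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  outline <- as.matrix(geom$outline[, c("row", "col")])
  axis <- resample_polyline(as.matrix(geom$axis[, c("row", "col")]), 200L)
  # trim half a cell width off each axis end before classifying: tangents
  # near the extended tips are unreliable and the pole caps must not be
  # claimed by either edge
  hw <- geom$half_width_px %||% 0
  len_px <- polyline_length(axis)
  q <- max(2L, ceiling(200L * hw / max(len_px, 1e-9)))
  if (2L * q + 10L >= 200L) {
    abort("cell too short relative to its width to separate edge paths")
  }
  axis <- axis[q:(200L - q + 1L), , drop = FALSE]
  m <- nrow(axis)

  # nearest axis sample, local tangent, and signed side per outline vertex
  n <- nrow(outline)
  j <- integer(n); side <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (axis[, 1L] - outline[i, 1L])^2 + (axis[, 2L] - outline[i, 2L])^2
    j[i] <- which.min(d2)
    k <- min(max(j[i], 2L), m - 1L)
    tang <- axis[k + 1L, ] - axis[k - 1L, ]
    v <- outline[i, ] - axis[j[i], ]
    side[i] <- tang[1L] * v[2L] - tang[2L] * v[1L]
  }
  is_cap <- j <= 2L | j >= m - 1L
  lab <- ifelse(is_cap, 0L, ifelse(side > 0, 1L, -1L))
  if (!any(lab == 1L) || !any(lab == -1L)) {
    abort("could not separate two edge paths; is the mask elongated?")
  }

  # longest contiguous run of each side on the cyclic outline
  extract_run <- function(want) {
    r <- rle(c(lab, lab) == want)             # doubled for wrap-around
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths == max(r$lengths[r$values]))
    i2 <- ends[ok[1L]]; i1 <- i2 - r$lengths[ok[1L]] + 1L
    idx <- ((i1:i2 - 1L) %% n) + 1L
    idx[seq_len(min(length(idx), n))]
  }
  run_a <- extract_run(1L)
  run_b <- extract_run(-1L)

  orient <- function(idx) {
    path <- outline[idx, , drop = FALSE]
    if (j[idx[1L]] > j[idx[length(idx)]]) {
      path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
    }
    smooth_polyline(path, window = 5L)   # removes raster staircase bias
  }
  path_a <- orient(run_a)
  path_b <- orient(run_b)

  # the concave (inner) side is the side the axis turns toward: total
  # signed turn of the axis tangent decides the labels, independent of the
  # few-pixel length asymmetry a raster contour carries. Tangents are taken
  # over ~10-sample baselines so raster noise does not corrupt the sum.
  coarse <- axis[unique(c(seq(1L, m, by = 10L), m)), , drop = FALSE]
  tang <- diff(coarse)
  ang <- atan2(tang[, 1L], tang[, 2L])
  turn <- sum(atan2(sin(diff(ang)), cos(diff(ang))))
  symmetric <- abs(turn) < 0.2           # < ~11 degrees: effectively straight
  if (symmetric) {
    warn("axis turns by < 0.2 rad; near-straight cell, labelling by arc length")
    inner_is_a <- polyline_length(path_a) <= polyline_length(path_b)
  } else {
    # side was cross(tangent, vertex - axis); the centre of curvature lies
    # on the negative-cross side when the total turn is positive
    inner_is_a <- turn < 0
  }
  inner <- if (inner_is_a) path_a else path_b
  outer <- if (inner_is_a) path_b else path_a
  ps <- geom$pixel_size
  structure(list(
    outer = tibble(row = outer[, 1L], col = outer[, 2L]),
    inner = tibble(row = inner[, 1L], col = inner[, 2L]),
    outer_length_um = polyline_length(outer) * ps,
    inner_length_um = polyline_length(inner) * ps,
    symmetric_flagged = symmetric
  ), class = "cell_edges")
}

#' @export
print.cell_edges <- function(x, ...) {
  cat(sprintf("<cell_edges> outer %.2f um, inner %.2f um%s\n",
              x$outer_length_um, x$inner_length_um,
              if (x$symmetric_flagged) " (near-straight, flagged)" else ""))
  invisible(x)
}

#' Sinuosity of a medial axis
#'
#' Arc length of the centerline divided by the Euclidean distance between
#' its endpoints. 1 for a straight cell; pi/2 for a semicircular one.
#'
#' @param geom A `cell_geometry`, or a two-column (row, col) matrix /
#'   data frame giving the axis polyline.
#' @return A single number >= 1.
#' @export
sinuosity <- function(geom) {
  axis <- if (inherits(geom, "cell_geometry")) {
    as.matrix(geom$axis[, c("row", "col")])
  } else {
    as.matrix(as.data.frame(geom)[, 1:2])
  }
  if (nrow(axis) < 2L) abort("axis needs at least 2 points")
  chord <- sqrt(sum((axis[nrow(axis), ] - axis[1L, ])^2))
  if (chord < .Machine$double.eps^0.5) {
    abort("axis endpoints coincide; sinuosity undefined")
  }
  max(polyline_length(axis) / chord, 1)
}
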