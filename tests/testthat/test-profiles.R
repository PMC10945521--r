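arc_fixture <- function(enrichment = 2, noise_sd = 0, seed = 1, radius = 40,
                        angle = pi, width = 10) {
  cc <- render_curved_cell(centerline_radius = radius, arc_angle = angle,
                           cell_width = width, inner_enrichment = enrichment,
                           noise_sd = noise_sd, seed = seed)
  g <- extract_geometry(cc$mask)
  list(cc = cc, g = g, e = split_edges(g))
}

test_that("profiles on a uniform image are constant", {
  f <- arc_fixture(enrichment = 1)
  img <- matrix(7, nrow(f$cc$mask), ncol(f$cc$mask))
  ep <- edge_profiles(img, f$e, f$cc$mask)
  expect_true(all(abs(ep$intensity - 7) < 1e-12))
  ap <- axis_profile(img, f$g, f$cc$mask)
  expect_true(all(abs(ap$intensity - 7) < 1e-12))
})

test_that("edge profiles recover the rendered inner-curve enrichment", {
  f <- arc_fixture(enrichment = 2, noise_sd = 0)
  ep <- edge_profiles(f$cc$channel_b, f$e, f$cc$mask)
  expect_equal(inner_enrichment(ep), 2.0, tolerance = 0.05)
})

test_that("profile means are stable under resampling density", {
  f <- arc_fixture(enrichment = 1.5)
  ep10 <- edge_profiles(f$cc$channel_b, f$e, f$cc$mask, n_points = 10)
  ep25 <- edge_profiles(f$cc$channel_b, f$e, f$cc$mask, n_points = 25)
  ep100 <- edge_profiles(f$cc$channel_b, f$e, f$cc$mask, n_points = 100)
  expect_equal(mean(ep10$intensity), mean(ep100$intensity), tolerance = 0.02)
  expect_equal(inner_enrichment(ep25), inner_enrichment(ep100),
               tolerance = 0.03)
})

test_that("concatenation appends inner after outer and round-trips", {
  f <- arc_fixture()
  ep <- edge_profiles(f$cc$channel_b, f$e, f$cc$mask, n_points = 20)
  cp <- concat_profile(ep)
  expect_equal(nrow(cp), 40L)
  expect_equal(attr(cp, "transition_index"), 20L)
  outer <- ep$intensity[ep$side == "outer"]
  inner <- ep$intensity[ep$side == "inner"]
  expect_equal(cp$intensity[1:20], outer)
  expect_equal(cp$intensity[21:40], inner)
  # splitting at the transition recovers the inputs exactly
  t <- attr(cp, "transition_index")
  expect_identical(cp$intensity[seq_len(t)], outer)
  expect_identical(cp$intensity[-seq_len(t)], inner)
})

test_that("a bright pole shows up at the matching end of the axis profile", {
  m <- rect_mask()
  g <- extract_geometry(m)
  img <- matrix(0, nrow(m), ncol(m))
  img[m == 1L] <- 10
  img[6:15, 6:15] <- 100                      # bright left pole
  ap <- axis_profile(img, g, m, n_points = 30)
  peak <- which.max(ap$intensity)
  expect_true(peak <= 5 || peak >= 26)        # at an end, whichever pole is A
})

test_that("axis profile integral is consistent with the band-restricted sum", {
  m <- rect_mask()
  g <- extract_geometry(m)
  img <- matrix(0, nrow(m), ncol(m)); img[m == 1L] <- 3
  ap <- axis_profile(img, g, m, n_points = 40)
  expect_equal(mean(ap$intensity), 3, tolerance = 1e-12)
})

test_that("enrichment of identical profiles is exactly 1 and mirrors agree", {
  f <- arc_fixture(enrichment = 1)
  ep <- edge_profiles(f$cc$channel_a, f$e, f$cc$mask)
  expect_equal(inner_enrichment(ep), 1, tolerance = 0.02)

  f2 <- arc_fixture(enrichment = 2)
  ep2 <- edge_profiles(f2$cc$channel_b, f2$e, f2$cc$mask)
  mir_mask <- f2$cc$mask[, rev(seq_len(ncol(f2$cc$mask)))]
  mir_img <- f2$cc$channel_b[, rev(seq_len(ncol(f2$cc$channel_b)))]
  gm <- extract_geometry(mir_mask)
  epm <- edge_profiles(mir_img, split_edges(gm), mir_mask)
  expect_equal(inner_enrichment(epm), inner_enrichment(ep2),
               tolerance = 0.03)
})

test_that("zero outer signal makes enrichment an error, not infinity", {
  f <- arc_fixture(enrichment = 1)
  img <- matrix(0, nrow(f$cc$mask), ncol(f$cc$mask))
  ep <- edge_profiles(img, f$e, f$cc$mask)
  expect_error(inner_enrichment(ep), "zero")
})

test_that("a sampling band escaping the image is refused", {
  m <- matrix(0L, 12, 40); m[2:11, 2:39] <- 1L
  g <- extract_geometry(m)
  e <- suppressWarnings(split_edges(g))
  img <- matrix(1, 12, 40)
  expect_error(edge_profiles(img, e, m, band_width_px = 6), "beyond")
})

test_that("demograph rows are sorted by length and normalized per cell", {
  profs <- list(a = c(1, 5, 3), b = rnorm(20), c = rnorm(30), d = rnorm(10))
  dg <- build_demograph(profs, lengths = c(3, 20, 30, 10))
  info <- attr(dg, "cell_info")
  expect_equal(info$cell_id, c("a", "d", "b", "c"))
  expect_equal(nrow(dg), 4L)
  for (i in seq_len(nrow(dg))) {
    row <- dg[i, !is.na(dg[i, ])]
    expect_equal(min(row), 0)
    expect_equal(max(row), 1)
  }
})

test_that("flat profiles normalize to 0.5 and are flagged", {
  dg <- build_demograph(list(x = rep(2, 10), y = 1:10))
  info <- attr(dg, "cell_info")
  expect_true(info$flat[info$cell_id == "x"])
  expect_true(all(dg["x", !is.na(dg["x", ])] == 0.5))
})

test_that("transition alignment registers the outer/inner boundary", {
  profs <- list(p = 1:10, q = 1:16, r = 1:12)
  dg <- build_demograph(profs, lengths = c(10, 16, 12),
                        align = "transition", transitions = c(4, 8, 6))
  tc <- attr(dg, "transition_col")
  expect_equal(tc, 8L)
  # every cell's transition lands on the same column
  expect_equal(unname(dg["p", tc]), 3 / 9)   # p: position 4 of 1:10, scaled
  expect_false(is.na(dg["q", tc]))
  expect_false(is.na(dg["r", tc]))
})

test_that("the demograph of enriched curved cells is brighter inner-side", {
  ncells <- 25
  profs <- vector("list", ncells)
  lens <- numeric(ncells)
  trans <- integer(ncells)
  for (i in seq_len(ncells)) {
    f <- arc_fixture(enrichment = 2, noise_sd = 4, seed = 100 + i,
                     radius = 25 + (i %% 5) * 4,
                     angle = 2.0 + (i %% 7) * 0.15, width = 10)
    ep <- edge_profiles(f$cc$channel_b, f$e, f$cc$mask, n_points = 25)
    cp <- concat_profile(ep)
    profs[[i]] <- cp$intensity
    lens[i] <- attr(cp, "arc_length_um")
    trans[i] <- attr(cp, "transition_index")
  }
  dg <- build_demograph(profs, lengths = lens, align = "transition",
                        transitions = trans)
  tc <- attr(dg, "transition_col")
  outer_mean <- mean(dg[, seq_len(tc)], na.rm = TRUE)
  inner_mean <- mean(dg[, (tc + 1L):ncol(dg)], na.rm = TRUE)
  expect_gt(inner_mean, outer_mean)
  expect_equal(nrow(dg), ncells)             # no row lost or duplicated
})

test_that("demograph input validation catches mismatches", {
  expect_error(build_demograph(list()), "at least one")
  expect_error(build_demograph(list(1:5), lengths = c(1, 2)), "one value")
  expect_error(build_demograph(list(1:5), align = "transition"),
               "transitions")
})
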