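#' Simulate two-state Brownian single-particle trajectories
#'
#' Generates trajectories mimicking slimfield single-molecule tracking of a
#' protein that exchanges between a polymer-bound ("static") and a freely
#' diffusing ("mobile") state. Each track is assigned an identity by a
#' Bernoulli draw with probability `f_static`; per-axis steps are zero-mean
#' Gaussian with variance 2*D*dt for the state's diffusion coefficient.
#' Localization error, when requested, is added to recorded *positions*, so
#' consecutive observed displacements are negatively correlated, as in real
#' localization microscopy data.
#'
#' By default molecules do not switch state within a track, matching the
#' assumption of the downstream displacement mixture model; `switching`
#' enables a two-state Markov chain with binding rate `k_on` (mobile ->
#' static) and unbinding rate `k_off` (static -> mobile), applied per frame.
#'
#' @param n_tracks Number of tracks.
#' @param steps_per_track Steps per track (fixed length), or the mean of a
#'   geometric length distribution when `track_length_model = "geometric"`
#'   (a crude photobleaching model; minimum 1 step).
#' @param d_static,d_mobile Diffusion coefficients, um^2/s
#'   (`d_static <= d_mobile`).
#' @param f_static Fraction of tracks in the static state, in `[0, 1]`.
#' @param frame_interval Frame interval dt in seconds; default 0.03 s
#'   (30 ms acquisition).
#' @param localization_sd Localization error SD in um, added independently to
#'   every recorded coordinate. Default 0.
#' @param confinement Optional region the particles are confined to by
#'   specular reflection: `list(type = "rectangle", xlim =, ylim =)` or
#'   `list(type = "spherocylinder", length =, radius =)` (um, centred at the
#'   origin; `length` is the cylinder-axis length between cap centres).
#' @param track_length_model `"fixed"` (default) or `"geometric"`.
#' @param switching Optional `list(k_on =, k_off =)` rates in 1/s.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A [track_set] with a `ground_truth` attribute: a tibble with one
#'   row per track (`track_id`, `state` of the first step, `n_steps`).
#' @export
#' @examples
#' ts <- simulate_tracks(n_tracks = 20, f_static = 0.5, seed = 1)
#' ts
simulate_tracks <- function(n_tracks = 500,
                            steps_per_track = 20,
                            d_static = 0.02,
                            d_mobile = 0.35,
                            f_static = 0.7,
                            frame_interval = 0.03,
                            localization_sd = 0,
                            confinement = NULL,
                            track_length_model = c("fixed", "geometric"),
                            switching = NULL,
                            seed = 1L) {
  n_tracks <- stop_if_not_count(n_tracks, "n_tracks")
  stop_if_not_scalar_number(d_static, "d_static", 0)
  stop_if_not_scalar_number(d_mobile, "d_mobile", 0)
  if (d_static > d_mobile) abort("`d_static` must be <= `d_mobile`")
  stop_if_not_scalar_number(f_static, "f_static", 0, 1)
  stop_if_not_scalar_number(frame_interval, "frame_interval", 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(localization_sd, "localization_sd", 0)
  track_length_model <- match.arg(track_length_model)
  if (!is.null(confinement)) validate_confinement(confinement)

  set.seed(new_seed(seed))

  lengths <- if (track_length_model == "fixed") {
    rep(stop_if_not_count(steps_per_track, "steps_per_track"), n_tracks)
  } else {
    pmax(1L, stats::rgeom(n_tracks, prob = 1 / steps_per_track))
  }
  state0 <- rbinom(n_tracks, 1L, f_static) == 1L   # TRUE = static

  sigma <- function(static) sqrt(2 * ifelse(static, d_static, d_mobile) *
                                   frame_interval)

  tracks <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    n_steps <- lengths[i]
    if (is.null(switching)) {
      static <- rep(state0[i], n_steps)
    } else {
      static <- simulate_switching(state0[i], n_steps, switching,
                                   frame_interval)
    }
    dx <- rnorm(n_steps, 0, sigma(static))
    dy <- rnorm(n_steps, 0, sigma(static))
    start <- if (is.null(confinement)) c(0, 0) else {
      confinement_uniform_point(confinement)
    }
    if (is.null(confinement)) {
      x <- start[1L] + cumsum(c(0, dx))
      y <- start[2L] + cumsum(c(0, dy))
    } else {
      pos <- matrix(NA_real_, n_steps + 1L, 2L)
      pos[1L, ] <- start
      for (k in seq_len(n_steps)) {
        pos[k + 1L, ] <- reflect_into(pos[k, ] + c(dx[k], dy[k]), confinement)
      }
      x <- pos[, 1L]; y <- pos[, 2L]
    }
    if (localization_sd > 0) {
      x <- x + rnorm(n_steps + 1L, 0, localization_sd)
      y <- y + rnorm(n_steps + 1L, 0, localization_sd)
    }
    tracks[[i]] <- tibble(track_id = i, frame = 0:n_steps, x_um = x, y_um = y)
  }

  out <- track_set(bind_rows(tracks), frame_interval = frame_interval)
  attr(out, "ground_truth") <- tibble(
    track_id = seq_len(n_tracks),
    state = ifelse(state0, "static", "mobile"),
    n_steps = lengths
  )
  out
}

simulate_switching <- function(static0, n_steps, switching, dt) {
  stopifnot(is.list(switching), all(c("k_on", "k_off") %in% names(switching)))
  p_bind <- 1 - exp(-switching$k_on * dt)    # mobile -> static
  p_release <- 1 - exp(-switching$k_off * dt)
  static <- logical(n_steps)
  s <- static0
  for (k in seq_len(n_steps)) {
    static[k] <- s
    s <- if (s) runif(1) >= p_release else runif(1) < p_bind
  }
  static
}

validate_confinement <- function(conf) {
  if (!is.list(conf) || is.null(conf$type)) {
    abort("`confinement` must be a list with a `type` field")
  }
  switch(conf$type,
    rectangle = {
      stopifnot(length(conf$xlim) == 2L, length(conf$ylim) == 2L,
                conf$xlim[1L] < conf$xlim[2L], conf$ylim[1L] < conf$ylim[2L])
    },
    spherocylinder = {
      stop_if_not_scalar_number(conf$length, "confinement$length", 0)
      stop_if_not_scalar_number(conf$radius, "confinement$radius", 0,
                                strict_lower = TRUE)
    },
    abort(sprintf("unknown confinement type '%s'", conf$type))
  )
  invisible(conf)
}

confinement_uniform_point <- function(conf) {
  repeat {
    p <- switch(conf$type,
      rectangle = c(runif(1, conf$xlim[1L], conf$xlim[2L]),
                    runif(1, conf$ylim[1L], conf$ylim[2L])),
      spherocylinder = c(
        runif(1, -conf$length / 2 - conf$radius, conf$length / 2 + conf$radius),
        runif(1, -conf$radius, conf$radius)
      )
    )
    if (inside_confinement(p, conf)) return(p)
  }
}

inside_confinement <- function(p, conf) {
  switch(conf$type,
    rectangle = p[1L] >= conf$xlim[1L] && p[1L] <= conf$xlim[2L] &&
      p[2L] >= conf$ylim[1L] && p[2L] <= conf$ylim[2L],
    spherocylinder = {
      ax <- pmin(pmax(p[1L], -conf$length / 2), conf$length / 2)
      (p[1L] - ax)^2 + p[2L]^2 <= conf$radius^2
    }
  )
}

# Specular reflection of a proposed position back into the region. Folding
# is exact for the rectangle; for the spherocylinder the radial overshoot is
# folded about the nearest boundary point, iterated for large steps.
reflect_into <- function(p, conf, max_iter = 50L) {
  if (conf$type == "rectangle") {
    p[1L] <- fold_interval(p[1L], conf$xlim[1L], conf$xlim[2L])
    p[2L] <- fold_interval(p[2L], conf$ylim[1L], conf$ylim[2L])
    return(p)
  }
  for (i in seq_len(max_iter)) {
    if (inside_confinement(p, conf)) return(p)
    ax <- pmin(pmax(p[1L], -conf$length / 2), conf$length / 2)
    v <- p - c(ax, 0)
    r <- sqrt(sum(v^2))
    p <- c(ax, 0) + v * (2 * conf$radius / r - 1)   # fold radial overshoot
  }
  c(ax <- pmin(pmax(p[1L], -conf$length / 2), conf$length / 2),
    0) + (p - c(ax, 0)) * conf$radius / sqrt(sum((p - c(ax, 0))^2))
}

fold_interval <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}
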