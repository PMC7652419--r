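# Synthetic startle-trial tables and arena trajectories.

#' Generate a startle trial table with programmed attenuation
#'
#' Block 1 holds `n_tone` tone-only trials (basal startle); block 2 holds
#' `n_tone` further tone-only trials interleaved with `n_prepulse` trials per
#' prepulse level, attenuated by the truth's per-level fractions. With
#' `cv = 0`, [ppi_percent()] returns the programmed attenuation x 100
#' exactly.
#'
#' @param truth a [ground_truth()] (uses `ppi_params` and `seed`).
#' @param n_tone tone-only trials per block (default 10).
#' @param n_prepulse trials per prepulse level (default 5).
#' @param cv coefficient of variation of multiplicative trial noise.
#' @param seed RNG seed (default: the truth's startle substream).
#' @return data.frame: `trial`, `block`, `condition`, `amplitude`.
#' @export
gen_startle_trials <- function(truth, n_tone = 10, n_prepulse = 5, cv = 0.2,
                               seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  pp <- truth$ppi_params
  if (pp$basal < 0) stop("negative basal startle mean", call. = FALSE)
  if (n_tone < 1 || n_prepulse < 1) stop("trial counts must be >= 1",
                                         call. = FALSE)
  if (cv < 0) stop("`cv` must be nonnegative", call. = FALSE)
  if (is.null(seed)) seed <- substream_seed(truth, "startle")

  lv_names <- paste0("prepulse_+", names(pp$attenuation), "dB")
  with_seed(seed, {
    noise <- function(n) pmax(0, 1 + cv * stats::rnorm(n))
    rows <- list(
      data.frame(block = 1L, condition = "tone_only",
                 amplitude = pp$basal * noise(n_tone)),
      data.frame(block = 2L, condition = "tone_only",
                 amplitude = pp$basal * noise(n_tone)))
    for (i in seq_along(pp$attenuation)) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = 2L, condition = lv_names[i],
        amplitude = pp$basal * (1 - pp$attenuation[[i]]) * noise(n_prepulse))
    }
    out <- do.call(rbind, rows)
    out$trial <- seq_len(nrow(out))
    out[, c("trial", "block", "condition", "amplitude")]
  })
}

#' Generate a correlated-random-walk trajectory in an arena
#'
#' Heading evolves by wrapped-Gaussian increments (SD
#' `(1 - persistence) * pi`), step lengths are Weibull(shape 2) with the
#' truth's scale. In rectangular arenas with no avoidance the free path is
#' folded into the box (billiard reflection), which leaves the occupancy
#' distribution uniform; otherwise steps are proposed sequentially, steps
#' leaving the arena are re-aimed, and steps entering the anxiogenic zone are
#' accepted only with probability `exp(-avoid)`.
#'
#' @param truth a [ground_truth()] (uses `track_params` and `seed`).
#' @param arena an arena object ([open_field_arena()], [epm_arena()],
#'   [ld_arena()]).
#' @param duration recording length, seconds (default 600).
#' @param fs frame rate, Hz (default 25).
#' @param start release position: `NULL` for the arena's standard release
#'   point (e.g. an open-field corner), `"random"` for a uniform draw over
#'   the arena (useful when the stationary occupancy itself is under study),
#'   or a `c(x, y)` coordinate.
#' @param seed RNG seed (default: the truth's track substream).
#' @return A [track()].
#' @export
gen_track <- function(truth, arena = open_field_arena(), duration = 600,
                      fs = 25, start = NULL, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(arena, "arena"))
  stop_if_not_scalar_pos(fs, "fs")
  stop_if_not_scalar_pos(duration, "duration")
  tp <- truth$track_params
  avoid <- min(tp$avoid, 50)
  n <- floor(duration * fs)
  if (is.null(seed)) seed <- substream_seed(truth, "track")

  xy <- with_seed(seed, {
    p0 <- if (is.null(start)) {
      arena$start
    } else if (identical(start, "random")) {
      repeat {
        cand <- c(stats::runif(1, arena$bbox$xmin, arena$bbox$xmax),
                  stats::runif(1, arena$bbox$ymin, arena$bbox$ymax))
        if (in_arena(arena, cand[1], cand[2])) break
      }
      cand
    } else {
      if (!in_arena(arena, start[1], start[2])) {
        stop("`start` lies outside the arena", call. = FALSE)
      }
      start
    }
    steps <- stats::rweibull(n, shape = 2, scale = tp$step)
    dth <- stats::rnorm(n, 0, (1 - tp$persistence) * pi)
    theta <- cumsum(dth)
    dx <- steps * cos(theta)
    dy <- steps * sin(theta)
    if (arena$shape == "rect" && avoid == 0) {
      x <- fold_interval(p0[1] + cumsum(dx),
                         arena$bbox$xmin, arena$bbox$xmax)
      y <- fold_interval(p0[2] + cumsum(dy),
                         arena$bbox$ymin, arena$bbox$ymax)
      cbind(c(p0[1], x), c(p0[2], y))
    } else {
      x <- numeric(n + 1); y <- numeric(n + 1)
      x[1] <- p0[1]; y[1] <- p0[2]
      th <- 0
      avoid_zone <- arena$anxiogenic
      for (i in seq_len(n)) {
        th <- th + dth[i]
        placed <- FALSE
        ang <- th
        for (try in 1:30) {
          cx <- x[i] + steps[i] * cos(ang)
          cy <- y[i] + steps[i] * sin(ang)
          if (in_arena(arena, cx, cy)) {
            enter_anx <- avoid > 0 &&
              in_zone(arena, avoid_zone, cx, cy) &&
              !in_zone(arena, avoid_zone, x[i], y[i])
            if (enter_anx && stats::runif(1) > exp(-avoid)) break # stay put
            x[i + 1] <- cx; y[i + 1] <- cy
            th <- ang
            placed <- TRUE
            break
          }
          ang <- stats::runif(1, -pi, pi)
        }
        if (!placed) { x[i + 1] <- x[i]; y[i + 1] <- y[i] }
      }
      cbind(x, y)
    }
  })
  track(t = (0:n) / fs, x = xy[, 1], y = xy[, 2], fs = fs, arena = arena)
}
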