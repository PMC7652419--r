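# Behavioral scoring: prepulse inhibition of acoustic startle, and
# zone-occupancy metrics from overhead-camera trajectory tracks.

.rect <- function(xmin, xmax, ymin, ymax) {
  list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
}

.in_rects <- function(rects, x, y) {
  inside <- rep(FALSE, length(x))
  for (r in rects) {
    inside <- inside | (x >= r$xmin & x <= r$xmax & y >= r$ymin & y <= r$ymax)
  }
  inside
}

# `floor` is the list of rectangles whose union is the walkable surface;
# `shape = "rect"` asserts that union is itself the bounding box.
.arena <- function(zones, anxiogenic, bbox, shape, start, floor = NULL) {
  if (is.null(floor)) floor <- list(bbox)
  structure(list(zones = zones, anxiogenic = anxiogenic, bbox = bbox,
                 shape = shape, start = start, floor = floor),
            class = "arena")
}

#' Open-field arena with a centered anxiogenic zone
#'
#' @param width side of the square arena, cm (default 40).
#' @param center_width side of the centered square center zone, cm
#'   (default 20). The `periphery` zone is its complement.
#' @return An `arena` object with zones `center` and `periphery`.
#' @export
open_field_arena <- function(width = 40, center_width = 20) {
  if (width <= 0 || center_width <= 0 || center_width >= width) {
    stop("need 0 < center_width < width (zero-area arena rejected)",
         call. = FALSE)
  }
  m <- (width - center_width) / 2
  .arena(
    zones = list(center = list(rects = list(.rect(m, width - m, m, width - m))),
                 periphery = list(complement_of = "center")),
    anxiogenic = "center",
    bbox = .rect(0, width, 0, width), shape = "rect",
    start = c(1, 1))
}

#' Elevated-plus-maze arena
#'
#' Open arms lie along the x axis, closed arms along y; the central square
#' belongs to neither arm class.
#'
#' @param arm_len,arm_w arm length and width, cm (default 30 x 5).
#' @return An `arena` with zones `open`, `closed`, `center`.
#' @export
epm_arena <- function(arm_len = 30, arm_w = 5) {
  if (arm_len <= 0 || arm_w <= 0) stop("zero-area arena", call. = FALSE)
  h <- arm_w / 2
  e <- h + arm_len
  .arena(
    zones = list(
      open = list(rects = list(.rect(h, e, -h, h), .rect(-e, -h, -h, h))),
      closed = list(rects = list(.rect(-h, h, h, e), .rect(-h, h, -e, -h))),
      center = list(rects = list(.rect(-h, h, -h, h)))),
    anxiogenic = "open",
    bbox = .rect(-e, e, -e, e), shape = "plus",
    start = c(0, -(h + arm_len / 2)),
    floor = list(.rect(-e, e, -h, h), .rect(-h, h, -e, e)))
}

#' Light-dark box arena
#'
#' @param light,dark `c(width, depth)` of the two chambers, cm
#'   (defaults 25x25 and 15x25); chambers share the full dividing wall.
#' @return An `arena` with zones `light` and `dark`.
#' @export
ld_arena <- function(light = c(25, 25), dark = c(15, 25)) {
  if (any(light <= 0) || any(dark <= 0)) stop("zero-area arena", call. = FALSE)
  depth <- min(light[2], dark[2])
  .arena(
    zones = list(
      light = list(rects = list(.rect(0, light[1], 0, depth))),
      dark = list(rects = list(.rect(light[1], light[1] + dark[1], 0, depth)))),
    anxiogenic = "light",
    bbox = .rect(0, light[1] + dark[1], 0, depth), shape = "rect",
    start = c(light[1] + dark[1] / 2, depth / 2))
}

in_zone <- function(arena, zone, x, y) {
  z <- arena$zones[[zone]]
  if (is.null(z)) {
    stop(sprintf("arena has no zone '%s' (zones: %s)", zone,
                 paste(names(arena$zones), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(z$complement_of)) {
    in_arena(arena, x, y) & !in_zone(arena, z$complement_of, x, y)
  } else {
    .in_rects(z$rects, x, y)
  }
}

in_arena <- function(arena, x, y) {
  .in_rects(arena$floor, x, y)
}

#' Construct a trajectory track
#'
#' @param t,x,y time (s, strictly increasing) and position (cm) samples.
#' @param fs nominal sampling rate, Hz.
#' @param arena the `arena` the positions live in; all samples must fall
#'   inside it.
#' @return data.frame of class `track` with attributes `fs`, `arena`.
#' @export
track <- function(t, x, y, fs, arena) {
  if (length(t) < 1 || length(x) != length(t) || length(y) != length(t)) {
    stop("t, x, y must have equal positive length", call. = FALSE)
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (!all(in_arena(arena, x, y))) {
    stop("track leaves the arena", call. = FALSE)
  }
  structure(data.frame(t = t, x = x, y = y),
            fs = fs, arena = arena, class = c("track", "data.frame"))
}

# Debounce an inside/outside indicator: inside runs shorter than `debounce`
# samples are treated as boundary jitter and folded back into outside.
.debounce_inside <- function(inside, debounce) {
  if (debounce <= 1 || !length(inside)) return(inside)
  r <- rle(inside)
  r$values[r$values & r$lengths < debounce] <- FALSE
  inverse.rle(r)
}

#' Occupancy metrics for one named zone
#'
#' @param trk a [track()].
#' @param zone zone name in the track's arena.
#' @param debounce entry persistence in samples (default 2): an entry is an
#'   outside-to-inside transition persisting at least this long.
#' @return One-row data.frame: `zone`, `total_distance` (cm),
#'   `pct_distance_in_zone`, `pct_time_in_zone`, `entries`. Distance of a
#'   step is attributed to the zone containing its destination sample.
#' @export
zone_metrics <- function(trk, zone, debounce = 2) {
  stopifnot(inherits(trk, "track"))
  arena <- attr(trk, "arena")
  inside <- in_zone(arena, zone, trk$x, trk$y)
  steps <- sqrt(diff(trk$x)^2 + diff(trk$y)^2)
  total <- sum(steps)
  pct_dist <- if (total > 0) 100 * sum(steps[inside[-1]]) / total else 0
  deb <- .debounce_inside(inside, debounce)
  entries <- if (!any(deb)) 0L else {
    r <- rle(deb)
    sum(r$values)
  }
  data.frame(zone = zone,
             total_distance = total,
             pct_distance_in_zone = pct_dist,
             pct_time_in_zone = 100 * mean(inside),
             entries = entries)
}

#' Open-field summary (center-zone metrics)
#'
#' @inheritParams zone_metrics
#' @return [zone_metrics()] of the `center` zone.
#' @export
oft_metrics <- function(trk, debounce = 2) {
  zone_metrics(trk, "center", debounce)
}

#' Elevated-plus-maze summary
#'
#' @inheritParams zone_metrics
#' @return data.frame with one [zone_metrics()] row per zone (`open`,
#'   `closed`, `center`); the three `pct_time_in_zone` values partition 100%.
#' @export
epm_metrics <- function(trk, debounce = 2) {
  do.call(rbind, lapply(c("open", "closed", "center"),
                        function(z) zone_metrics(trk, z, debounce)))
}

#' Light-dark box summary
#'
#' @inheritParams zone_metrics
#' @return One-row data.frame: `time_in_light_s`, `entries_light`,
#'   `pct_time_in_light`, `total_distance`.
#' @export
ld_metrics <- function(trk, debounce = 2) {
  zm <- zone_metrics(trk, "light", debounce)
  dur <- trk$t[nrow(trk)] - trk$t[1] + 1 / attr(trk, "fs")
  data.frame(time_in_light_s = zm$pct_time_in_zone / 100 * dur,
             entries_light = zm$entries,
             pct_time_in_light = zm$pct_time_in_zone,
             total_distance = zm$total_distance)
}

#' Percent prepulse inhibition of the startle response
#'
#' `Percent PPI = 100 * (mean tone-only startle - mean prepulse startle) /
#' mean tone-only startle`, computed per prepulse level against the tone-only
#' trials of the prepulse block. Basal startle is reported as the tone-only
#' mean of the first block. Negative values (facilitation) are allowed.
#'
#' @param trials data.frame with columns `condition` (`tone_only` or
#'   `prepulse_+<level>dB`), `amplitude` (>= 0, arbitrary load-cell units),
#'   and optionally `block`.
#' @param basal_block which block defines basal startle (default 1).
#' @return data.frame with `level`, `n_trials`, `ppi` per prepulse level;
#'   attribute `basal_startle`.
#' @examples
#' tr <- data.frame(condition = c(rep("tone_only", 3), rep("prepulse_+16dB", 3)),
#'                  amplitude = c(10, 10, 10, 4, 4, 4))
#' ppi_percent(tr)  # 60
#' @export
ppi_percent <- function(trials, basal_block = 1) {
  if (!all(c("condition", "amplitude") %in% names(trials))) {
    stop("`trials` needs columns condition, amplitude", call. = FALSE)
  }
  if (any(trials$amplitude < 0)) {
    stop("startle amplitudes must be nonnegative", call. = FALSE)
  }
  has_block <- "block" %in% names(trials)
  pp_rows <- grepl("^prepulse", trials$condition)
  if (!any(pp_rows)) stop("no prepulse trials present", call. = FALSE)

  if (has_block) {
    pp_blocks <- unique(trials$block[pp_rows])
    tone <- trials$amplitude[trials$condition == "tone_only" &
                               trials$block %in% pp_blocks]
    basal <- mean(trials$amplitude[trials$condition == "tone_only" &
                                     trials$block == basal_block])
  } else {
    tone <- trials$amplitude[trials$condition == "tone_only"]
    basal <- mean(tone)
  }
  if (!length(tone)) stop("no tone-only trials in the prepulse block",
                          call. = FALSE)
  tone_mean <- mean(tone)
  if (tone_mean == 0) stop("tone-only mean startle is zero", call. = FALSE)

  levels <- unique(trials$condition[pp_rows])
  out <- do.call(rbind, lapply(levels, function(lv) {
    amp <- trials$amplitude[trials$condition == lv]
    data.frame(level = lv, n_trials = length(amp),
               ppi = 100 * (tone_mean - mean(amp)) / tone_mean)
  }))
  attr(out, "basal_startle") <- basal
  out
}
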