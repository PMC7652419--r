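test_that("percent PPI follows the printed formula, sign included", {
  mk <- function(tone, pp) {
    data.frame(condition = c(rep("tone_only", length(tone)),
                             rep("prepulse_+16dB", length(pp))),
               amplitude = c(tone, pp))
  }
  expect_equal(ppi_percent(mk(rep(10, 5), rep(4, 5)))$ppi, 60)
  expect_equal(ppi_percent(mk(rep(10, 5), rep(10, 5)))$ppi, 0)
  expect_equal(ppi_percent(mk(rep(10, 5), rep(12, 5)))$ppi, -20)
  # invariant to rescaling all amplitudes
  expect_equal(ppi_percent(mk(rep(30, 5), rep(12, 5)))$ppi, 60)
  expect_error(ppi_percent(mk(rep(0, 5), rep(0, 5))), "zero")
  expect_error(ppi_percent(data.frame(condition = "tone_only",
                                      amplitude = 5)),
               "no prepulse")
})

test_that("basal startle is the tone-only mean of the first block", {
  tr <- data.frame(
    block = c(1, 1, 2, 2, 2, 2),
    condition = c("tone_only", "tone_only", "tone_only", "tone_only",
                  "prepulse_+8dB", "prepulse_+8dB"),
    amplitude = c(20, 22, 10, 10, 4, 4))
  res <- ppi_percent(tr)
  expect_equal(attr(res, "basal_startle"), 21)
  expect_equal(res$ppi, 60)  # against block-2 tone mean 10
})

square_track <- function(pts, fs = 10, arena = open_field_arena()) {
  track(t = seq_along(pts[, 1]) / fs, x = pts[, 1], y = pts[, 2],
        fs = fs, arena = arena)
}

test_that("zone metrics handle full-occupancy, stationary and loop tracks", {
  arena <- open_field_arena()
  inside <- cbind(runif(50, 11, 29), runif(50, 11, 29))
  trk <- square_track(inside)
  zm <- zone_metrics(trk, "center")
  expect_equal(zm$pct_time_in_zone, 100)
  expect_equal(zm$entries, 1)

  still <- square_track(cbind(rep(5, 20), rep(5, 20)))
  expect_equal(zone_metrics(still, "center")$total_distance, 0)

  # straight double crossing: out -> in -> out -> in -> out, 2 entries and
  # hand-computable in-zone path shares
  xs <- seq(1, 39, by = 0.5)
  path1 <- cbind(xs, rep(20, length(xs)))          # crosses the center band
  path2 <- cbind(rev(xs), rep(20, length(xs)))
  trk2 <- square_track(rbind(path1, path2))
  zm2 <- zone_metrics(trk2, "center")
  expect_equal(zm2$entries, 2)
  expect_equal(zm2$total_distance, 2 * 38, tolerance = 1e-9)
  # the 20-cm center band of each 38-cm crossing: 20/38 of the path
  expect_equal(zm2$pct_distance_in_zone, 100 * 20 / 38, tolerance = 2)
})

test_that("complementary zones partition time and entries stay consistent", {
  set.seed(13)
  trk <- gen_track(ground_truth(seed = 13), duration = 60)
  a <- zone_metrics(trk, "center")
  b <- zone_metrics(trk, "periphery")
  expect_equal(a$pct_time_in_zone + b$pct_time_in_zone, 100)

  ep <- epm_arena()
  trk2 <- gen_track(ground_truth(seed = 14), ep, duration = 30)
  em <- epm_metrics(trk2)
  expect_equal(sum(em$pct_time_in_zone), 100)
})

test_that("total distance is invariant under rigid motions", {
  set.seed(15)
  pts <- cbind(cumsum(runif(100, -0.5, 0.5)) + 20,
               cumsum(runif(100, -0.5, 0.5)) + 20)
  arena <- open_field_arena()
  d0 <- zone_metrics(square_track(pts), "center")$total_distance
  th <- 0.7
  rot <- cbind(cos(th) * (pts[, 1] - 20) - sin(th) * (pts[, 2] - 20) + 20,
               sin(th) * (pts[, 1] - 20) + cos(th) * (pts[, 2] - 20) + 20)
  d1 <- zone_metrics(square_track(rot), "center")$total_distance
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("light-dark and plus-maze summaries report the field's measures", {
  ld <- ld_arena()
  dark_only <- track(t = (1:40) / 10, x = runif(40, 26, 39),
                     y = runif(40, 1, 24), fs = 10, arena = ld)
  lm <- ld_metrics(dark_only)
  expect_equal(lm$entries_light, 0)
  expect_equal(lm$time_in_light_s, 0)

  # half the samples in an open arm by construction
  ep <- epm_arena()
  half <- track(t = (1:40) / 10,
                x = c(seq(5, 30, length.out = 20), rep(0, 20)),
                y = c(rep(0, 20), seq(-30, -5, length.out = 20)),
                fs = 10, arena = ep)
  em <- epm_metrics(half)
  expect_equal(em$pct_time_in_zone[em$zone == "open"], 50, tolerance = 1)

  expect_error(zone_metrics(dark_only, "open"), "no zone")
})

test_that("entry debouncing suppresses single-sample boundary jitter", {
  arena <- open_field_arena()
  # one real entry plus a one-sample blip
  xs <- c(rep(5, 5), 20, 5, 5, rep(20, 6), rep(5, 5))
  trk <- square_track(cbind(xs, rep(20, length(xs))))
  expect_equal(zone_metrics(trk, "center", debounce = 2)$entries, 1)
  expect_equal(zone_metrics(trk, "center", debounce = 1)$entries, 2)
})

test_that("track containers validate geometry and time", {
  arena <- open_field_arena()
  expect_error(track(c(1, 2), c(5, 50), c(5, 5), 10, arena), "leaves")
  expect_error(track(c(2, 1), c(5, 5), c(5, 5), 10, arena), "increasing")
  expect_error(open_field_arena(width = 0), "zero-area|center_width")
})
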