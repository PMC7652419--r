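noise_free_set <- function(...) {
  gen_step_sweeps(ground_truth(..., seed = 8), noise_sd = 0)
}

test_that("baseline measures respect their windows", {
  ss <- noise_free_set(cell_params = list(rmp = -60))
  expect_equal(measure_rmp(ss), -60, tolerance = 1e-9)
  expect_error(measure_rmp(ss, baseline_window = c(0, ss$onset + 0.05)),
               "overlaps")
  expect_error(measure_rmp(ss, baseline_window = c(0.1, 0.1)), "empty")
})

test_that("input resistance recovers the programmed value via Ohm's law", {
  for (rn in c(100, 250, 310)) {
    ss <- noise_free_set(cell_params = list(r_n = rn))
    expect_equal(input_resistance(ss), rn, tolerance = 1e-3)
  }
  ss <- noise_free_set()
  # invariant to a constant offset on the whole trace
  ss2 <- ss
  ss2$voltage <- ss$voltage + 7.5
  expect_equal(input_resistance(ss2), input_resistance(ss), tolerance = 1e-9)
})

test_that("tau fit recovers the membrane time constant", {
  ss <- noise_free_set(cell_params = list(tau = 20, sag = 0))
  expect_equal(fit_tau(ss), 20, tolerance = 0.01)

  # 0.5 mV noise at 20 kHz: within 5% across seeds
  errs <- vapply(1:12, function(i) {
    tr <- ground_truth(cell_params = list(tau = 35, sag = 0), seed = i)
    ssn <- gen_step_sweeps(tr, noise_sd = 0.5)
    abs(fit_tau(ssn) - 35) / 35
  }, numeric(1))
  expect_lt(max(errs), 0.05)

  flat <- noise_free_set()
  flat$voltage[] <- -60
  expect_error(fit_tau(flat), "flat")
})

test_that("sag measures follow the peak-minus-steady-state definition", {
  ss <- noise_free_set(cell_params = list(sag = 5))
  sg <- sag_measures(ss)
  expect_equal(sg$sag_voltage, -5, tolerance = 0.01)
  expect_gt(sg$sag_percent, 0)

  none <- noise_free_set(cell_params = list(sag = 0))
  sg0 <- sag_measures(none)
  expect_equal(sg0$sag_voltage, 0, tolerance = 1e-3)
  expect_equal(sg0$sag_percent, 0, tolerance = 0.01)
  expect_error(sag_measures(ss, current = 20), "hyperpolarizing")
})

test_that("spike detection applies threshold and refractory rules", {
  t <- seq(0, 1, by = 1e-4)
  v <- rep(-60, length(t))
  expect_length(detect_spikes(v, time = t), 0)
  spike_at <- function(v, t0) { v[t >= t0 & t < t0 + 0.001] <- 20; v }
  for (st in c(0.1, 0.3, 0.5, 0.7, 0.9)) v <- spike_at(v, st)
  st <- detect_spikes(v, time = t)
  expect_length(st, 5)
  expect_equal(st, c(0.1, 0.3, 0.5, 0.7, 0.9), tolerance = 2e-4)
  # two crossings 1 ms apart with a 2 ms refractory collapse to one
  v2 <- rep(-60, length(t)); v2 <- spike_at(v2, 0.2); v2 <- spike_at(v2, 0.2013)
  expect_length(detect_spikes(v2, time = t, refractory_ms = 2), 1)
})

test_that("accommodation index equals the printed ratio", {
  # ISIs 10, 20, 40 ms; last spike to step end 50 ms -> 50/10 = 5
  spikes <- c(0, 0.010, 0.030, 0.070)
  expect_equal(accommodation_index(spikes, step_end = 0.120), 5)
  # perfectly regular spiking filling the step -> 1
  reg <- seq(0.01, 0.1, by = 0.01)
  expect_equal(accommodation_index(reg, step_end = 0.11), 1)
  # undefined below two spikes: missing, not zero
  expect_true(is.na(accommodation_index(0.05, step_end = 0.1)))
  # scale-invariant under uniform time dilation
  expect_equal(accommodation_index(spikes * 3.7, step_end = 0.444),
               accommodation_index(spikes, step_end = 0.120))
})

test_that("generated trains yield the analytic geometric-ISI index", {
  g <- 1.4
  tr <- ground_truth(cell_params = list(accommodation = g, gain = 0.08,
                                        i_rheo = 40), seed = 2)
  ss <- gen_step_sweeps(tr, noise_sd = 0)
  I <- 180
  st <- detect_spikes(ss, I)
  # analytic train: isi1 = 1/(gain*(I - rheo)), intervals isi1 * g^k
  isi1 <- 1 / (0.08 * (I - 40))
  times <- isi1 * cumsum(g^(0:10))
  times <- times[times < 0.498]
  isis <- diff(times)
  expected <- max(c(isis, 0.5 - times[length(times)])) / isis[1]
  got <- accommodation_index(st - ss$onset, ss$offset - ss$onset)
  expect_equal(got, expected, tolerance = 0.01)
})

test_that("input-output curves count spikes and ANCOVA compares groups", {
  tr <- ground_truth(seed = 4)
  ss <- gen_step_sweeps(tr, noise_sd = 0)
  io <- io_curve(ss)
  expect_true(all(io$n_spikes[io$current <= 40] == 0))
  expect_true(all(diff(io$n_spikes[io$current >= 40]) >= 0))

  # identical groups: interaction F ~ 0, group p ~ 1
  one <- io_curve(ss)
  mk <- function(cell, group) cbind(one, cell = cell, group = group)
  same <- rbind(mk("a1", "A"), mk("a2", "A"), mk("b1", "B"), mk("b2", "B"))
  res <- compare_io(same)
  expect_lt(res$slope_F, 1e-9)
  expect_gt(res$intercept_p, 0.99)

  # programmed slope ratio 2 with mild noise is detected on the slope
  set.seed(99)
  grid <- seq(0, 180, by = 20)
  cells <- function(gain, group, n = 4) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(cell = paste0(group, i), group = group, current = grid,
                 n_spikes = pmax(0, round(gain * grid / 20 +
                                            rnorm(length(grid), 0, 0.3))))
    }))
  }
  two <- rbind(cells(1, "A"), cells(2, "B"))
  expect_lt(compare_io(two)$slope_p, 0.05)

  single <- rbind(data.frame(cell = "a", group = "A", current = 100, n_spikes = 3),
                  data.frame(cell = "b", group = "A", current = 100, n_spikes = 4),
                  data.frame(cell = "c", group = "B", current = 100, n_spikes = 5),
                  data.frame(cell = "d", group = "B", current = 100, n_spikes = 6))
  expect_error(compare_io(single), "two current levels")
})
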