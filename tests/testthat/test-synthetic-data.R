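truth_default <- function(...) ground_truth(..., seed = 42L)

test_that("a fixed seed reproduces every generated dataset exactly", {
  tr <- truth_default()
  expect_identical(gen_isotopomer_dataset(tr, noise_cv = 0.1, n = 3),
                   gen_isotopomer_dataset(tr, noise_cv = 0.1, n = 3))
  expect_identical(gen_step_sweeps(tr, noise_sd = 0.5),
                   gen_step_sweeps(tr, noise_sd = 0.5))
  g1 <- suppressWarnings(gen_psc_trace(tr, duration = 5))
  g2 <- suppressWarnings(gen_psc_trace(tr, duration = 5))
  expect_identical(g1, g2)
  expect_identical(gen_startle_trials(tr), gen_startle_trials(tr))
  expect_identical(gen_track(tr, duration = 5), gen_track(tr, duration = 5))
  expect_identical(gen_qpcr(tr), gen_qpcr(tr))
})

test_that("noise-free isotopomer samples hit the programmed fluxes exactly", {
  tr <- ground_truth(flux_targets = c(mr_glu = 0.3476, mr_gaba = 0.117,
                                      mr_total = 0.585), seed = 1)
  s <- gen_isotopomer_dataset(tr, noise_cv = 0)[[1]]
  expect_equal(mr_glu(s), 0.3476, tolerance = 1e-10)
  expect_equal(mr_gaba(s), 0.117, tolerance = 1e-10)
  expect_equal(mr_total(s), 0.585, tolerance = 1e-10)
})

test_that("zero flux targets give all-zero enrichments and zero rates", {
  tr <- ground_truth(flux_targets = c(mr_glu = 0, mr_gaba = 0, mr_total = 0))
  s <- gen_isotopomer_dataset(tr, noise_cv = 0.1)[[1]]
  expect_true(all(s$enrich == 0))
  expect_equal(mr_total(s), 0)
})

test_that("degenerate isotopomer requests are rejected", {
  tr <- truth_default()
  zero_template <- c(glu_c4 = 0, glu_c3 = 0, gaba_c2 = 1, gaba_c4 = 1,
                     asp_c3 = 0, gln_c4 = 1)
  expect_error(gen_isotopomer_dataset(tr, template = zero_template),
               "all-zero")
  expect_error(ground_truth(flux_targets = c(mr_glu = -0.1, mr_gaba = 0.1,
                                             mr_total = 0.2)),
               "nonnegative")
  # targets demanding negative GABA enrichment are impossible
  expect_error(gen_isotopomer_dataset(
    ground_truth(flux_targets = c(mr_glu = 0.5, mr_gaba = 0.001,
                                  mr_total = 0.9))),
    "incompatible")
})

test_that("flux recovery under multiplicative noise is unbiased", {
  tr <- ground_truth(flux_targets = c(mr_glu = 0.3, mr_gaba = 0.12,
                                      mr_total = 0.55), seed = 9)
  samples <- gen_isotopomer_dataset(tr, noise_cv = 0.05, n = 100)
  vals <- vapply(samples, mr_glu, numeric(1))
  sem <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.3), 2 * sem)
})

test_that("sweep generator obeys Ohm's law and returns its spikes", {
  tr <- ground_truth(cell_params = list(r_n = 310, sag = 0), seed = 3)
  ss <- gen_step_sweeps(tr, noise_sd = 0)
  j <- which(ss$currents == -100)
  v_ss <- mean(ss$voltage[ss$time >= ss$offset - 0.1 & ss$time < ss$offset, j])
  expect_equal(v_ss - tr$cell_params$rmp, -31, tolerance = 1e-3)

  sup <- which(ss$currents == 180)
  expect_gt(length(ss$spike_times[[sup]]), 1)
  det <- detect_spikes(ss, 180)
  expect_equal(length(det), length(ss$spike_times[[sup]]))
  # detected time is the 0 mV crossing, partway up the 0.5 ms rise
  expect_lt(max(abs(det - ss$spike_times[[sup]])), 0.0006)
})

test_that("sweep generator rejects invalid requests", {
  tr <- truth_default()
  expect_error(gen_step_sweeps(tr, fs = 5000), "10 kHz")
  expect_error(gen_step_sweeps(tr, noise_sd = -1), "nonnegative")
  expect_error(step_protocol(step_dur = 0), "positive")
})

test_that("event count and tail mass follow their programmed laws", {
  tr <- ground_truth(seed = 5)
  g <- gen_psc_trace(tr, duration = 150, fs = 10000, noise_sd = 0)
  # Poisson count: 300 expected, allow 4 sd
  expect_lt(abs(nrow(g$events) - 300), 4 * sqrt(300))
  # binomial check of the 5% tail mass at n = 5000
  amps <- gen_event_amplitudes(tr, 5000)
  frac <- mean(amps > tr$event_params$tail_cutoff)
  ci <- qbinom(c(0.025, 0.975), 5000, 0.05) / 5000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("psc generator validates kernel and sampling", {
  tr <- ground_truth(event_params = list(rise = 6, decay = 3))
  expect_error(gen_psc_trace(tr, duration = 150), "decay")
  tr2 <- ground_truth()
  expect_error(gen_psc_trace(tr2, duration = 150, fs = 2000), "resolve")
  expect_warning(gen_psc_trace(tr2, duration = 10), "200")
})

test_that("startle trials encode the programmed attenuation", {
  tr <- ground_truth(seed = 11)
  exact <- gen_startle_trials(tr, cv = 0)
  res <- ppi_percent(exact)
  expect_equal(res$ppi[res$level == "prepulse_+16dB"], 60)
  expect_equal(res$ppi[res$level == "prepulse_+4dB"], 20)
  none <- ground_truth(ppi_params = list(attenuation = c(`8` = 0)), seed = 1)
  expect_equal(ppi_percent(gen_startle_trials(none, cv = 0))$ppi, 0)
  expect_error(ground_truth(ppi_params = list(basal = -3)), "nonnegative")
})

test_that("tracks stay inside their arena and respect avoidance limits", {
  tr <- ground_truth(seed = 21)
  arena <- open_field_arena()
  trk <- gen_track(tr, arena, duration = 60)
  expect_true(all(in_arena(arena, trk$x, trk$y)))
  expect_equal(nrow(trk), 60 * 25 + 1)

  # clamped infinite avoidance: never enters the center
  avoid <- ground_truth(track_params = list(avoid = Inf), seed = 22)
  trk2 <- gen_track(avoid, arena, duration = 60)
  expect_equal(oft_metrics(trk2)$pct_time_in_zone, 0)

  # plus-maze walks honor the non-convex geometry
  ep <- epm_arena()
  trk3 <- gen_track(tr, ep, duration = 30)
  expect_true(all(in_arena(ep, trk3$x, trk3$y)))
})

test_that("qPCR tables return programmed fold changes exactly at zero noise", {
  tr <- ground_truth(qpcr_params = list(
    log2_fc = c(Gapdh = 0, g1 = 1, g2 = 0, g3 = -1),
    subject_sd = 0.4), seed = 31)
  ct <- gen_qpcr(tr, ct_sd = 0)
  res <- ddct_fold_change(ct)
  expect_equal(res$fold_change[res$gene == "g1"], 2, tolerance = 1e-12)
  expect_equal(res$fold_change[res$gene == "g2"], 1, tolerance = 1e-12)
  expect_equal(res$fold_change[res$gene == "g3"], 0.5, tolerance = 1e-12)
  expect_error(gen_qpcr(tr, genes = c("g1", "g2")), "housekeeping")
})
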