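#' Ground-truth parameter set for the synthetic-data generators
#'
#' Bundles every programmable parameter the synthetic generators consume, so a
#' single object (plus one seed) pins down all generated datasets
#' bit-identically. Defaults describe a typical adult CA1 pyramidal recording
#' configuration and desk-scale versions of the assay designs the package
#' analyzes.
#'
#' @param flux_targets named numeric vector with `mr_glu`, `mr_gaba`,
#'   `mr_total`: target glucose-oxidation rates (µmol g⁻¹ min⁻¹) the
#'   isotopomer generator must reproduce. All nonnegative, and
#'   `mr_total >= mr_glu + mr_gaba` must be achievable.
#' @param cell_params list overriding any of: `rmp` (mV), `r_n` (MΩ), `tau`
#'   (ms), `sag` (mV, peak-minus-steady-state magnitude on hyperpolarizing
#'   steps), `tau_slow` (ms, sag relaxation), `accommodation` (geometric
#'   inter-spike-interval growth ratio, >= 1), `v_thresh` (mV), `i_rheo` (pA),
#'   `gain` (Hz/pA above rheobase).
#' @param event_params list overriding any of: `rate` (Hz), `amp_meanlog`,
#'   `amp_sdlog` (log-normal body of the amplitude distribution, pA),
#'   `tail_frac` (mixture weight of the heavy tail, in \[0,1\]), `tail_cutoff`
#'   (pA), `tail_scale` (pA, exponential excess above the cutoff), `rise`,
#'   `decay` (ms, difference-of-exponentials kernel).
#' @param ppi_params list overriding `basal` (arbitrary load-cell units) and
#'   `attenuation`, a named vector of per-prepulse-level startle attenuation
#'   fractions in \[0,1\] (names are prepulse intensities above background, dB).
#' @param track_params list overriding `step` (cm, Weibull scale of per-frame
#'   step length), `persistence` (heading correlation in \[0,1\]), `avoid`
#'   (nonnegative weight biasing steps away from the arena's anxiogenic zone;
#'   internally clamped at 50).
#' @param qpcr_params list overriding `log2_fc` (named per-gene log2 fold
#'   changes, housekeeping gene must be 0), `housekeeping` (gene name),
#'   `ct_sd` (cycles), `subject_sd` (cycles, per-subject loading offset).
#' @param seed integer; expanded into fixed per-generator substreams.
#'
#' @return An object of class `ground_truth`.
#' @examples
#' truth <- ground_truth(seed = 42)
#' truth$cell_params$r_n
#' @export
ground_truth <- function(flux_targets = c(mr_glu = 0.35, mr_gaba = 0.12,
                                          mr_total = 0.59),
                         cell_params = list(),
                         event_params = list(),
                         ppi_params = list(),
                         track_params = list(),
                         qpcr_params = list(),
                         seed = 1L) {
  cp <- utils::modifyList(list(
    rmp = -62, r_n = 195, tau = 19, sag = 4.3, tau_slow = 100,
    accommodation = 1.3, v_thresh = -45, i_rheo = 40, gain = 0.08
  ), cell_params)
  ep <- utils::modifyList(list(
    rate = 2, amp_meanlog = log(30), amp_sdlog = 0.35,
    tail_frac = 0.05, tail_cutoff = 100, tail_scale = 50,
    rise = 1, decay = 6
  ), event_params)
  pp <- utils::modifyList(list(
    basal = 10, attenuation = c(`4` = 0.2, `8` = 0.4, `16` = 0.6)
  ), ppi_params)
  tp <- utils::modifyList(list(
    step = 0.3, persistence = 0.9, avoid = 0
  ), track_params)
  qp <- utils::modifyList(list(
    log2_fc = c(Gapdh = 0, Bdnf = 0.5, Homer1 = 0, Gria1 = -0.3),
    housekeeping = "Gapdh", ct_sd = 0.2, subject_sd = 0.3
  ), qpcr_params)

  ft <- flux_targets
  if (!all(c("mr_glu", "mr_gaba", "mr_total") %in% names(ft))) {
    stop("`flux_targets` needs named entries mr_glu, mr_gaba, mr_total",
         call. = FALSE)
  }
  if (any(!is.finite(ft)) || any(ft < 0)) {
    stop("flux targets must be finite and nonnegative", call. = FALSE)
  }

  for (nm in c("r_n", "tau", "tau_slow", "gain")) {
    stop_if_not_scalar_pos(cp[[nm]], paste0("cell_params$", nm))
  }
  stop_if_not_scalar_pos(cp$sag, "cell_params$sag", strict = FALSE)
  if (cp$accommodation < 1) {
    stop("`accommodation` (ISI growth ratio) must be >= 1", call. = FALSE)
  }
  for (nm in c("rate", "tail_cutoff", "tail_scale", "rise", "decay")) {
    stop_if_not_scalar_pos(ep[[nm]], paste0("event_params$", nm))
  }
  if (ep$tail_frac < 0 || ep$tail_frac > 1) {
    stop("`tail_frac` must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_pos(pp$basal, "ppi_params$basal", strict = FALSE)
  if (any(pp$attenuation < 0) || any(pp$attenuation > 1)) {
    stop("attenuation fractions must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_pos(tp$step, "track_params$step")
  if (tp$persistence < 0 || tp$persistence > 1) {
    stop("`persistence` must lie in [0, 1]", call. = FALSE)
  }
  if (tp$avoid < 0) stop("`avoid` must be nonnegative", call. = FALSE)
  if (!qp$housekeeping %in% names(qp$log2_fc)) {
    stop("housekeeping gene must appear in `log2_fc`", call. = FALSE)
  }
  if (qp$log2_fc[[qp$housekeeping]] != 0) {
    stop("housekeeping gene must have zero programmed fold change",
         call. = FALSE)
  }
  stop_if_not_scalar_pos(qp$ct_sd, "qpcr_params$ct_sd", strict = FALSE)

  structure(list(
    flux_targets = ft, cell_params = cp, event_params = ep,
    ppi_params = pp, track_params = tp, qpcr_params = qp,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> seed", x$seed, "\n")
  cat("  flux targets (umol/g/min):",
      paste(sprintf("%s=%.3g", names(x$flux_targets), x$flux_targets),
            collapse = ", "), "\n")
  cat(sprintf("  cell: RMP %.3g mV, R_N %.3g MOhm, tau %.3g ms, sag %.3g mV\n",
              x$cell_params$rmp, x$cell_params$r_n, x$cell_params$tau,
              x$cell_params$sag))
  cat(sprintf("  events: %.3g Hz, tail %.2g above %.3g pA\n",
              x$event_params$rate, x$event_params$tail_frac,
              x$event_params$tail_cutoff))
  invisible(x)
}
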