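# Intrinsic membrane properties from current-step sweeps.
#
# Window conventions (configurable, fixed defaults): baseline = the full
# pre-step segment; steady state = last 20% of the step; sag peak search =
# first 40% of the step. All measures operate on the -100 pA sweep by default,
# the trace the field standardly uses for passive properties.

.sweep_col <- function(ss, current) {
  j <- which(abs(ss$currents - current) < 1e-6)
  if (!length(j)) {
    stop(sprintf("no sweep at %g pA (protocol: %s)", current,
                 paste(ss$currents, collapse = ", ")), call. = FALSE)
  }
  j[1]
}

#' Resting membrane potential from the pre-step baseline
#'
#' @param ss a [sweep_set()].
#' @param current which sweep to read, pA (default the first sweep's current;
#'   RMP is shared across sweeps of one cell).
#' @param baseline_window `c(start, end)` in seconds; must end at or before
#'   the step onset.
#' @return Mean baseline voltage, mV.
#' @export
measure_rmp <- function(ss, current = ss$currents[1],
                        baseline_window = c(0, ss$onset)) {
  j <- .sweep_col(ss, current)
  if (baseline_window[2] > ss$onset + 1e-12) {
    stop("baseline window overlaps the current step", call. = FALSE)
  }
  idx <- ss$time >= baseline_window[1] & ss$time < baseline_window[2]
  if (!any(idx)) stop("empty baseline window", call. = FALSE)
  mean(ss$voltage[idx, j])
}

.steady_state_v <- function(ss, j, steady_frac = 0.2) {
  dur <- ss$offset - ss$onset
  idx <- ss$time >= ss$offset - steady_frac * dur & ss$time < ss$offset
  mean(ss$voltage[idx, j])
}

#' Input resistance by Ohm's law
#'
#' `R_N = (V_ss - RMP) / I`, from the steady-state deflection of the
#' hyperpolarizing test sweep, reported positive in MΩ.
#'
#' @param ss a [sweep_set()].
#' @param current test current, pA (default -100).
#' @param steady_frac fraction of the step, at its end, averaged for the
#'   steady state (default 0.2).
#' @return Input resistance, MΩ.
#' @export
input_resistance <- function(ss, current = -100, steady_frac = 0.2) {
  if (current == 0) stop("test current must be nonzero", call. = FALSE)
  j <- .sweep_col(ss, current)
  rmp <- measure_rmp(ss, current)
  v_ss <- .steady_state_v(ss, j, steady_frac)
  abs((v_ss - rmp) / current) * 1000              # mV/pA -> MOhm
}

#' Membrane time constant from a single-exponential fit
#'
#' Fits `V(t) = V_inf + A * exp(-t/tau)` to the charging transient of the
#' test sweep (step onset to steady state) by nonlinear least squares, with
#' the initial tau taken from the 63% crossing time.
#'
#' @param ss a [sweep_set()].
#' @param current test current, pA (default -100).
#' @param window optional `c(start, end)` in seconds relative to step onset
#'   restricting the fit; default the whole step.
#' @return Fitted tau, ms.
#' @export
fit_tau <- function(ss, current = -100, window = NULL) {
  j <- .sweep_col(ss, current)
  dur <- ss$offset - ss$onset
  if (is.null(window)) window <- c(0, dur)
  idx <- ss$time >= ss$onset + window[1] & ss$time < ss$onset + window[2]
  tt <- ss$time[idx] - ss$onset
  vv <- ss$voltage[idx, j]
  v_ss <- .steady_state_v(ss, j)
  v0 <- vv[1]
  if (abs(v0 - v_ss) < 0.5) {
    stop("no charging transient in this sweep (flat trace)", call. = FALSE)
  }
  cross <- which(abs(vv - v0) >= 0.632 * abs(v_ss - v0))[1]
  if (is.na(cross)) stop("transient never reaches 63% of its asymptote",
                         call. = FALSE)
  tau0 <- max(tt[cross], 2 / ss$fs)
  fit <- tryCatch(
    minpack.lm::nlsLM(vv ~ vinf + A * exp(-tt / tau),
                      start = list(vinf = v_ss, A = v0 - v_ss, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("single-exponential fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  unname(stats::coef(fit)[["tau"]]) * 1000
}

#' Sag voltage and sag percent of a hyperpolarizing step
#'
#' Sag voltage is the peak negative-going voltage minus the steady-state
#' voltage (so it is <= 0); sag percent is its magnitude relative to the peak
#' deflection from rest.
#'
#' @param ss a [sweep_set()].
#' @param current hyperpolarizing test current, pA (must be < 0).
#' @param peak_frac fraction of the step, from its onset, searched for the
#'   negative peak (default 0.4).
#' @param steady_frac steady-state averaging fraction (default 0.2).
#' @return List with `sag_voltage` (mV, <= 0) and `sag_percent`.
#' @export
sag_measures <- function(ss, current = -100, peak_frac = 0.4,
                         steady_frac = 0.2) {
  if (current >= 0) {
    stop("sag is defined on hyperpolarizing steps (current < 0)",
         call. = FALSE)
  }
  j <- .sweep_col(ss, current)
  dur <- ss$offset - ss$onset
  idx_pk <- ss$time >= ss$onset & ss$time < ss$onset + peak_frac * dur
  v_peak <- min(ss$voltage[idx_pk, j])
  v_ss <- .steady_state_v(ss, j, steady_frac)
  sag_v <- min(v_peak - v_ss, 0)
  rmp <- measure_rmp(ss, current)
  denom <- abs(v_peak - rmp)
  sag_pct <- if (denom < 1e-9) 0 else 100 * abs(sag_v) / denom
  list(sag_voltage = sag_v, sag_percent = sag_pct)
}

#' Detect spikes as refractory-gated upward threshold crossings
#'
#' @param ss a [sweep_set()] (or a numeric voltage vector, with `time`
#'   supplied).
#' @param current which sweep, pA (ignored for vector input).
#' @param threshold crossing threshold, mV (default 0; must sit above RMP).
#' @param refractory_ms minimum separation between spikes, ms.
#' @param time time base for vector input, seconds.
#' @return Spike times, seconds.
#' @export
detect_spikes <- function(ss, current = NULL, threshold = 0,
                          refractory_ms = 2, time = NULL) {
  if (inherits(ss, "sweep_set")) {
    if (is.null(current)) stop("specify the sweep `current`", call. = FALSE)
    v <- ss$voltage[, .sweep_col(ss, current)]
    time <- ss$time
  } else {
    v <- as.numeric(ss)
    if (is.null(time)) stop("vector input needs a `time` base", call. = FALSE)
  }
  if (refractory_ms <= 0) stop("`refractory_ms` must be positive", call. = FALSE)
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (!length(up)) return(numeric(0))
  times <- time[up + 1]
  keep <- times[1]
  for (tm in times[-1]) {
    if (tm - keep[length(keep)] >= refractory_ms / 1000) keep <- c(keep, tm)
  }
  keep
}

#' Spike-frequency accommodation index
#'
#' Ratio of the maximum inter-spike interval -- including the interval from
#' the last spike to the end of the current injection -- to the first
#' inter-spike interval. By this definition the index is always >= 1 for
#' trains with growing intervals; it is scale-invariant under uniform time
#' dilation.
#'
#' @param spike_times spike times within the step, seconds (>= 2 required).
#' @param step_end end of the current injection, seconds (>= last spike).
#' @return The index (dimensionless), or `NA_real_` when fewer than two
#'   spikes make it undefined (reported missing, never zero).
#' @examples
#' accommodation_index(c(0, 0.010, 0.030, 0.070), step_end = 0.120)  # 5
#' @export
accommodation_index <- function(spike_times, step_end) {
  if (length(spike_times) < 2) return(NA_real_)
  spike_times <- sort(spike_times)
  if (step_end < spike_times[length(spike_times)]) {
    stop("`step_end` precedes the last spike", call. = FALSE)
  }
  isis <- diff(spike_times)
  max(c(isis, step_end - spike_times[length(spike_times)])) / isis[1]
}

#' Input-output curve: spike count per injected current
#'
#' @param ss a [sweep_set()].
#' @param threshold,refractory_ms passed to [detect_spikes()].
#' @return data.frame with `current` (pA) and `n_spikes`, counting spikes
#'   inside the step window only.
#' @export
io_curve <- function(ss, threshold = 0, refractory_ms = 2) {
  counts <- vapply(ss$currents, function(I) {
    st <- detect_spikes(ss, I, threshold, refractory_ms)
    sum(st >= ss$onset & st <= ss$offset)
  }, numeric(1))
  data.frame(current = ss$currents, n_spikes = counts)
}

#' Compare input-output curves between groups by linear regression + ANCOVA
#'
#' Fits spike count against injected current with a group term, testing the
#' slope difference first (current x group interaction); if the slopes do not
#' differ at `alpha`, the intercept (group main effect) is tested in the
#' additive model.
#'
#' @param io long data.frame with columns `cell`, `group`, `current`,
#'   `n_spikes`; exactly two groups, each with >= 2 cells, sharing >= 2
#'   current levels.
#' @param alpha slope-equality decision level (default 0.05).
#' @return List: `slope_F`, `slope_p`, `intercept_F`, `intercept_p`
#'   (intercept entries `NA` when slopes differ), `currents`, `n_cells`.
#' @export
compare_io <- function(io, alpha = 0.05) {
  need <- c("cell", "group", "current", "n_spikes")
  if (!all(need %in% names(io))) {
    stop("`io` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  io$group <- factor(io$group)
  if (nlevels(io$group) != 2) stop("exactly two groups required", call. = FALSE)
  grids <- tapply(io$current, io$group, unique, simplify = FALSE)
  shared <- sort(Reduce(intersect, grids))
  if (length(shared) < 2) {
    stop("groups must share at least two current levels", call. = FALSE)
  }
  io <- io[io$current %in% shared, ]
  n_cells <- tapply(io$cell, io$group, function(x) length(unique(x)))
  if (any(n_cells < 2)) stop("each group needs >= 2 cells", call. = FALSE)

  full <- stats::lm(n_spikes ~ current * group, data = io)
  av <- stats::anova(full)
  slope_F <- av["current:group", "F value"]
  slope_p <- av["current:group", "Pr(>F)"]
  if (is.finite(slope_p) && slope_p < alpha) {
    int_F <- NA_real_; int_p <- NA_real_
  } else {
    add <- stats::lm(n_spikes ~ current + group, data = io)
    av2 <- stats::anova(add)
    int_F <- av2["group", "F value"]
    int_p <- av2["group", "Pr(>F)"]
  }
  list(slope_F = unname(slope_F), slope_p = unname(slope_p),
       intercept_F = unname(int_F), intercept_p = unname(int_p),
       currents = shared, n_cells = as.vector(n_cells))
}
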