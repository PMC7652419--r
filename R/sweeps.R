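# Current-step protocols and synthetic voltage sweeps.

#' Current-step protocol description
#'
#' @param currents injected currents in pA, one per sweep. The default spans
#'   the standard stepped protocol from -100 pA to 180 pA.
#' @param step_dur step duration in seconds (default 0.5).
#' @param pre,post baseline before and settle time after the step, seconds.
#' @return List of class `step_protocol`.
#' @export
step_protocol <- function(currents = seq(-100, 180, by = 40),
                          step_dur = 0.5, pre = 0.2, post = 0.3) {
  stop_if_not_scalar_pos(step_dur, "step_dur")
  stop_if_not_scalar_pos(pre, "pre")
  stop_if_not_scalar_pos(post, "post")
  if (!length(currents)) stop("protocol needs at least one current",
                              call. = FALSE)
  structure(list(currents = currents, step_dur = step_dur,
                 pre = pre, post = post),
            class = "step_protocol")
}

#' Assemble a sweep set
#'
#' @param time shared time base, seconds, uniformly sampled.
#' @param voltage matrix (time x sweeps) of membrane potential, mV.
#' @param currents per-sweep injected current, pA.
#' @param fs sampling rate, Hz.
#' @param onset,offset step window, seconds (strictly inside the sweep).
#' @param spike_times optional list of per-sweep ground-truth spike times, s.
#' @return Object of class `sweep_set`.
#' @export
sweep_set <- function(time, voltage, currents, fs, onset, offset,
                      spike_times = NULL) {
  voltage <- as.matrix(voltage)
  if (nrow(voltage) != length(time)) {
    stop("`voltage` must have one row per time sample", call. = FALSE)
  }
  if (ncol(voltage) != length(currents)) {
    stop("`voltage` must have one column per sweep current", call. = FALSE)
  }
  if (onset <= time[1] || offset >= time[length(time)] || offset <= onset) {
    stop("step window must lie strictly inside the sweep", call. = FALSE)
  }
  structure(list(time = time, voltage = voltage, currents = currents,
                 fs = fs, onset = onset, offset = offset,
                 spike_times = spike_times),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples at %g kHz\n",
              ncol(x$voltage), nrow(x$voltage), x$fs / 1000))
  cat("  currents (pA):", paste(x$currents, collapse = ", "), "\n")
  cat(sprintf("  step window: %.3f-%.3f s\n", x$onset, x$offset))
  invisible(x)
}

# Split the hyperpolarizing deflection between the fast RC charge and an
# opposing slow exponential, calibrated against the analysis conventions so
# that (i) the mean over the last 20% of the step (the steady-state window)
# equals I*R_N exactly and (ii) that mean minus the transient peak equals the
# programmed sag. Returns the deflection time course over the step.
.calibrated_sag_deflection <- function(D, sag, tau_s, tau_slow_s, tt) {
  shape <- function(Dp, a) {
    (Dp - a) * (1 - exp(-tt / tau_s)) + a * (1 - exp(-tt / tau_slow_s))
  }
  if (sag <= 0) return(D * (1 - exp(-tt / tau_s)))
  steady <- tt >= 0.8 * max(tt)
  Dp <- D
  a <- 0
  for (iter in 1:8) {
    overshoot <- function(a) {
      d <- shape(Dp, a)
      (mean(d[steady]) - min(d)) - sag
    }
    upper <- sag * 2
    while (overshoot(upper) < 0 && upper < sag * 1024) upper <- upper * 2
    if (overshoot(upper) < 0) {
      stop("requested sag amplitude is unreachable for this step",
           call. = FALSE)
    }
    a <- stats::uniroot(overshoot, c(0, upper), tol = 1e-12)$root
    d <- shape(Dp, a)
    err <- D - mean(d[steady])
    if (abs(err) < 1e-12) break
    Dp <- Dp + err
  }
  shape(Dp, a)
}

# Geometric inter-spike-interval train for a given current; returns spike
# times relative to step onset (seconds).
.geometric_spike_train <- function(current, cp, step_dur) {
  if (current <= cp$i_rheo) return(numeric(0))
  f <- cp$gain * (current - cp$i_rheo)            # Hz
  isi1 <- 1 / f
  times <- c()
  t <- isi1
  k <- 0
  while (t < step_dur - 0.002 && k < 1000) {
    times <- c(times, t)
    k <- k + 1
    t <- t + isi1 * cp$accommodation^k
  }
  times
}

#' Generate voltage sweeps under a stepped current protocol
#'
#' Subthreshold responses follow `RMP + I*R_N*(1 - exp(-t/tau))`;
#' hyperpolarizing steps additionally carry an opposing slow-exponential sag
#' calibrated so the steady-state deflection still equals `I*R_N` and the peak
#' overshoots it by the programmed sag amplitude. Suprathreshold sweeps carry
#' threshold-and-reset spikes whose inter-spike intervals grow geometrically by
#' the accommodation ratio; ground-truth spike times are returned alongside.
#'
#' @param truth a [ground_truth()] (uses `cell_params` and `seed`).
#' @param protocol a [step_protocol()].
#' @param fs sampling rate, Hz (>= 10 kHz).
#' @param noise_sd Gaussian voltage noise SD, mV (>= 0).
#' @param seed RNG seed; defaults to the truth's sweep substream.
#' @return A [sweep_set()] with `spike_times` filled in.
#' @export
gen_step_sweeps <- function(truth, protocol = step_protocol(), fs = 20000,
                            noise_sd = 0, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(protocol, "step_protocol"))
  if (fs < 10000) stop("`fs` must be at least 10 kHz", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  cp <- truth$cell_params
  total <- protocol$pre + protocol$step_dur + protocol$post
  n <- floor(total * fs)
  t <- (seq_len(n) - 1) / fs
  onset <- protocol$pre
  offset <- protocol$pre + protocol$step_dur
  in_step <- t >= onset & t < offset
  post_step <- t >= offset
  tt <- t[in_step] - onset
  tau_s <- cp$tau / 1000
  tau_slow_s <- cp$tau_slow / 1000

  if (is.null(seed)) seed <- substream_seed(truth, "sweeps")
  v <- matrix(cp$rmp, nrow = n, ncol = length(protocol$currents))
  spikes <- vector("list", length(protocol$currents))
  for (j in seq_along(protocol$currents)) {
    I <- protocol$currents[j]
    D <- I * cp$r_n * 1e-3                          # pA x MOhm -> mV
    st <- .geometric_spike_train(I, cp, protocol$step_dur)
    if (!length(st)) {
      if (I < 0 && cp$sag > 0) {
        defl <- .calibrated_sag_deflection(D, cp$sag, tau_s, tau_slow_s, tt)
      } else {
        defl <- D * (1 - exp(-tt / tau_s))
      }
      v[in_step, j] <- cp$rmp + defl
      v_end <- cp$rmp + defl[length(defl)]
    } else {
      # depolarizing plateau clipped at threshold, spikes painted on top
      defl <- pmin(D * (1 - exp(-tt / tau_s)), cp$v_thresh - cp$rmp)
      vj <- cp$rmp + defl
      idx_rise <- round(0.0005 * fs)                # 0.5 ms up
      idx_fall <- round(0.0010 * fs)                # 1.0 ms down
      for (s_rel in st) {
        i0 <- which.min(abs(tt - s_rel))
        up <- i0:min(i0 + idx_rise, length(vj))
        vj[up] <- seq(vj[i0], 30, length.out = length(up))
        dn <- (i0 + idx_rise):min(i0 + idx_rise + idx_fall, length(vj))
        vj[dn] <- seq(30, cp$v_thresh - 5, length.out = length(dn))
      }
      v[in_step, j] <- vj
      v_end <- vj[length(vj)]
      spikes[[j]] <- onset + st
    }
    tp <- t[post_step] - offset
    v[post_step, j] <- cp$rmp + (v_end - cp$rmp) * exp(-tp / tau_s)
  }
  if (noise_sd > 0) {
    v <- v + with_seed(seed, matrix(stats::rnorm(length(v), 0, noise_sd),
                                    nrow = n))
  }
  sweep_set(t, v, protocol$currents, fs, onset, offset, spikes)
}
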