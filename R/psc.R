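# Synthetic postsynaptic-current traces: a Poisson event train convolved with
# a difference-of-exponentials kernel plus Gaussian noise, with an optional
# heavy-tail amplitude component and compound (burst) events.

#' Unit-peak difference-of-exponentials synaptic kernel
#'
#' `k(t) = exp(-t/decay) - exp(-t/rise)`, normalized so its peak equals 1.
#'
#' @param t_s times from event onset, seconds (values < 0 return 0).
#' @param rise,decay kernel time constants, ms; `decay > rise > 0`.
#' @return Kernel values.
#' @export
psc_kernel <- function(t_s, rise = 1, decay = 6) {
  stop_if_not_scalar_pos(rise, "rise")
  if (decay <= rise) stop("kernel `decay` must exceed `rise`", call. = FALSE)
  tr <- rise / 1000; td <- decay / 1000
  tp <- log(td / tr) * tr * td / (td - tr)        # time to peak
  norm <- exp(-tp / td) - exp(-tp / tr)
  k <- ifelse(t_s < 0, 0, exp(-t_s / td) - exp(-t_s / tr))
  k / norm
}

#' Compose a current trace from event onsets and amplitudes
#'
#' Places one unit-peak kernel per event, scaled to its amplitude, and adds
#' Gaussian noise. Inward events are rendered as negative deflections
#' (`polarity = -1`, the convention at -70 mV holding).
#'
#' @param onsets event onset times, seconds.
#' @param amplitudes event peak amplitudes, pA (magnitudes, > 0).
#' @param duration trace duration, seconds.
#' @param fs sampling rate, Hz; must resolve the kernel rise with >= 5
#'   samples.
#' @param rise,decay kernel time constants, ms.
#' @param noise_sd Gaussian noise SD, pA.
#' @param polarity -1 (inward, default) or +1.
#' @param seed optional RNG seed for the noise.
#' @return Object of class `psc_trace`: list with `current` (pA), `fs`,
#'   `duration`, `polarity`.
#' @export
compose_psc_trace <- function(onsets, amplitudes, duration, fs,
                              rise = 1, decay = 6, noise_sd = 0,
                              polarity = -1, seed = NULL) {
  if (decay <= rise) stop("kernel `decay` must exceed `rise`", call. = FALSE)
  if (fs * rise / 1000 < 5) {
    stop("`fs` too low to resolve the kernel rise (< 5 samples per rise time)",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (length(onsets) != length(amplitudes)) {
    stop("`onsets` and `amplitudes` must have equal length", call. = FALSE)
  }
  n <- floor(duration * fs)
  sig <- numeric(n)
  klen <- ceiling(fs * 8 * decay / 1000)
  kt <- (0:(klen - 1)) / fs
  k <- psc_kernel(kt, rise, decay)
  for (i in seq_along(onsets)) {
    i0 <- floor(onsets[i] * fs) + 1
    if (i0 > n) next
    i1 <- min(i0 + klen - 1, n)
    sig[i0:i1] <- sig[i0:i1] + amplitudes[i] * k[seq_len(i1 - i0 + 1)]
  }
  cur <- polarity * sig
  if (noise_sd > 0) {
    cur <- cur + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  structure(list(current = cur, fs = fs, duration = duration,
                 polarity = polarity),
            class = "psc_trace")
}

#' @export
print.psc_trace <- function(x, ...) {
  cat(sprintf("<psc_trace> %.3g s at %g kHz, polarity %+d\n",
              x$duration, x$fs / 1000, x$polarity))
  invisible(x)
}

#' Draw event amplitudes from the two-component mixture
#'
#' Body: log-normal; with probability `tail_frac` the amplitude is instead
#' drawn from the heavy tail, `tail_cutoff` plus an exponential excess of
#' scale `tail_scale`. Caller seeds the RNG.
#'
#' @param truth a [ground_truth()].
#' @param n number of amplitudes.
#' @param seed optional seed (default: the truth's PSC substream).
#' @return Numeric amplitudes, pA.
#' @export
gen_event_amplitudes <- function(truth, n, seed = NULL) {
  ep <- truth$event_params
  if (is.null(seed)) seed <- substream_seed(truth, "psc")
  with_seed(seed, .sample_amplitudes(ep, n))
}

# mixture draw on the current RNG stream (no reseeding)
.sample_amplitudes <- function(ep, n) {
  tail <- stats::runif(n) < ep$tail_frac
  a <- stats::rlnorm(n, ep$amp_meanlog, ep$amp_sdlog)
  a[tail] <- ep$tail_cutoff + stats::rexp(sum(tail), rate = 1 / ep$tail_scale)
  a
}

#' Generate a spontaneous-PSC trace with ground-truth events
#'
#' Event count is Poisson with mean `rate * duration`; onsets are uniform;
#' amplitudes come from [gen_event_amplitudes()]'s mixture. With probability
#' `compound_prob` an event becomes a compound burst (2-4 sub-events within
#' ~15 ms) recorded in the ground truth as a single event at the burst's
#' composite peak.
#'
#' @param truth a [ground_truth()] (uses `event_params` and `seed`).
#' @param duration trace length, seconds. A warning is issued when fewer than
#'   200 events are expected, the minimum the downstream protocol requires.
#' @param fs sampling rate, Hz.
#' @param noise_sd Gaussian noise SD, pA.
#' @param compound_prob probability an event is a compound burst.
#' @param seed RNG seed (default: the truth's PSC substream).
#' @param cell,condition provenance labels for the ground-truth series.
#' @return List with `trace` (a `psc_trace`) and `events` (an
#'   [event_series()] of ground-truth onsets and amplitudes).
#' @export
gen_psc_trace <- function(truth, duration = 150, fs = 10000, noise_sd = 6,
                          compound_prob = 0, seed = NULL,
                          cell = "c1", condition = "sPSC") {
  stopifnot(inherits(truth, "ground_truth"))
  ep <- truth$event_params
  if (ep$decay <= ep$rise) stop("kernel `decay` must exceed `rise`",
                                call. = FALSE)
  if (fs * ep$rise / 1000 < 5) {
    stop("`fs` too low to resolve the kernel rise", call. = FALSE)
  }
  if (compound_prob < 0 || compound_prob > 1) {
    stop("`compound_prob` must lie in [0, 1]", call. = FALSE)
  }
  expected <- duration * ep$rate
  if (expected < 200) {
    warning(sprintf("only %.0f events expected; the analysis protocol ",
                    expected), "requires at least 200 per cell",
            call. = FALSE)
  }
  if (is.null(seed)) seed <- substream_seed(truth, "psc")

  gen <- with_seed(seed, {
    n_ev <- stats::rpois(1, expected)
    onsets <- sort(stats::runif(n_ev, 0.05, duration - 0.1))
    amps <- .sample_amplitudes(ep, n_ev)
    is_comp <- stats::runif(n_ev) < compound_prob
    sub_on <- as.list(onsets)
    sub_amp <- as.list(amps)
    for (i in which(is_comp)) {
      extra <- sample(1:3, 1)
      offs <- cumsum(stats::runif(extra, 0.002, 0.006))
      sub_on[[i]] <- c(onsets[i], onsets[i] + offs)
      sub_amp[[i]] <- c(amps[i], amps[i] * stats::runif(extra, 0.4, 0.9))
    }
    list(onsets = onsets, is_comp = is_comp,
         sub_on = sub_on, sub_amp = sub_amp)
  })

  all_on <- unlist(gen$sub_on)
  all_amp <- unlist(gen$sub_amp)
  trace <- compose_psc_trace(all_on, all_amp, duration, fs,
                             rise = ep$rise, decay = ep$decay,
                             noise_sd = noise_sd, polarity = -1,
                             seed = seed + 1L)

  # ground-truth amplitude of a compound event = its composite burst peak
  truth_amp <- vapply(seq_along(gen$onsets), function(i) {
    on_i <- gen$sub_on[[i]]; am_i <- gen$sub_amp[[i]]
    if (length(on_i) == 1) return(am_i)
    span <- max(on_i) - min(on_i) + 8 * ep$decay / 1000
    mini <- compose_psc_trace(on_i - min(on_i), am_i, span, fs,
                              rise = ep$rise, decay = ep$decay,
                              noise_sd = 0, polarity = 1)
    max(mini$current)
  }, numeric(1))

  events <- event_series(onset = gen$onsets, amplitude = truth_amp,
                         cell = cell, condition = condition,
                         duration = duration)
  list(trace = trace, events = events)
}
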