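# Spontaneous/miniature postsynaptic-current event detection and
# distribution comparison.

#' Detected (or ground-truth) postsynaptic-current events
#'
#' @param onset strictly increasing onset times, seconds.
#' @param amplitude event peak amplitudes, pA (magnitudes).
#' @param cell cell identifier.
#' @param condition recording condition (`sPSC`, `sEPSC`, `mEPSC`, `sIPSC`,
#'   `mIPSC`).
#' @param duration recording length, seconds.
#' @return data.frame of class `event_series` with columns `onset`,
#'   `amplitude`, `iei` (inter-event interval, ms; first entry `NA`), and
#'   attributes `cell`, `condition`, `duration`.
#' @export
event_series <- function(onset, amplitude, cell = "c1", condition = "sPSC",
                         duration = NA_real_) {
  if (length(onset) != length(amplitude)) {
    stop("`onset` and `amplitude` lengths differ", call. = FALSE)
  }
  if (length(onset) > 1 && any(diff(onset) <= 0)) {
    stop("onsets must be strictly increasing", call. = FALSE)
  }
  iei <- if (length(onset)) c(NA_real_, diff(onset) * 1000) else numeric(0)
  df <- data.frame(onset = as.numeric(onset),
                   amplitude = as.numeric(amplitude),
                   iei = iei)
  structure(df, cell = cell, condition = condition, duration = duration,
            class = c("event_series", "data.frame"))
}

#' Detect postsynaptic-current events in a holding-current trace
#'
#' Semi-automated template-correlation detector. The rectified,
#' baseline-subtracted trace is correlated with the nominal
#' difference-of-exponentials kernel; the correlation is normalized so that an
#' isolated clean event scores exactly its peak amplitude (a matched-filter
#' amplitude estimate, the noise-optimal linear detector for a known kernel).
#' Candidate onsets are local maxima of this score that dominate their
#' `min_separation` neighborhood and reach `threshold`; candidates closer
#' than `min_separation` are merged into one compound event whose amplitude
#' is the compound peak.
#'
#' @param trace a `psc_trace` from [compose_psc_trace()]/[gen_psc_trace()],
#'   or a numeric current vector (then supply `fs` and `polarity`).
#' @param threshold minimum peak amplitude over local baseline, pA. A warning
#'   is issued when it sits below ~3x the robust noise floor.
#' @param fs sampling rate, Hz (taken from the trace object when present).
#' @param rise,decay nominal event kernel time constants, ms (set smoothing
#'   and search windows).
#' @param min_separation merge window, ms.
#' @param polarity -1 for inward (negative) events, +1 for outward.
#' @param cell,condition provenance labels.
#' @return An [event_series()].
#' @export
detect_events <- function(trace, threshold, fs = NULL, rise = 1, decay = 6,
                          min_separation = 5, polarity = NULL,
                          cell = "c1", condition = "sPSC") {
  if (inherits(trace, "psc_trace")) {
    x <- trace$current
    fs <- trace$fs
    if (is.null(polarity)) polarity <- trace$polarity
  } else {
    x <- as.numeric(trace)
    if (is.null(fs)) stop("supply `fs` for a bare numeric trace", call. = FALSE)
    if (is.null(polarity)) polarity <- -1
  }
  stop_if_not_scalar_pos(threshold, "threshold")
  stop_if_not_scalar_pos(min_separation, "min_separation")
  if (decay <= rise) stop("`decay` must exceed `rise`", call. = FALSE)
  n <- length(x)
  duration <- n / fs
  empty <- event_series(numeric(0), numeric(0), cell, condition, duration)
  if (n < 10) return(empty)

  y <- polarity * x
  y <- y - stats::median(y)

  # onset-aligned normalized template correlation: for an isolated clean
  # event of amplitude A starting at sample i, score[i] = A
  klen <- min(ceiling(fs * 4 * decay / 1000), n)
  k <- psc_kernel((0:(klen - 1)) / fs, rise, decay)
  score <- rev(stats::filter(rev(y), k, method = "convolution", sides = 1))
  score <- as.numeric(score) / sum(k^2)
  score[is.na(score)] <- 0

  noise <- stats::mad(score)
  if (threshold < 3 * noise) {
    warning(sprintf(paste0("threshold %.3g pA is below 3x the matched-filter ",
                           "noise floor (%.3g pA); expect false positives"),
                    threshold, noise), call. = FALSE)
  }

  above <- which(score >= threshold)
  if (!length(above)) return(empty)
  prev <- pmax(above - 1L, 1L)
  nxt <- pmin(above + 1L, n)
  lmax <- above[score[above] >= score[prev] & score[above] >= score[nxt]]
  if (!length(lmax)) return(empty)
  hw <- max(1L, round(fs * min_separation / 2000))
  dominant <- vapply(lmax, function(i) {
    score[i] >= max(score[max(1, i - hw):min(n, i + hw)])
  }, logical(1))
  cand <- lmax[dominant]
  if (!length(cand)) return(empty)

  # merge candidates closer than min_separation into one compound event
  sep_samp <- fs * min_separation / 1000
  grp <- cumsum(c(TRUE, diff(cand) >= sep_samp))
  onset_i <- as.numeric(tapply(cand, grp, min))
  amps <- as.numeric(tapply(score[cand], grp, max))
  event_series((onset_i - 1) / fs, amps, cell, condition, duration)
}

#' Empirical cumulative distribution of event amplitudes or intervals
#'
#' Thin validated wrapper around [stats::ecdf()]: the returned step function
#' is right-continuous, nondecreasing, and reaches 1.
#'
#' @param values nonempty numeric vector.
#' @return An `ecdf` step function.
#' @export
amplitude_ecdf <- function(values) {
  if (!length(values) || any(!is.finite(values))) {
    stop("`values` must be nonempty and finite", call. = FALSE)
  }
  stats::ecdf(values)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two empirical cumulative
#' distributions; the p-value uses the asymptotic two-sample null
#' distribution (the convention for the large event counts compared here),
#' with an exact option for small samples.
#'
#' @param a,b nonempty numeric samples (e.g. amplitudes or inter-event
#'   intervals pooled per group).
#' @param exact use the exact null distribution (default FALSE).
#' @return List: `D`, `p`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (!length(a) || !length(b)) stop("empty input sample", call. = FALSE)
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(res$statistic), p = unname(res$p.value),
       n_a = length(a), n_b = length(b))
}

#' Fraction of events exceeding large-amplitude cutoffs
#'
#' @param amplitudes nonempty numeric, pA.
#' @param cutoffs amplitude cutoffs, pA (default 100 and 250).
#' @return Named numeric: percent of events strictly above each cutoff.
#' @export
tail_fraction <- function(amplitudes, cutoffs = c(100, 250)) {
  if (!length(amplitudes)) stop("`amplitudes` is empty", call. = FALSE)
  out <- vapply(cutoffs, function(co) 100 * mean(amplitudes > co), numeric(1))
  names(out) <- paste0("gt", cutoffs, "pA")
  out
}

#' Enforce the minimum-event recording protocol
#'
#' Keeps only cells contributing at least `n_min` events within a common
#' temporal bin, mirroring the rule that at least 200 events from identical
#' temporal bins enter each comparison.
#'
#' @param series_list list of [event_series()] objects (one per cell).
#' @param n_min minimum event count per cell (default 200).
#' @param bin `c(start, end)` in seconds; default spans the shortest
#'   recording. Must not exceed any recording's duration.
#' @return The retained subset (same class), with a `report` attribute
#'   (data.frame: cell, n_in_bin, retained) and a message summarizing
#'   exclusions.
#' @export
enforce_event_protocol <- function(series_list, n_min = 200, bin = NULL) {
  durations <- vapply(series_list, function(s) attr(s, "duration"), numeric(1))
  if (is.null(bin)) bin <- c(0, min(durations))
  if (any(bin[2] > durations + 1e-9)) {
    stop("bin extends beyond a recording's duration", call. = FALSE)
  }
  counts <- vapply(series_list, function(s) {
    sum(s$onset >= bin[1] & s$onset < bin[2])
  }, numeric(1))
  keep <- counts >= n_min
  report <- data.frame(
    cell = vapply(series_list, function(s) attr(s, "cell"), character(1)),
    n_in_bin = counts, retained = keep)
  if (any(!keep)) {
    message(sum(!keep), " cell(s) excluded with < ", n_min,
            " events in the common bin")
  }
  out <- series_list[keep]
  attr(out, "report") <- report
  out
}
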