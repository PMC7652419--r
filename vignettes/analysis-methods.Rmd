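---
title: "Models and methods behind neurophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurophys)
```

`neurophys` re-implements, as a tested library, the computational layer of a
developmental chemogenetics phenotyping workflow: ¹³C-NMR neurometabolic flux
estimation, whole-cell patch-clamp trace analysis, behavioral scoring, and
the matching group statistics. Because the data such studies rest on are
in-house animal recordings, the package ships a first-class synthetic-data
module that generates every input class with known ground truth; every
analysis stage is validated as a round trip against it. This vignette
explains the models, the tunable parameters, and the design decisions taken
where the underlying procedures leave choices open.

## Compartmental glucose-oxidation rates

During a brief (minutes-scale) [1,6-¹³C₂]glucose infusion, ¹³C label is
trapped at specific carbons of glutamate, GABA, aspartate and glutamine.
With `[X]` a pool concentration (µmol/g), `X_Ci` the percent ¹³C enrichment
at carbon *i*, and `Glc_C1` the percent plasma glucose-C1 enrichment, the
rates are fixed linear forms:

$$MR_{Glu} = 0.5 \cdot \tfrac{1}{10} \cdot \tfrac{1}{Glc_{C1}}
  \{0.82\,[Glu](Glu_{C4} + 2Glu_{C3}) + 0.42\,[Asp](2Asp_{C3})\}$$

$$MR_{GABA} = 0.5 \cdot \tfrac{1}{10} \cdot \tfrac{1}{Glc_{C1}}
  \{0.02\,[Glu](Glu_{C4} + 2Glu_{C3}) + [GABA](GABA_{C2} + 2GABA_{C4})
   + 0.42\,[Asp](2Asp_{C3})\}$$

$$MR_{Total} = 0.5 \cdot \tfrac{1}{10} \cdot \tfrac{1}{Glc_{C1}}
  \{[Glu](Glu_{C4} + 2Glu_{C3}) + [GABA](GABA_{C2} + 2GABA_{C4})
   + [Asp](2Asp_{C3}) + [Gln]\,Gln_{C4}\}$$

Design notes:

* The glutamine term is implemented as `[Gln] * Gln_C4`; the source notation
  brackets it ambiguously, and no alternative reading is supported silently.
* The 1/10 factor is adopted as printed; its dimensional role (infusion-time
  normalization versus unit conversion) is not derivable from the formula
  alone, so rates are reported in µmol g⁻¹ min⁻¹ on the formula's own scale.
* Enrichments enter in **percent**. A sample whose enrichments are all below
  1 triggers a fraction-scale warning rather than a hard rejection, because
  silently rescaling by 100 is the dangerous failure mode, while genuinely
  tiny enrichments remain legal.
* The 1.1% ¹³C natural abundance is subtracted from tissue enrichments
  (floored at zero) via `correct_natural_abundance()`. Plasma `Glc_C1` is
  *not* corrected by default: the satellite-area measurement already isolates
  the ¹³C-coupled signal. The helper takes an explicit `natural_abundance`
  argument so either convention is overridable.
* `conc_from_reference()` exposes a `proton_ratio` argument (default 1)
  because per-proton normalization against the [2-¹³C]glycine standard
  depends on which resonance was integrated; the assumption is visible
  rather than baked in.

For nonnegative inputs the coefficient structure guarantees
`mr_total >= mr_glu + mr_gaba` (glutamate enters the total with weight 1
versus 0.82 + 0.02, aspartate with 1 versus 0.42 + 0.42, and the glutamine
term is extra); the test suite asserts this on randomized samples.

The isotopomer generator inverts the linear forms: a nonnegative template of
relative position weights is scaled blockwise — one scale for
(`glu_c4`, `glu_c3`, `asp_c3`), one for (`gaba_c2`, `gaba_c4`), one for
`gln_c4` — so the triangular system hits the three programmed targets
exactly. Incompatible targets (those requiring negative enrichments, e.g. a
GABA rate below the glutamatergic spillover term) are rejected rather than
clipped. Multiplicative Gaussian noise is applied per position; because the
rates are linear in enrichments, noisy recovery is unbiased by construction.

## Intrinsic membrane properties

Sweeps follow the standard stepped protocol (500 ms steps, −100 to +180 pA)
at ≥ 10 kHz. Analysis windows are fixed, configurable defaults chosen once:
baseline = the full pre-step segment; steady state = last 20% of the step;
sag peak search = first 40% of the step.

* **Input resistance**: Ohm's law on the −100 pA sweep,
  `R_N = (V_ss − RMP)/I`, reported positive in MΩ. Adding a constant to the
  whole trace leaves it unchanged.
* **Membrane time constant**: nonlinear least-squares fit of
  `V(t) = V_∞ + A e^{−t/τ}` to the charging transient
  (`minpack.lm::nlsLM`), initial τ from the 63% crossing time. A flat trace
  is an error, not a zero.
* **Sag**: `sag_voltage = V_peak − V_ss` (≤ 0);
  `sag_percent = 100·|sag_voltage|/|V_peak − RMP|`. The percent denominator
  (peak deflection from rest, rather than steady-state deflection) is a
  documented choice; the alternative is one argument away.
* **Accommodation index**: the printed definition, max inter-spike interval
  (including last spike → step end) over the first interval. Note this
  definition yields values ≥ 1 for decelerating trains, whereas published
  tables for the same preparation report 0.32–0.48 — an apparent
  inconsistency in the source description. The package implements the
  printed formula verbatim and surfaces the discrepancy here instead of
  inverting the ratio silently. Fewer than two spikes gives `NA`, never 0.
* **Input–output comparison**: per-cell spike counts against current, linear
  regression with ANCOVA — the slope (current × group interaction) is tested
  first; intercepts are only compared when slopes are compatible at α = 0.05.

The sweep generator's subthreshold response is
`RMP + I·R_N(1 − e^{−t/τ})`; hyperpolarizing steps add an opposing slow
exponential (τ_slow default 100 ms). The fast/slow amplitude split is
calibrated numerically (fixed-point iteration around a `uniroot` solve)
against the analysis conventions themselves, so that the last-20% mean
equals `I·R_N` exactly and the peak overshoots it by exactly the programmed
sag. RMP, R_N and sag are therefore recoverable to machine precision on
noise-free sweeps. τ recovery at the 1% level is validated on sag-free
sweeps, because a single-exponential fit is only a correct model there; with
sag present the fit inherits the bias every single-exponential analysis of a
sagging neuron has, which is a property of the stated method, not of this
implementation. Suprathreshold sweeps place threshold-and-reset spikes with
first interval `1/(gain·(I − I_rheo))` and geometric interval growth by the
accommodation ratio, making the accommodation index analytic.

## Postsynaptic-current events

Traces are Poisson event trains convolved with a unit-peak
difference-of-exponentials kernel (`rise` 1 ms, `decay` 6 ms by default)
plus Gaussian noise; inward events are negative deflections at −70 mV
holding, and detection operates on the rectified polarity. Amplitudes follow
a two-component mixture: a log-normal body (meanlog `log 30` pA, sdlog
0.35) and, with probability `tail_frac` (default 0.05), a heavy tail —
`tail_cutoff` (100 pA) plus an exponential excess (scale 50 pA). The mixture
is an artifact decision: the source material describes a long-tailed
amplitude distribution without naming a family, and a cutoff-anchored tail
makes the programmed tail mass directly measurable via `tail_fraction()`.
Compound events (probability `compound_prob`) are short bursts of 2–4
sub-events recorded in the ground truth as one event at the composite peak,
matching how compound peaks are counted in practice.

The detector correlates the rectified, median-centered trace with the
nominal kernel and normalizes by the template energy, so the score at a true
onset of an isolated clean event equals its amplitude exactly (a
matched-filter estimate). Candidates are local maxima of the score that
dominate their `min_separation` (5 ms) neighborhood and reach `threshold`;
candidates closer than `min_separation` merge into one compound event at the
compound peak. An earlier candidate rule based on thresholding the smoothed
first derivative was evaluated and rejected: at the design operating point
(noise SD one-fifth of the mean amplitude) a per-sample slope threshold
cannot separate near-threshold events from noise, while the matched filter
— the noise-optimal linear detector for a known kernel — achieves recall and
precision above 0.95 with amplitude error well under 10%. A threshold below
three times the matched-filter noise floor triggers a warning. Detection is
amplitude-scale equivariant: scaling trace and threshold together scales
amplitudes and changes nothing else.

Distribution comparison follows the field's protocol: per-cell series are
gated by `enforce_event_protocol()` (≥ 200 events within a common temporal
bin), pooled amplitudes/inter-event intervals are turned into empirical
CDFs, and groups are compared with the two-sample Kolmogorov–Smirnov test
(asymptotic p, the appropriate regime for hundreds of events; exact p is an
option for small samples, and the conventional significance level for these
comparisons is p < 0.001).

## Behavioral scoring

**Startle / PPI.** `Percent PPI = 100 × (mean tone-only startle − mean
prepulse startle) / mean tone-only startle`, per prepulse level, against the
tone-only trials of the block containing the prepulse trials. Basal startle
is reported as the tone-only mean of the first block (the block structure of
the standard protocol: 10 tone-only trials, then 10 tone-only + 5 per
prepulse level); whether "basal" should instead pool all tone-only trials is
left configurable via `basal_block`. Facilitation (negative PPI) is a legal
outcome. PPI is invariant to rescaling all amplitudes.

**Trajectories.** Arenas are unions of axis-aligned rectangles: a 40 × 40 cm
open field with a 20 × 20 cm center; an elevated plus maze with 30 × 5 cm
arms whose central square belongs to neither arm class (the standard
convention); a light–dark box with 25 × 25 and 15 × 25 cm chambers. Zone
membership uses the tracked center point. An entry is an outside→inside
transition persisting ≥ 2 samples (configurable debounce, standing in for a
commercial tracker's internal rule); step distance is attributed to the zone
containing the step's destination sample. Complementary zones partition
time exactly.

The track generator is a correlated random walk: Weibull(shape 2) step
lengths (scale 0.3 cm/frame at 25 fps, i.e. ~6.6 cm/s) and wrapped-Gaussian
heading increments with SD `(1 − persistence)·π`. Persistence defaults to
0.9, giving ~0.6 s straight runs — a mouse-like gait that mixes across a
40 cm arena within about a minute; much lower persistence produces a
diffusive crawl that never reaches the arena's stationary occupancy in a
10-min session. In rectangular arenas without avoidance the free path is
folded into the box (billiard reflection), which preserves a uniform
occupancy measure exactly — this is what makes the area-fraction check
(20²/40² = 25% center time for an unbiased walk) well-posed. The release
point defaults to the protocol's (corner, closed arm, dark chamber);
`start = "random"` removes the release transient when stationary occupancy
itself is the quantity under study. Center avoidance multiplies the
acceptance probability of zone-entering steps by `exp(−avoid)` (clamped at
50, where entry probability is numerically zero). The generator does not
emulate thigmotaxis-specific wall-following, rearing/freezing bouts, or
speed–anxiety coupling; passing occupancy tests therefore validates the
geometry and bookkeeping, not a behavioral model of anxiety.

## Group statistics

* `t_test_groups()`: two-tailed unpaired t, pooled by default, Welch where a
  comparison calls for it (the source applies the Welch correction
  selectively, so the flag is per-comparison rather than global). Two
  constant, equal groups return p = 1 by convention with a note.
* `ks_normality()`: one-sample Kolmogorov–Smirnov against a normal with the
  sample's own mean/SD. Estimated parameters make the test anti-conservative
  (Lilliefors' observation); the package logs the caveat in the return value
  rather than substituting a different test, staying faithful to the stated
  procedure.
* `fdr_bky()`: the two-stage linear step-up procedure at q = 0.05 — stage 1
  runs BH at `q/(1+q)` to estimate the number of true nulls `m0`, stage 2
  re-runs BH at `q/(1+q) · m/m0`. The implementation is exercised against an
  independently coded explicit step-up loop on random p-vectors, and its
  all-null false-discovery proportion is verified ≤ q by simulation.
  Discoveries are monotone in q.
* `ddct_fold_change()`: per-subject ΔCt against the housekeeping gene,
  group aggregation by arithmetic mean of ΔCt (equivalently the geometric
  mean of relative quantities — the standard convention for this method),
  `fold = 2^{−ΔΔCt}`; per-subject relative quantities are retained for group
  t tests. Housekeeping normalization makes results invariant to adding a
  constant to every Ct of a subject.

## Numerical and scale choices

Problem sizes used by the test and acceptance suites are the package's own
desk-scale choices: 1,000 randomized samples for formula-equivalence checks,
100 samples at 5% noise for flux recovery, 50 seeds for the noisy-τ check,
one 150 s / 10 kHz trace (~300 events) for detection metrics, 2,000
replicates for K-S null calibration, 1,000 seeds for PPI Monte Carlo, 200
ten-minute tracks for occupancy, and 800–1,000 replicates for the FDR
checks. Seeds expand into fixed per-generator substreams so a single
`ground_truth(seed = )` pins every dataset bit-identically while keeping
streams independent.

Known limitations: the sweep model is phenomenological
(threshold-and-reset, not conductance-based), so spike shape and
after-depolarization are cosmetic; the τ estimator shares the
single-exponential bias of the stated method on sagging traces; compound
events merge at the matched-filter peak, which can sit below the composite
peak for strongly overlapping bursts; raw NMR spectral processing (FID
transforms, phasing) is upstream of this package, which starts from peak
areas; and trace I/O uses long-format CSV rather than a binary container.
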