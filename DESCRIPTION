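Package: neurophys
Title: Neurometabolic Flux, Patch-Clamp Trace, and Behavioral Phenotyping Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for developmental neuroscience phenotyping
    studies. Computes compartmental rates of neuronal glucose oxidation
    (glutamatergic, GABAergic, total) from 13C isotopomer enrichments and
    metabolite concentrations measured by 1H-[13C]-NMR; extracts intrinsic
    membrane properties (input resistance, membrane time constant, sag,
    accommodation index) and input-output curves from current-step voltage
    sweeps; detects spontaneous postsynaptic-current events in holding-current
    traces and compares their amplitude and inter-event-interval distributions;
    scores prepulse inhibition of the acoustic startle response and
    zone-occupancy metrics from open-field, elevated-plus-maze and light-dark
    trajectories; and provides the matching inferential toolkit (pooled and
    Welch t tests, one-sample Kolmogorov-Smirnov normality check, two-stage
    Benjamini-Krieger-Yekutieli false-discovery control, delta-delta-Ct
    fold-change estimation, input-output ANCOVA). A synthetic-data module
    generates every input class with known ground truth so the full pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
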