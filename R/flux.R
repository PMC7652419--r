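# Compartmental glucose-oxidation rates from 13C isotopomer data.
#
# During a short [1,6-13C2]glucose infusion, label is trapped at specific
# carbon positions of glutamate, GABA, aspartate and glutamine. The fraction of
# each amino-acid pool labeled at those positions, together with the pool
# concentrations and the plasma glucose-C1 enrichment, yields the rates of
# glucose oxidation attributed to glutamatergic neurons, GABAergic neurons and
# all neurons via fixed linear combinations.

.enrich_positions <- c("glu_c4", "glu_c3", "gaba_c2", "gaba_c4",
                       "asp_c3", "gln_c4")

#' Fixed constants of the compartmental glucose-oxidation model
#'
#' The prefactor 0.5 (one glucose oxidized per two labeled three-carbon
#' units), the 1/10 infusion scaling, and the compartment partition
#' coefficients: 0.82 of the glutamate pool is glutamatergic, 0.02
#' GABAergic; aspartate enters both with weight 0.42. These are model
#' constants, not tunables.
#'
#' @return Named list of the five dimensionless constants.
#' @export
flux_constants <- function() {
  list(prefactor = 0.5, infusion_scale = 1 / 10,
       glu_in_glu = 0.82, asp_coeff = 0.42, glu_in_gaba = 0.02)
}

#' Construct a per-sample isotopomer measurement
#'
#' @param conc named numeric, µmol/g wet weight; needs at least `Glu`, `GABA`,
#'   `Asp`, `Gln` for the full rate panel.
#' @param enrich named numeric, percent 13C enrichment (excess over natural
#'   abundance) at `glu_c4`, `glu_c3`, `gaba_c2`, `gaba_c4`, `asp_c3`,
#'   `gln_c4`. Values must lie in \[0, 100\].
#' @param glc_c1 percent 13C enrichment of plasma glucose C1.
#' @param tissue tissue label, e.g. `"hippocampus"` or `"cortex"`.
#' @param id subject/sample identifier.
#' @return An object of class `isotopomer_sample`.
#' @examples
#' s <- isotopomer_sample(
#'   conc = c(Glu = 13.5, GABA = 3.6, Asp = 2.3, Gln = 5.0),
#'   enrich = c(glu_c4 = 20, glu_c3 = 5, gaba_c2 = 10, gaba_c4 = 8,
#'              asp_c3 = 8, gln_c4 = 10),
#'   glc_c1 = 50)
#' mr_glu(s)
#' @export
isotopomer_sample <- function(conc, enrich, glc_c1,
                              tissue = "hippocampus", id = "s1") {
  if (is.null(names(conc)) || is.null(names(enrich))) {
    stop("`conc` and `enrich` must be named vectors", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and nonnegative", call. = FALSE)
  }
  if (any(!is.finite(enrich)) || any(enrich < 0) || any(enrich > 100)) {
    stop("enrichments must lie in [0, 100] percent", call. = FALSE)
  }
  if (any(enrich > 0) && all(enrich < 1)) {
    warning("all enrichments are below 1: values look fraction-scaled, ",
            "but the rate formulas expect percent", call. = FALSE)
  }
  structure(list(conc = conc, enrich = enrich, glc_c1 = glc_c1,
                 tissue = tissue, id = id),
            class = "isotopomer_sample")
}

#' @export
print.isotopomer_sample <- function(x, ...) {
  cat(sprintf("<isotopomer_sample> %s (%s), plasma Glc_C1 %.3g%%\n",
              x$id, x$tissue, x$glc_c1))
  cat("  conc (umol/g):",
      paste(sprintf("%s=%.3g", names(x$conc), x$conc), collapse = ", "), "\n")
  cat("  enrich (%):  ",
      paste(sprintf("%s=%.3g", names(x$enrich), x$enrich), collapse = ", "),
      "\n")
  invisible(x)
}

#' Percent 13C enrichment from peak areas
#'
#' For plasma glucose the 13C area is the summed 13C-coupled satellites and the
#' total area the full (12C + 13C) resonance; for tissue metabolites the 13C
#' area comes from the carbon-edited difference spectrum and the total from the
#' non-edited spectrum.
#'
#' @param area_13c,area_total peak areas; `0 <= area_13c <= area_total`,
#'   `area_total > 0`. Vectorized.
#' @return Percent enrichment, `100 * area_13c / area_total`.
#' @examples
#' enrichment_from_areas(20, 100)  # 20
#' @export
enrichment_from_areas <- function(area_13c, area_total) {
  if (any(!is.finite(area_total)) || any(area_total <= 0)) {
    stop("`area_total` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(area_13c)) || any(area_13c < 0)) {
    stop("`area_13c` must be nonnegative", call. = FALSE)
  }
  if (any(area_13c > area_total)) {
    stop("`area_13c` exceeds `area_total`: peak-integration error",
         call. = FALSE)
  }
  100 * area_13c / area_total
}

#' Subtract the 1.1% natural abundance of 13C
#'
#' Measured tissue enrichments include the naturally occurring 1.1% 13C;
#' the excess enrichment is the measured value minus that background,
#' floored at zero.
#'
#' @param enrichment percent, nonnegative. Vectorized.
#' @param natural_abundance percent background, default 1.1.
#' @return Corrected percent enrichment.
#' @export
correct_natural_abundance <- function(enrichment, natural_abundance = 1.1) {
  if (any(!is.finite(enrichment)) || any(enrichment < 0)) {
    stop("`enrichment` must be nonnegative", call. = FALSE)
  }
  pmax(enrichment - natural_abundance, 0)
}

#' Metabolite concentration against an internal glycine standard
#'
#' A known amount of \[2-13C\]glycine added to the tissue homogenate serves as
#' the relative concentration standard.
#'
#' @param area_met metabolite peak area (nonnegative).
#' @param area_gly glycine reference peak area (> 0).
#' @param gly_amount µmol of glycine added (default 0.2).
#' @param tissue_mass g wet weight of tissue extracted (> 0).
#' @param proton_ratio protons contributing to the metabolite resonance
#'   relative to the glycine resonance; default 1 (per-proton normalization
#'   left to the caller where resonance assignments are known).
#' @return Concentration in µmol/g:
#'   `(area_met / area_gly) * (gly_amount / tissue_mass) / proton_ratio`.
#' @export
conc_from_reference <- function(area_met, area_gly, gly_amount = 0.2,
                                tissue_mass, proton_ratio = 1) {
  stop_if_not_scalar_pos(area_gly, "area_gly")
  stop_if_not_scalar_pos(gly_amount, "gly_amount")
  stop_if_not_scalar_pos(tissue_mass, "tissue_mass")
  stop_if_not_scalar_pos(proton_ratio, "proton_ratio")
  if (any(!is.finite(area_met)) || any(area_met < 0)) {
    stop("`area_met` must be nonnegative", call. = FALSE)
  }
  (area_met / area_gly) * (gly_amount / tissue_mass) / proton_ratio
}

.flux_require <- function(s, conc_names, enrich_names) {
  if (!inherits(s, "isotopomer_sample")) {
    stop("expected an `isotopomer_sample`", call. = FALSE)
  }
  miss_c <- setdiff(conc_names, names(s$conc))
  miss_e <- setdiff(enrich_names, names(s$enrich))
  if (length(miss_c) || length(miss_e)) {
    stop("sample is missing required entries: ",
         paste(c(miss_c, miss_e), collapse = ", "), call. = FALSE)
  }
  if (!is.finite(s$glc_c1) || s$glc_c1 <= 0) {
    stop("plasma `glc_c1` must be strictly positive to compute rates",
         call. = FALSE)
  }
}

.flux_k <- function(s) {
  k <- flux_constants()
  k$prefactor * k$infusion_scale / s$glc_c1
}

#' Glucose-oxidation rate of glutamatergic neurons
#'
#' `MR_Glu = 0.5 * (1/10) * (1/Glc_C1) *
#'   {0.82 [Glu] (Glu_C4 + 2 Glu_C3) + 0.42 [Asp] (2 Asp_C3)}`
#' with concentrations in µmol/g and enrichments in percent.
#'
#' @param s an [isotopomer_sample()].
#' @return Rate in µmol g⁻¹ min⁻¹ (as-printed formula; the 1/10 factor's
#'   dimensional role is adopted from the source model, not re-derived here).
#' @export
mr_glu <- function(s) {
  .flux_require(s, c("Glu", "Asp"), c("glu_c4", "glu_c3", "asp_c3"))
  k <- flux_constants()
  e <- s$enrich
  .flux_k(s) * (k$glu_in_glu * s$conc[["Glu"]] * (e[["glu_c4"]] + 2 * e[["glu_c3"]]) +
                k$asp_coeff * s$conc[["Asp"]] * (2 * e[["asp_c3"]]))
}

#' Glucose-oxidation rate of GABAergic neurons
#'
#' `MR_GABA = 0.5 * (1/10) * (1/Glc_C1) *
#'   {0.02 [Glu] (Glu_C4 + 2 Glu_C3) + [GABA] (GABA_C2 + 2 GABA_C4)
#'    + 0.42 [Asp] (2 Asp_C3)}`
#'
#' @inheritParams mr_glu
#' @return Rate in µmol g⁻¹ min⁻¹.
#' @export
mr_gaba <- function(s) {
  .flux_require(s, c("Glu", "GABA", "Asp"),
                c("glu_c4", "glu_c3", "gaba_c2", "gaba_c4", "asp_c3"))
  k <- flux_constants()
  e <- s$enrich
  .flux_k(s) * (k$glu_in_gaba * s$conc[["Glu"]] * (e[["glu_c4"]] + 2 * e[["glu_c3"]]) +
                s$conc[["GABA"]] * (e[["gaba_c2"]] + 2 * e[["gaba_c4"]]) +
                k$asp_coeff * s$conc[["Asp"]] * (2 * e[["asp_c3"]]))
}

#' Total neuronal glucose-oxidation rate
#'
#' `MR_Total = 0.5 * (1/10) * (1/Glc_C1) *
#'   {[Glu] (Glu_C4 + 2 Glu_C3) + [GABA] (GABA_C2 + 2 GABA_C4)
#'    + [Asp] (2 Asp_C3) + [Gln] Gln_C4}`
#'
#' The glutamine term is `[Gln] * Gln_C4`. For nonnegative inputs the
#' coefficient structure guarantees `mr_total >= mr_glu + mr_gaba`.
#'
#' @inheritParams mr_glu
#' @return Rate in µmol g⁻¹ min⁻¹.
#' @export
mr_total <- function(s) {
  .flux_require(s, c("Glu", "GABA", "Asp", "Gln"), .enrich_positions)
  e <- s$enrich
  .flux_k(s) * (s$conc[["Glu"]] * (e[["glu_c4"]] + 2 * e[["glu_c3"]]) +
                s$conc[["GABA"]] * (e[["gaba_c2"]] + 2 * e[["gaba_c4"]]) +
                s$conc[["Asp"]] * (2 * e[["asp_c3"]]) +
                s$conc[["Gln"]] * e[["gln_c4"]])
}

#' All three glucose-oxidation rates for one sample
#'
#' @inheritParams mr_glu
#' @return One-row data.frame: `id`, `tissue`, `mr_glu`, `mr_gaba`,
#'   `mr_total`.
#' @export
fluxes <- function(s) {
  data.frame(id = s$id, tissue = s$tissue,
             mr_glu = mr_glu(s), mr_gaba = mr_gaba(s), mr_total = mr_total(s),
             row.names = NULL)
}

#' Flux table for a collection of samples
#'
#' @param samples list of [isotopomer_sample()] objects.
#' @return data.frame with one row per sample (see [fluxes()]).
#' @export
flux_table <- function(samples) {
  do.call(rbind, lapply(samples, fluxes))
}
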