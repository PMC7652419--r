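# Synthetic isotopomer datasets with known flux ground truth.
#
# The three rate formulas are linear in the six position enrichments, so any
# flux target triple can be hit by scaling a nonnegative template of relative
# position weights blockwise: one scale for the glutamatergic block
# (glu_c4, glu_c3, asp_c3), one for the GABA block (gaba_c2, gaba_c4) and one
# for glutamine (gln_c4). The system is triangular in that order.

#' Generate isotopomer samples consistent with programmed flux targets
#'
#' Solves for position enrichments such that the noise-free sample returns
#' `truth$flux_targets` exactly under [mr_glu()], [mr_gaba()] and
#' [mr_total()], then applies multiplicative per-position noise.
#'
#' @param truth a [ground_truth()] object (uses `flux_targets` and `seed`).
#' @param template named nonnegative weights for the six labeled positions
#'   (`glu_c4`, `glu_c3`, `gaba_c2`, `gaba_c4`, `asp_c3`, `gln_c4`); only
#'   relative values within each block matter.
#' @param noise_cv coefficient of variation of multiplicative Gaussian noise
#'   applied per position (0 = exact samples).
#' @param n number of samples.
#' @param conc metabolite concentrations (µmol/g) shared by all samples.
#' @param glc_c1 plasma glucose-C1 enrichment, percent.
#' @param tissue tissue label.
#' @param seed RNG seed; defaults to the truth's isotopomer substream.
#' @return List of [isotopomer_sample()] objects, with the solved noise-free
#'   enrichments attached as attribute `"base_enrich"`.
#' @examples
#' truth <- ground_truth(flux_targets = c(mr_glu = 0.3476, mr_gaba = 0.12,
#'                                        mr_total = 0.59))
#' s <- gen_isotopomer_dataset(truth, noise_cv = 0, n = 1)[[1]]
#' mr_glu(s)  # 0.3476
#' @export
gen_isotopomer_dataset <- function(truth,
                                   template = c(glu_c4 = 2, glu_c3 = 0.5,
                                                gaba_c2 = 1, gaba_c4 = 0.8,
                                                asp_c3 = 1, gln_c4 = 1),
                                   noise_cv = 0, n = 1,
                                   conc = c(Glu = 13.5, GABA = 3.6,
                                            Asp = 2.3, Gln = 5.0),
                                   glc_c1 = 50,
                                   tissue = "hippocampus",
                                   seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!all(.enrich_positions %in% names(template))) {
    stop("`template` must name all six labeled positions", call. = FALSE)
  }
  template <- template[.enrich_positions]
  if (any(template < 0)) stop("template weights must be nonnegative",
                              call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be nonnegative", call. = FALSE)
  stop_if_not_scalar_pos(glc_c1, "glc_c1")
  tg <- truth$flux_targets
  if (any(tg < 0)) stop("negative target flux", call. = FALSE)

  kk <- flux_constants()
  K <- kk$prefactor * kk$infusion_scale / glc_c1
  t_glu <- template[["glu_c4"]] + 2 * template[["glu_c3"]]
  t_asp <- 2 * template[["asp_c3"]]
  t_gaba <- template[["gaba_c2"]] + 2 * template[["gaba_c4"]]
  t_gln <- template[["gln_c4"]]

  # per-unit-scale contributions of each block to each rate
  G  <- K * (kk$glu_in_glu * conc[["Glu"]] * t_glu +
             kk$asp_coeff * conc[["Asp"]] * t_asp)   # glutamatergic block -> mr_glu
  H1 <- K * (kk$glu_in_gaba * conc[["Glu"]] * t_glu +
             kk$asp_coeff * conc[["Asp"]] * t_asp)   # glutamatergic block -> mr_gaba
  H2 <- K * conc[["GABA"]] * t_gaba                  # GABA block -> mr_gaba
  T1 <- K * (conc[["Glu"]] * t_glu + conc[["Asp"]] * t_asp)
  T3 <- K * conc[["Gln"]] * t_gln

  a <- if (tg[["mr_glu"]] == 0) 0 else {
    if (G <= 0) stop("template is all-zero on the glutamatergic positions; ",
                     "no scaling can reach the mr_glu target", call. = FALSE)
    tg[["mr_glu"]] / G
  }
  resid_gaba <- tg[["mr_gaba"]] - a * H1
  b <- if (abs(resid_gaba) < 1e-12) 0 else {
    if (H2 <= 0) stop("template is all-zero on the GABA positions", call. = FALSE)
    resid_gaba / H2
  }
  resid_tot <- tg[["mr_total"]] - a * T1 - b * H2
  cc <- if (abs(resid_tot) < 1e-12) 0 else {
    if (T3 <= 0) stop("template is all-zero on gln_c4", call. = FALSE)
    resid_tot / T3
  }
  if (b < 0 || cc < 0) {
    stop("flux targets are incompatible with the template ",
         "(would require negative enrichments)", call. = FALSE)
  }

  base <- template
  base[c("glu_c4", "glu_c3", "asp_c3")] <-
    base[c("glu_c4", "glu_c3", "asp_c3")] * a
  base[c("gaba_c2", "gaba_c4")] <- base[c("gaba_c2", "gaba_c4")] * b
  base[["gln_c4"]] <- base[["gln_c4"]] * cc
  if (any(base > 100)) {
    stop("solved enrichments exceed 100%: lower the targets or raise glc_c1",
         call. = FALSE)
  }

  if (is.null(seed)) seed <- substream_seed(truth, "isotopomer")
  out <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      e <- base * pmax(0, 1 + noise_cv * stats::rnorm(length(base)))
      e <- pmin(e, 100)
      isotopomer_sample(conc = conc, enrich = e, glc_c1 = glc_c1,
                        tissue = tissue, id = sprintf("s%03d", i))
    })
  })
  attr(out, "base_enrich") <- base
  out
}
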