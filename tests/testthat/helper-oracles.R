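# Independent oracles, coded straight from the printed formulas/definitions
# and kept deliberately separate from the package implementation paths.

oracle_mr_glu <- function(Glu, GluC4, GluC3, Asp, AspC3, GlcC1) {
  0.5 * (1 / 10) * (1 / GlcC1) *
    (0.82 * Glu * (GluC4 + 2 * GluC3) + 0.42 * Asp * (2 * AspC3))
}

oracle_mr_gaba <- function(Glu, GluC4, GluC3, GABA, GABAC2, GABAC4,
                           Asp, AspC3, GlcC1) {
  0.5 * (1 / 10) * (1 / GlcC1) *
    (0.02 * Glu * (GluC4 + 2 * GluC3) +
       GABA * (GABAC2 + 2 * GABAC4) +
       0.42 * Asp * (2 * AspC3))
}

oracle_mr_total <- function(Glu, GluC4, GluC3, GABA, GABAC2, GABAC4,
                            Asp, AspC3, Gln, GlnC4, GlcC1) {
  0.5 * (1 / 10) * (1 / GlcC1) *
    (Glu * (GluC4 + 2 * GluC3) + GABA * (GABAC2 + 2 * GABAC4) +
       Asp * (2 * AspC3) + Gln * GlnC4)
}

# Random valid isotopomer sample plus its raw ingredient list.
random_flux_case <- function() {
  conc <- c(Glu = runif(1, 5, 15), GABA = runif(1, 1, 5),
            Asp = runif(1, 1, 4), Gln = runif(1, 2, 7))
  enr <- c(glu_c4 = runif(1, 1, 30), glu_c3 = runif(1, 1, 15),
           gaba_c2 = runif(1, 1, 20), gaba_c4 = runif(1, 1, 15),
           asp_c3 = runif(1, 1, 15), gln_c4 = runif(1, 1, 20))
  glc <- runif(1, 20, 60)
  list(sample = isotopomer_sample(conc, enr, glc),
       conc = conc, enr = enr, glc = glc)
}

oracle_fluxes <- function(case) {
  co <- case$conc; e <- case$enr; g <- case$glc
  c(mr_glu = oracle_mr_glu(co[["Glu"]], e[["glu_c4"]], e[["glu_c3"]],
                           co[["Asp"]], e[["asp_c3"]], g),
    mr_gaba = oracle_mr_gaba(co[["Glu"]], e[["glu_c4"]], e[["glu_c3"]],
                             co[["GABA"]], e[["gaba_c2"]], e[["gaba_c4"]],
                             co[["Asp"]], e[["asp_c3"]], g),
    mr_total = oracle_mr_total(co[["Glu"]], e[["glu_c4"]], e[["glu_c3"]],
                               co[["GABA"]], e[["gaba_c2"]], e[["gaba_c4"]],
                               co[["Asp"]], e[["asp_c3"]],
                               co[["Gln"]], e[["gln_c4"]], g))
}

# Two-stage linear step-up reference, written as the explicit sorted step-up
# loop (no p.adjust anywhere).
oracle_bky <- function(p, q = 0.05) {
  m <- length(p)
  step_up <- function(p, alpha) {
    o <- order(p)
    ps <- p[o]
    ok <- which(ps <= (seq_len(m) / m) * alpha)
    k <- if (length(ok)) max(ok) else 0
    disc <- logical(m)
    if (k > 0) disc[o[seq_len(k)]] <- TRUE
    disc
  }
  q1 <- q / (1 + q)
  s1 <- step_up(p, q1)
  r1 <- sum(s1)
  if (r1 == 0) return(logical(m))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  step_up(p, q1 * m / m0)
}

# Brute-force two-sample K-S statistic by direct supremum over the pooled
# sample points.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Match detected events to ground truth within a tolerance (seconds) and
# report recall, precision, and relative amplitude MAE over matches.
match_events <- function(truth_es, det_es, tol = 0.002) {
  if (!nrow(det_es)) {
    return(list(recall = 0, precision = NA_real_, amp_mae_pct = NA_real_))
  }
  idx <- vapply(truth_es$onset, function(o) {
    d <- abs(det_es$onset - o)
    if (min(d) <= tol) which.min(d) else NA_integer_
  }, integer(1))
  matched <- !is.na(idx)
  fp <- vapply(det_es$onset, function(o) {
    !any(abs(truth_es$onset - o) <= tol)
  }, logical(1))
  amp_mae <- if (any(matched)) {
    100 * mean(abs(det_es$amplitude[idx[matched]] -
                     truth_es$amplitude[matched])) /
      mean(truth_es$amplitude[matched])
  } else NA_real_
  list(recall = mean(matched), precision = 1 - mean(fp),
       amp_mae_pct = amp_mae)
}
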