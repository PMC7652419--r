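# The study's inferential toolkit: two-sample t tests, one-sample K-S
# normality check, two-stage adaptive FDR, and delta-delta-Ct fold changes.

#' Two-sample unpaired t test (pooled or Welch)
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param welch use the Welch-Satterthwaite correction (default FALSE:
#'   pooled variance).
#' @return One-row data.frame: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `sem_a`, `sem_b`, `method`. When both samples are constant
#'   with equal means, `t = 0, p = 1` by convention (noted in `method`).
#' @examples
#' t_test_groups(c(1, 2, 3), c(4, 5, 6))  # |t| = 3.674, df = 4
#' @export
t_test_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  method <- if (welch) "welch" else "pooled"
  res <- tryCatch(
    stats::t.test(a, b, var.equal = !welch),
    error = function(e) {
      if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
        method <<- paste0(method, " (both groups constant and equal; p = 1 ",
                          "by convention)")
        list(statistic = 0, parameter = length(a) + length(b) - 2,
             p.value = 1)
      } else {
        stop(e)
      }
    })
  data.frame(statistic = unname(res$statistic), df = unname(res$parameter),
             p_value = unname(res$p.value),
             mean_a = mean(a), mean_b = mean(b),
             sem_a = sem(a), sem_b = sem(b), method = method)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests the sample against a normal distribution with the sample's own mean
#' and SD. Estimating the parameters from the same sample makes the test
#' anti-conservative (the historical practice this mirrors); the caveat is
#' carried in the result.
#'
#' @param values numeric sample, n >= 5, non-constant.
#' @return List: `D`, `p`, `n`, `note`.
#' @export
ks_normality <- function(values) {
  if (length(values) < 5) stop("need n >= 5 for the normality check",
                               call. = FALSE)
  if (stats::sd(values) == 0) stop("constant sample", call. = FALSE)
  res <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  list(D = unname(res$statistic), p = unname(res$p.value),
       n = length(values),
       note = "normal parameters estimated from the sample; p anti-conservative")
}

#' Two-stage linear step-up false-discovery control
#'
#' The adaptive two-stage procedure: a first linear step-up (BH) pass at
#' `q' = q / (1 + q)` estimates the number of true nulls `m0 = m - r1`; the
#' second pass re-runs BH at `q' * m / m0`. Discoveries are monotone in `q`.
#'
#' @param pvals p-values in \[0, 1\], nonempty.
#' @param q target false-discovery rate (default 0.05).
#' @return Logical discovery mask, with attributes `m0` (estimated true
#'   nulls) and `stage2_level`.
#' @export
fdr_bky <- function(pvals, q = 0.05) {
  if (!length(pvals)) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  q1 <- q / (1 + q)
  adj <- stats::p.adjust(pvals, method = "BH")
  r1 <- sum(adj <= q1)
  if (r1 == 0) {
    mask <- rep(FALSE, m)
    return(structure(mask, m0 = m, stage2_level = q1))
  }
  m0 <- m - r1
  if (m0 == 0) {
    return(structure(rep(TRUE, m), m0 = 0L, stage2_level = 1))
  }
  q2 <- q1 * m / m0
  structure(adj <= q2, m0 = m0, stage2_level = q2)
}

#' Delta-delta-Ct relative fold changes
#'
#' Per subject, `dCt = Ct(gene) - Ct(housekeeping)`; per gene,
#' `ddCt = mean dCt(comparison group) - mean dCt(reference group)` and
#' `fold = 2^(-ddCt)`. Group aggregation uses the arithmetic mean of dCt
#' (the geometric mean of relative quantities). Per-subject relative
#' quantities `2^-(dCt - mean dCt(reference))` are retained for group t tests.
#'
#' @param ct a `ct_table` from [gen_qpcr()], or any data.frame with columns
#'   `subject`, `group`, `gene`, `ct`.
#' @param reference_group reference group label (default: first group level
#'   in the table).
#' @param housekeeping housekeeping gene name (default: the table's
#'   attribute).
#' @return data.frame with one row per gene and non-reference group:
#'   `gene`, `group`, `ddct`, `fold_change`, `n_ref`, `n_grp`; attribute
#'   `relative_quantity` (per-subject data.frame).
#' @export
ddct_fold_change <- function(ct, reference_group = NULL, housekeeping = NULL) {
  need <- c("subject", "group", "gene", "ct")
  if (!all(need %in% names(ct))) {
    stop("`ct` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(ct$ct))) stop("Ct values must be finite", call. = FALSE)
  if (is.null(housekeeping)) housekeeping <- attr(ct, "housekeeping")
  if (is.null(housekeeping) || !housekeeping %in% ct$gene) {
    stop("housekeeping gene not found in the table", call. = FALSE)
  }
  groups <- unique(ct$group)
  if (is.null(reference_group)) reference_group <- groups[1]
  if (!reference_group %in% groups) {
    stop("reference group not present", call. = FALSE)
  }

  hk <- ct[ct$gene == housekeeping, c("subject", "ct")]
  names(hk)[2] <- "ct_hk"
  dat <- merge(ct[ct$gene != housekeeping, ], hk, by = "subject",
               all.x = TRUE)
  if (any(is.na(dat$ct_hk))) {
    stop("subjects missing a housekeeping Ct: ",
         paste(unique(dat$subject[is.na(dat$ct_hk)]), collapse = ", "),
         call. = FALSE)
  }
  dat$dct <- dat$ct - dat$ct_hk

  ref_means <- tapply(dat$dct[dat$group == reference_group],
                      dat$gene[dat$group == reference_group], mean)
  dat$relative_quantity <- 2^(-(dat$dct - ref_means[dat$gene]))

  other <- setdiff(groups, reference_group)
  out <- do.call(rbind, lapply(other, function(g) {
    do.call(rbind, lapply(sort(unique(dat$gene)), function(gene) {
      d_ref <- dat$dct[dat$group == reference_group & dat$gene == gene]
      d_grp <- dat$dct[dat$group == g & dat$gene == gene]
      dd <- mean(d_grp) - mean(d_ref)
      data.frame(gene = gene, group = g, ddct = dd, fold_change = 2^(-dd),
                 n_ref = length(d_ref), n_grp = length(d_grp))
    }))
  }))
  attr(out, "relative_quantity") <-
    dat[, c("subject", "group", "gene", "dct", "relative_quantity")]
  out
}
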