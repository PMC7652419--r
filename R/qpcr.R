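# Synthetic qPCR Ct tables with programmed fold changes.

#' Generate a Ct table with known log2 fold changes
#'
#' Per-subject Ct values are
#' `baseline(gene) + subject offset - log2_fc(gene) * [treated] + noise`.
#' The subject offset models loading/pipetting differences and cancels in the
#' housekeeping-normalized delta-Ct, so a noise-free table returns the
#' programmed fold changes exactly under [ddct_fold_change()].
#'
#' @param truth a [ground_truth()] (uses `qpcr_params` and `seed`).
#' @param genes genes to include (default: names of the programmed
#'   `log2_fc`); must contain the housekeeping gene.
#' @param n_per_group subjects per group (default 11).
#' @param groups two group labels, reference first.
#' @param ct_sd override the truth's Ct noise SD (e.g. 0 for a noise-free
#'   table).
#' @param seed RNG seed (default: the truth's qPCR substream).
#' @return data.frame of class `ct_table`: `subject`, `group`, `gene`, `ct`;
#'   attribute `housekeeping`.
#' @export
gen_qpcr <- function(truth, genes = NULL, n_per_group = 11,
                     groups = c("vehicle", "treated"), ct_sd = NULL,
                     seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  qp <- truth$qpcr_params
  if (is.null(genes)) genes <- names(qp$log2_fc)
  if (!qp$housekeeping %in% genes) {
    stop("housekeeping gene missing from `genes`", call. = FALSE)
  }
  fc <- qp$log2_fc[genes]
  if (any(is.na(fc))) {
    stop("no programmed fold change for: ",
         paste(genes[is.na(fc)], collapse = ", "), call. = FALSE)
  }
  if (is.null(ct_sd)) ct_sd <- qp$ct_sd
  if (ct_sd < 0) stop("`ct_sd` must be nonnegative", call. = FALSE)
  if (is.null(seed)) seed <- substream_seed(truth, "qpcr")

  with_seed(seed, {
    baseline <- stats::runif(length(genes), 20, 28)
    names(baseline) <- genes
    n_sub <- 2 * n_per_group
    subj <- sprintf("m%02d", seq_len(n_sub))
    grp <- rep(groups, each = n_per_group)
    offs <- stats::rnorm(n_sub, 0, qp$subject_sd)
    rows <- expand.grid(subject = subj, gene = genes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows$group <- grp[match(rows$subject, subj)]
    treated <- as.numeric(rows$group == groups[2])
    rows$ct <- baseline[rows$gene] + offs[match(rows$subject, subj)] -
      fc[rows$gene] * treated +
      if (ct_sd > 0) stats::rnorm(nrow(rows), 0, ct_sd) else 0
    rows <- rows[, c("subject", "group", "gene", "ct")]
    structure(rows, housekeeping = qp$housekeeping,
              class = c("ct_table", "data.frame"))
  })
}
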