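test_that("two-sample t test matches hand computation and conventions", {
  res <- t_test_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(res$statistic), 3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)

  same <- t_test_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  const <- t_test_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$p_value, 1)
  expect_match(const$method, "convention")

  # Welch equals pooled for equal variances and sizes
  a <- c(1.2, 2.1, 2.9, 4.4); b <- a + 1
  expect_equal(t_test_groups(a, b, welch = TRUE)$p_value,
               t_test_groups(a, b, welch = FALSE)$p_value,
               tolerance = 1e-12)
  expect_error(t_test_groups(1, c(2, 3)), "n >= 2")
})

test_that("t test null rejection rate is calibrated at alpha 0.05", {
  set.seed(55)
  n_rep <- 4000
  rej <- sum(replicate(n_rep, {
    t_test_groups(rnorm(8), rnorm(8))$p_value < 0.05
  }))
  bounds <- qbinom(c(0.025, 0.975), n_rep, 0.05)
  expect_gte(rej, bounds[1]); expect_lte(rej, bounds[2])
})

test_that("K-S normality check separates normal from exponential samples", {
  set.seed(66)
  norm_p <- ks_normality(rnorm(500))$p
  expect_gt(norm_p, 0.05)
  rejections <- mean(replicate(40, ks_normality(rexp(200))$p < 0.05))
  expect_gt(rejections, 0.9)
  expect_error(ks_normality(rnorm(3)), "n >= 5")
  expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("two-stage FDR control matches the independent step-up reference", {
  expect_equal(unclass(fdr_bky(rep(1, 17)))[1:17], rep(FALSE, 17),
               ignore_attr = TRUE)
  one_hit <- c(1e-6, runif(16, 0.2, 1))
  expect_true(fdr_bky(one_hit)[1])

  set.seed(88)
  for (i in 1:300) {
    m <- sample(c(5, 17, 40), 1)
    p <- runif(m)^sample(c(1, 3), 1)   # mix of null-ish and signal-ish
    got <- as.logical(fdr_bky(p))
    expect_identical(got, oracle_bky(p))
  }
  expect_error(fdr_bky(numeric(0)), "empty")
  expect_error(fdr_bky(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("FDR discoveries are monotone in q and FDP is controlled", {
  set.seed(89)
  for (i in 1:50) {
    p <- runif(20)^2
    d1 <- as.logical(fdr_bky(p, q = 0.02))
    d2 <- as.logical(fdr_bky(p, q = 0.10))
    expect_true(all(d2[d1]))   # raising q never removes a discovery
  }
  # all-null mean false-discovery proportion stays below q
  fdp <- replicate(800, {
    disc <- fdr_bky(runif(17), q = 0.05)
    if (any(disc)) 1 else 0    # all nulls: FDP is 1 when anything is called
  })
  se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 2 * se)
})

test_that("ddCt fold changes honor housekeeping normalization", {
  mk_ct <- function(shift = 0) {
    subj <- rep(sprintf("m%d", 1:4), each = 3)
    grp <- rep(c("vehicle", "treated"), each = 6)
    gene <- rep(c("Gapdh", "gA", "gB"), 4)
    base <- c(Gapdh = 20, gA = 24, gB = 26)
    ct <- base[gene]
    ct[gene == "gA" & grp == "treated"] <- 24 - 1     # fold 2
    ct[gene == "gB" & grp == "treated"] <- 26 + 1     # fold 0.5
    per_sub <- c(m1 = 0, m2 = shift, m3 = 0, m4 = shift)
    ct <- ct + per_sub[subj]
    structure(data.frame(subject = subj, group = grp, gene = gene, ct = ct),
              housekeeping = "Gapdh", class = c("ct_table", "data.frame"))
  }
  res <- ddct_fold_change(mk_ct())
  expect_equal(res$fold_change[res$gene == "gA"], 2)
  expect_equal(res$fold_change[res$gene == "gB"], 0.5)
  expect_equal(res$ddct[res$gene == "gA"], -1)

  # invariant to adding a constant to every Ct of a subject
  res_shift <- ddct_fold_change(mk_ct(shift = 3.7))
  expect_equal(res_shift$fold_change, res$fold_change, tolerance = 1e-12)

  broken <- mk_ct()
  broken <- broken[!(broken$subject == "m2" & broken$gene == "Gapdh"), ]
  attr(broken, "housekeeping") <- "Gapdh"
  expect_error(ddct_fold_change(broken), "missing a housekeeping")
})

test_that("noisy ddCt estimation is consistent across simulations", {
  tr <- ground_truth(qpcr_params = list(
    log2_fc = c(Gapdh = 0, g1 = 1)), seed = 100)
  folds <- vapply(1:200, function(i) {
    ct <- gen_qpcr(tr, n_per_group = 11, seed = 1000 + i)
    ddct_fold_change(ct)$fold_change
  }, numeric(1))
  sem <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 2), 3 * sem + 0.01)
})
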