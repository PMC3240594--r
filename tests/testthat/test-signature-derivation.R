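test_that("high/low split follows interpolated percentiles with minimum group size", {
  x <- setNames(1:15, paste0("S", 1:15))
  sp <- split_high_low(x)                     # p80 = 12.2, p20 = 3.8
  expect_true(sp$eligible)
  expect_setequal(sp$high, c("S13", "S14", "S15"))
  expect_setequal(sp$low, c("S1", "S2", "S3"))

  sp10 <- split_high_low(setNames(1:10, paste0("S", 1:10)))  # p80 = 8.2
  expect_false(sp10$eligible)                 # high group is only {S9, S10}

  expect_false(split_high_low(setNames(rep(1, 10), paste0("S", 1:10)))$eligible)
  expect_error(split_high_low(1:5), "at least 6")
})

test_that("moderated t reduces to the pooled t and honors its limits", {
  withr::with_seed(11, {
    m <- random_expr(200, 10)
    hi <- colnames(m)[1:5]; lo <- colnames(m)[6:10]
    res <- moderated_t_test(m, hi, lo)
    oracle <- pooled_t_oracle(m[, hi], m[, lo])

    # d0 -> 0: exactly the ordinary pooled t
    r0 <- moderated_t_test(m, hi, lo, d0 = 0, s0sq = 1)
    expect_equal(r0$t_mod, unname(oracle$t), tolerance = 1e-12)
    expect_equal(r0$p, unname(oracle$p), tolerance = 1e-12)

    # d0 -> Inf: common-variance z-like test
    rInf <- moderated_t_test(m, hi, lo, d0 = Inf, s0sq = 0.8)
    md <- rowMeans(m[, hi]) - rowMeans(m[, lo])
    expect_equal(rInf$t_mod, unname(md / sqrt(0.8 * (2 / 5))),
                 tolerance = 1e-12)

    # estimated shrinkage lands between the two limits gene-wise
    expect_true(all(res$q >= res$p - 1e-15))
    expect_true(all(res$p >= 0 & res$p <= 1))
    expect_equal(attr(res, "d0") + 8, res$df_total[1])
  })
})

test_that("identical gene variances collapse the moderated t onto the pooled t", {
  # construct groups whose pooled variance is identical for every gene
  base <- c(-1, 0, 1)
  m <- expression_matrix(
    t(sapply(1:50, function(i) c(base + i, base + i * 0.5))),
    feature_ids = sprintf("G%02d", 1:50),
    sample_ids = sprintf("S%d", 1:6))
  res <- moderated_t_test(m, paste0("S", 1:3), paste0("S", 4:6))
  oracle <- pooled_t_oracle(m[, 1:3], m[, 4:6])
  expect_equal(res$t_mod, unname(oracle$t), tolerance = 1e-9)

  zero <- m
  zero[1, ] <- 5  # zero-variance gene must not produce NaN
  expect_true(all(is.finite(moderated_t_test(zero, paste0("S", 1:3),
                                             paste0("S", 4:6))$t_mod)))
  expect_error(moderated_t_test(m[1, , drop = FALSE], paste0("S", 1:3),
                                paste0("S", 4:6)), "2 genes")
})

test_that("zero mean difference gives t = 0 and p = 1", {
  m <- expression_matrix(rbind(c(1, 2, 3, 1, 2, 3), c(4, 0, 2, 1, 2, 3)),
                         c("G1", "G2"), paste0("S", 1:6))
  res <- moderated_t_test(m, paste0("S", 1:3), paste0("S", 4:6))
  expect_equal(res$t_mod[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("derivation recovers planted targets and respects alpha", {
  sim <- generate_cohorts(sim_config(n_genes = 1000, n_mirnas = 6,
                                     n_pathways = 2, n_samples_per_cohort = 50,
                                     n_cohorts = 1, targets_per_mirna = 40,
                                     seed = 21))
  ch <- sim$cohorts[[1]]
  m <- rownames(ch$mirna)[1]
  sig <- derive_signature(ch, m)
  expect_s3_class(sig, "gene_signature")
  tg <- sim$truth$targets_of[[m]]
  # repressive planted effect: most targets end up in the down set
  expect_gt(length(intersect(sig$down, tg)) / length(tg), 0.5)

  all_genes <- derive_signature(ch, m, alpha = 1 + 1e-12, adjust = FALSE)
  expect_equal(signature_size(all_genes), nrow(ch$mrna))

  expect_error(derive_signature(ch, "NOT_A_MIRNA"), "unknown miRNA")
})

test_that("ineligible splits yield a skipped miRNA, not an error", {
  withr::with_seed(31, {
    mrna <- random_expr(50, 12)
    mir <- expression_matrix(matrix(rep(1, 12), 1), "MIRX", colnames(mrna))
    ch <- cohort("c", mrna, mir)
    expect_null(derive_signature(ch, "MIRX"))
  })
})

test_that("robustness permutations clear strong signatures and reject weak ones", {
  sim <- generate_cohorts(sim_config(n_genes = 800, n_mirnas = 4,
                                     n_pathways = 2, n_samples_per_cohort = 50,
                                     n_cohorts = 1, targets_per_mirna = 40,
                                     seed = 23))
  ch <- sim$cohorts[[1]]
  m <- rownames(ch$mirna)[1]
  sp <- split_high_low(ch$mirna[m, ])
  rb <- robustness_test(ch$mrna, sp, n_perm = 100, seed = 7)
  expect_equal(rb$fdr, 0)          # no permutation beats a planted signature
  expect_true(rb$retained)
  expect_length(rb$permuted_sizes, 100)

  # permutation-order invariance: same seed, same answer
  rb2 <- robustness_test(ch$mrna, sp, n_perm = 100, seed = 7)
  expect_identical(rb$fdr, rb2$fdr)
  expect_error(robustness_test(ch$mrna, sp, n_perm = 0), "n_perm")
})

test_that("the derivation funnel is monotone and nearly empty on null data", {
  withr::with_seed(41, {
    mrna <- random_expr(400, 40)
    mir <- random_expr(8, 40, prefix = "MIR")
    ch <- cohort("null", mrna, mir)
    out <- derive_all_signatures(ch, n_perm = 30, seed = 3)
    r <- out$report
    expect_true(sum(r$retained) <= sum(r$size > 0 & r$eligible))
    expect_true(sum(r$eligible) <= nrow(r))
    # under the null, BH at 1e-4 finds essentially nothing
    expect_lte(sum(r$size > 0), 1)
  })
})
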