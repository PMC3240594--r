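test_that("Storey q-values hit their analytic anchors", {
  expect_equal(storey_qvalue(rep(1, 10)), rep(1, 10))

  withr::with_seed(61, {
    # pi0 forced to 1 reproduces Benjamini-Hochberg exactly
    for (i in 1:10) {
      p <- runif(sample(5:300, 1))
      expect_lt(max(abs(storey_qvalue(p, pi0 = 1) - p.adjust(p, "BH"))),
                1e-12)
    }
    # uniform p-values: the estimator recognizes a pure null
    p <- runif(10000)
    pi0_hat <- median(vapply(seq(0.05, 0.95, 0.05),
                             function(l) mean(p > l) / (1 - l), numeric(1)))
    expect_gte(min(pi0_hat, 1), 0.9)
    expect_true(all(storey_qvalue(p) <= 1))
  })
  expect_error(storey_qvalue(numeric()), "empty")
  expect_error(storey_qvalue(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("pairwise correlations call signs at the q threshold", {
  withr::with_seed(62, {
    base <- rnorm(30)
    scores <- rbind(sigA = base,
                    sigB = base,                     # identical: R = 1
                    sigC = -base,                    # negated: R = -1
                    sigD = rnorm(30))                # unrelated
    colnames(scores) <- paste0("S", 1:30)
    rec <- pairwise_correlations(scores, cohort = "c1")
    ab <- rec[rec$a == "sigA" & rec$b == "sigB", ]
    expect_equal(ab$R, 1)
    expect_equal(ab$call, "+")
    ac <- rec[rec$a == "sigA" & rec$b == "sigC", ]
    expect_equal(ac$R, -1)
    expect_equal(ac$call, "-")

    const <- rbind(scores, sigE = rep(1, 30))
    rec2 <- pairwise_correlations(const, cohort = "c1")
    expect_true(all(is.na(rec2$R[rec2$a == "sigE" | rec2$b == "sigE"])))
    expect_true(all(rec2$call[is.na(rec2$R)] == "ns"))
  })
})

test_that("independent score rows stay mostly uncalled under FDR control", {
  withr::with_seed(63, {
    frac_called <- replicate(20, {
      scores <- matrix(rnorm(15 * 40), 15, 40,
                       dimnames = list(paste0("e", 1:15), paste0("S", 1:40)))
      rec <- pairwise_correlations(scores)
      mean(rec$call != "ns")
    })
    expect_lt(mean(frac_called), 0.05)
  })
})

make_records <- function(calls, Rs, sigs = paste0("sig", seq_along(calls)),
                         partner = "mirX", cohort = "c1") {
  data.frame(a = sigs, b = partner, cohort = cohort, R = Rs,
             p = 0.01, q = ifelse(calls == "ns", 0.5, 0.01), call = calls,
             stringsAsFactors = FALSE)
}

test_that("pathway aggregation keeps single-sign support and flags discordance", {
  assignment <- data.frame(signature = c("sig1", "sig2"), pathway = "PW1")
  plus_ns <- aggregate_pathway(make_records(c("+", "ns"), c(0.8, 0.1)),
                               assignment)
  expect_equal(plus_ns$call, "+")
  expect_equal(plus_ns$R, 0.8)

  conflict <- aggregate_pathway(make_records(c("+", "-"), c(0.8, -0.7)),
                                assignment)
  expect_equal(conflict$call, "conflict")

  ns <- aggregate_pathway(make_records(c("ns", "ns"), c(0.1, 0.1)),
                          assignment)
  expect_equal(ns$call, "ns")
})

test_that("cross-cohort merge discards discordance and applies the cohort gate", {
  node_types <- c(mirX = "miRNA", PW1 = "pathway")
  mk <- function(calls) {
    data.frame(a = "PW1", b = "mirX", cohort = paste0("c", seq_along(calls)),
               call = calls, R = ifelse(calls == "+", 0.6,
                                        ifelse(calls == "-", -0.6, 0)),
               stringsAsFactors = FALSE)
  }
  net <- cross_cohort_merge(mk(c("+", "+", "+", "ns", "ns")), node_types)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sign, "+")
  expect_equal(net$edges$support_count, 3L)
  expect_equal(net$edges$call.c4, "ns")

  expect_equal(nrow(cross_cohort_merge(mk(c("+", "-", "ns", "ns", "ns")),
                                       node_types)$edges), 0)

  gated <- cross_cohort_merge(mk(c("ns", "+", "+", "ns", "ns")), node_types,
                              require_cohort = "c1")
  expect_equal(nrow(gated$edges), 0)
  passed <- cross_cohort_merge(mk(c("+", "+", "ns", "ns", "ns")), node_types,
                               require_cohort = "c1")
  expect_equal(nrow(passed$edges), 1)

  # order invariance over cohorts
  shuffled <- mk(c("+", "+", "+", "ns", "ns"))[c(4, 2, 5, 1, 3), ]
  net2 <- cross_cohort_merge(shuffled, node_types)
  expect_equal(net2$edges, net$edges)
})

test_that("modulator nomination needs full support and knockdown independence", {
  nodes <- data.frame(id = c("mirA", "mirB", "mirC", "PW1"),
                      type = c(rep("miRNA", 3), "pathway"))
  edges <- data.frame(a = c("mirA", "mirB", "mirC"), b = "PW1",
                      sign = c("+", "+", "+"), support_count = c(5L, 5L, 4L),
                      R = c(0.9, 0.8, 0.7), stringsAsFactors = FALSE)
  net <- signed_network(nodes, edges)
  kd <- data.frame(mirna = c("mirA", "mirB", "mirC"),
                   p = c(0.9, 0.001, 0.8))   # mirB responds to the knockdown
  expect_equal(nominate_modulators(net, "PW1", kd, n_cohorts = 5), "mirA")
  expect_error(nominate_modulators(net, "PW9", kd, 5), "unknown pathway")
})

test_that("build_network recovers planted structure across cohorts", {
  sim <- generate_cohorts(sim_config(n_genes = 600, n_mirnas = 8,
                                     n_pathways = 2, n_samples_per_cohort = 40,
                                     n_cohorts = 3, targets_per_mirna = 30,
                                     seed = 65))
  sigs <- sim$truth$pathway_signatures
  # score the true miRNA target sets as down-gene signatures plus pathway sigs
  mir_sigs <- lapply(names(sim$truth$targets_of), function(m) {
    gene_signature(m, down = sim$truth$targets_of[[m]])
  })
  names(mir_sigs) <- names(sim$truth$targets_of)
  score_list <- lapply(sim$cohorts, function(ch) {
    score_signatures(ch$mrna, c(mir_sigs, sigs))
  })
  nb <- build_network(score_list, sim$truth$assignment)
  links <- sim$truth$planted_links
  key <- paste(pmin(links$mirna, links$pathway),
               pmax(links$mirna, links$pathway))
  ek <- paste(nb$network$edges$a, nb$network$edges$b)
  expect_gte(mean(key %in% ek), 0.8)
  m <- match(key[key %in% ek], ek)
  expect_true(all(nb$network$edges$sign[m] ==
                    ifelse(links$sign[key %in% ek] > 0, "+", "-")))
})
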