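test_that("overlap ratio matches hand counts and is symmetric and monotone", {
  expect_equal(overlap_ratio(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_ratio(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_ratio(c("a", "b", "c"), c("b", "c", "d", "e")), 2 / 3)
  expect_equal(overlap_ratio(c("b", "c", "d", "e"), c("a", "b", "c")), 2 / 3)
  expect_error(overlap_ratio(character(), "a"), "non-empty")

  # growing the intersection with margins fixed never lowers the ratio
  base <- overlap_ratio(c("a", "b", "c"), c("c", "x", "y"))
  more <- overlap_ratio(c("a", "b", "c"), c("b", "c", "y"))
  expect_gte(more, base)
})

test_that("Fisher exact test equals hypergeometric enumeration", {
  myc <- matrix(c(10, 0, 1, 7), 2, byrow = TRUE)
  expect_equal(fisher_exact(myc), 8 / 31824, tolerance = 1e-10)
  expect_equal(fisher_exact(myc), brute_force_fisher(myc), tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)

  withr::with_seed(71, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 4), 2)
      if (sum(tab) == 0) next
      expect_equal(fisher_exact(tab), brute_force_fisher(tab),
                   tolerance = 1e-9)
    }
  })
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("chi-square test matches the Pearson closed form", {
  prop <- matrix(c(20, 10, 40, 20), 2)   # perfectly proportional
  res <- chi_square(prop, yates = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  tab <- matrix(c(30, 10, 10, 30), 2)
  plain <- chi_square(tab, yates = FALSE)
  expect_equal(plain$statistic, 20)
  expect_equal(plain$p, pchisq(20, 1, lower.tail = FALSE))
  expect_lt(chi_square(tab, yates = TRUE)$statistic, plain$statistic)
  expect_error(chi_square(matrix(c(0, 0, 1, 2), 2, byrow = TRUE)), "margins")
})

test_that("redundancy tests detect planted family and overlap structure", {
  net <- fixture_network()
  family_of <- c(mirA = "f1", mirB = "f1", mirC = "f2", mirD = "f2")
  fam <- family_redundancy_test(net, family_of)
  # the only positive edge (mirA, mirB) is the same-family pair
  expect_equal(unname(fam$table["same_family", "positive_edge"]), 1)
  expect_gt(fam$proportions[["same_family"]],
            fam$proportions[["different_family"]])

  targets <- list(mirA = letters[1:10], mirB = letters[1:9],
                  mirC = letters[15:24], mirD = letters[13:22])
  ov <- overlap_redundancy_test(net, targets)
  expect_equal(unname(ov$table["large_overlap", "positive_edge"]), 1)

  expect_error(family_redundancy_test(net, c(mirA = "f1", mirB = "f1")),
               "same-family and different-family")
})

test_that("contingency tests give uniform p-values when labels are shuffled", {
  withr::with_seed(72, {
    net <- fixture_network()
    fam_ids <- c("mirA", "mirB", "mirC", "mirD")
    ps <- replicate(100, {
      fam <- setNames(sample(c("f1", "f1", "f2", "f2")), fam_ids)
      tryCatch(family_redundancy_test(net, fam, yates = FALSE)$p,
               error = function(e) NA_real_)
    })
    ps <- ps[!is.na(ps)]
    # shuffled labels: large p-values dominate, no excess of small ones
    expect_lt(mean(ps < 0.05), 0.1)
  })
})

test_that("pathway cotarget pairs require joint same-sign edges", {
  nodes <- data.frame(id = c("m1", "m2", "m3", "P1"),
                      type = c("miRNA", "miRNA", "miRNA", "pathway"))
  edges <- data.frame(a = c("m1", "m2", "m3"), b = "P1",
                      sign = c("+", "+", "-"), support_count = 1L,
                      stringsAsFactors = FALSE)
  net <- signed_network(nodes, edges)
  cp <- pathway_cotarget_pairs(net)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$mirna1, "m1")
  expect_equal(cp$mirna2, "m2")
  expect_equal(cp$pathways, "P1")

  no_pw <- signed_network(nodes[1:3, , drop = FALSE],
                          data.frame(a = "m1", b = "m2", sign = "+",
                                     support_count = 1L))
  expect_equal(nrow(pathway_cotarget_pairs(no_pw)), 0)
})

test_that("cluster and overlap cotargeting tests read planted structure", {
  nodes <- data.frame(id = c(paste0("m", 1:4), "P1"),
                      type = c(rep("miRNA", 4), "pathway"))
  edges <- data.frame(a = c("m1", "m2"), b = "P1", sign = "+",
                      support_count = 1L, stringsAsFactors = FALSE)
  net <- signed_network(nodes, edges)
  cluster_of <- c(m1 = "cl1", m2 = "cl1", m3 = "cl2", m4 = "cl2")
  res <- cluster_cotargeting_test(net, cluster_of)
  expect_equal(unname(res$table["same_cluster", "cotargeted"]), 1)
  expect_equal(sum(res$table), 6)

  targets <- list(m1 = letters[1:10], m2 = letters[1:9],
                  m3 = letters[15:24], m4 = letters[13:22])
  res2 <- overlap_cotargeting_test(net, targets)
  expect_equal(unname(res2$table["large_overlap", "cotargeted"]), 1)
})

test_that("sequence similarity scores follow the zero-match scheme", {
  expect_equal(sequence_similarity("ACGUACGUACGU", "ACGUACGUACGU"), 0)
  expect_equal(sequence_similarity("AAA", "AAU"), -1)
  expect_equal(sequence_similarity("AA", "AAAA"), -2)
  expect_equal(sequence_similarity("acgu", "ACGT"), 0)  # case and T/U
  expect_error(sequence_similarity("ACGX", "ACGU"), "invalid character")

  withr::with_seed(73, {
    for (i in 1:15) {
      s1 <- paste(sample(c("A", "C", "G", "U"), sample(4:12, 1), TRUE),
                  collapse = "")
      s2 <- paste(sample(c("A", "C", "G", "U"), sample(4:12, 1), TRUE),
                  collapse = "")
      expect_equal(sequence_similarity(s1, s2), nw_oracle(s1, s2))
    }
  })
})

test_that("dissimilarity filtering applies the strict -5 threshold", {
  seqs <- c(mirA = "ACGUACGUACGUACGUACGUAC",
            mirB = "ACGUACGUACGUACGUACGUAC",       # identical to mirA: 0
            mirC = "UGCAUGCAUGCAUGCAUGCAUG",       # far from mirA
            mirD = "ACGUACGUACGUACGUACGAUC")       # close to mirA
  expect_lt(sequence_similarity(seqs["mirA"], seqs["mirC"]), -5)
  exact5 <- sequence_similarity("AAAAACCCCC", "AAAAAGGGGG")
  expect_equal(exact5, -5)

  pairs <- data.frame(mirna1 = c("mirA", "mirA", "mirA", "mirX"),
                      mirna2 = c("mirB", "mirC", "mirD", "mirC"),
                      stringsAsFactors = FALSE)
  expect_warning(out <- filter_dissimilar_pairs(pairs, seqs), "missing")
  expect_equal(out$mirna2, "mirC")            # identical & near pairs removed
  expect_true(all(out$similarity < -5))

  # a score of exactly -5 is removed under the strict rule
  p5 <- data.frame(mirna1 = "x", mirna2 = "y")
  s5 <- c(x = "AAAAACCCCC", y = "AAAAAGGGGG")
  expect_equal(nrow(filter_dissimilar_pairs(p5, s5)), 0)
})

test_that("FASTA reading returns named mature sequences", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">hsa-miR-21 some description", "UAGCUUAUCAGACUGAUGUUGA",
               ">hsa-miR-155", "uuaaugcuaaucgugauagggguu"), p)
  seqs <- read_mirna_fasta(p)
  expect_equal(names(seqs), c("hsa-miR-21", "hsa-miR-155"))
  expect_equal(unname(seqs[1]), "UAGCUUAUCAGACUGAUGUUGA")
  expect_equal(sequence_similarity(seqs[1], seqs[1]), 0)
})
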