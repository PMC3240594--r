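#' Target-set overlap ratio
#'
#' `|S_X inter S_Y| / min(|S_X|, |S_Y|)`: symmetric, in `[0, 1]`, and the
#' basis of the large (> 0.6) / small (< 0.4) overlap dichotomy used by the
#' redundancy analyses.
#'
#' @param sx,sy Non-empty gene sets (character vectors).
#' @return The overlap ratio.
#' @export
overlap_ratio <- function(sx, sy) {
  sx <- unique(sx); sy <- unique(sy)
  if (length(sx) == 0 || length(sy) == 0) stop("target sets must be non-empty")
  length(intersect(sx, sy)) / min(length(sx), length(sy))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, of tables no more probable than the
#' observed one.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) == 0) stop("at least one margin must be positive")
  stats::fisher.test(counts)$p.value
}

#' Chi-square test on a 2x2 table
#'
#' Pearson chi-square statistic, with Yates continuity correction by
#' default for 2x2 tables, against the chi-square distribution with 1
#' degree of freedom.
#'
#' @param counts 2x2 matrix of nonnegative counts with positive margins.
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return List with `statistic` and `p`.
#' @export
chi_square <- function(counts, yates = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all margins must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

# all unordered pairs of ids as a two-column matrix
all_pairs <- function(ids) {
  if (length(ids) < 2) return(matrix(character(), 0, 2))
  t(combn(sort(ids), 2))
}

# named lookup of positive miRNA-miRNA edges in a network
positive_edge_lookup <- function(net) {
  e <- net$edges[net$edges$sign == "+", , drop = FALSE]
  paste(pmin(e$a, e$b), pmax(e$a, e$b))
}

#' Same-family enrichment of positive miRNA-miRNA edges
#'
#' Tests whether miRNA pairs from the same family are more likely to be
#' connected by a positive edge than pairs from different families, over all
#' pairs of family-annotated miRNA nodes.
#'
#' @param net A [signed_network()].
#' @param family_of Named character vector, miRNA -> family id (`NA`
#'   allowed).
#' @param yates Continuity correction for the chi-square test.
#' @return List with `table` (2x2: same/different family x positive edge
#'   yes/no), `statistic`, `p`, and `proportions` (positive-edge rate per
#'   row).
#' @export
family_redundancy_test <- function(net, family_of, yates = TRUE) {
  mir <- net$nodes$id[net$nodes$type == "miRNA"]
  mir <- mir[mir %in% names(family_of) & !is.na(family_of[mir])]
  pairs <- all_pairs(mir)
  if (nrow(pairs) == 0) stop("no annotated miRNA pairs in the network")
  same <- family_of[pairs[, 1]] == family_of[pairs[, 2]]
  if (length(unique(same)) < 2) {
    stop("need both same-family and different-family pairs")
  }
  pos <- paste(pairs[, 1], pairs[, 2]) %in% positive_edge_lookup(net)
  contingency_result(same, pos, c("same_family", "different_family"),
                     yates)
}

#' Target-overlap enrichment of positive miRNA-miRNA edges
#'
#' Classifies miRNA pairs by target-set overlap ratio (large > `large`,
#' small < `small`; intermediate pairs are excluded) and tests whether
#' large-overlap pairs are more often connected by positive edges.
#'
#' @param net A [signed_network()].
#' @param targets_of Named list, miRNA -> predicted target gene set.
#' @param large,small Overlap class cutoffs (paper defaults 0.6 / 0.4).
#' @param yates Continuity correction.
#' @return As [family_redundancy_test()].
#' @export
overlap_redundancy_test <- function(net, targets_of, large = 0.6,
                                    small = 0.4, yates = TRUE) {
  cls <- overlap_classes(net, targets_of, large, small)
  pos <- paste(cls$pairs[, 1], cls$pairs[, 2]) %in% positive_edge_lookup(net)
  contingency_result(cls$is_large, pos, c("large_overlap", "small_overlap"),
                     yates)
}

overlap_classes <- function(net, targets_of, large, small) {
  mir <- net$nodes$id[net$nodes$type == "miRNA"]
  mir <- mir[mir %in% names(targets_of)]
  pairs <- all_pairs(mir)
  if (nrow(pairs) == 0) stop("no miRNA pairs with target annotations")
  ratio <- vapply(seq_len(nrow(pairs)), function(i) {
    overlap_ratio(targets_of[[pairs[i, 1]]], targets_of[[pairs[i, 2]]])
  }, numeric(1))
  keep <- ratio > large | ratio < small
  pairs <- pairs[keep, , drop = FALSE]
  is_large <- ratio[keep] > large
  if (length(unique(is_large)) < 2) {
    stop("need pairs in both overlap classes")
  }
  list(pairs = pairs, is_large = is_large)
}

contingency_result <- function(row_flag, col_flag, row_labels, yates) {
  tab <- matrix(c(sum(row_flag & col_flag), sum(row_flag & !col_flag),
                  sum(!row_flag & col_flag), sum(!row_flag & !col_flag)),
                2, 2, byrow = TRUE,
                dimnames = list(row_labels, c("positive_edge", "no_edge")))
  ct <- chi_square(tab, yates = yates)
  list(table = tab, statistic = ct$statistic, p = ct$p,
       proportions = tab[, 1] / rowSums(tab))
}

#' miRNA pairs cotargeted by a common pathway
#'
#' Lists every unordered pair of miRNAs that is jointly positively or
#' jointly negatively connected to at least one common pathway, with the
#' shared pathways annotated.
#'
#' @param net A [signed_network()].
#' @return Data frame with columns `mirna1`, `mirna2`, `pathways`
#'   (`;`-separated) and `n_shared`.
#' @export
pathway_cotarget_pairs <- function(net) {
  types <- setNames(net$nodes$type, net$nodes$id)
  e <- net$edges
  empty <- data.frame(mirna1 = character(), mirna2 = character(),
                      pathways = character(), n_shared = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(e) == 0) return(empty)
  mp <- e[types[e$a] != types[e$b], , drop = FALSE]
  if (nrow(mp) == 0) return(empty)
  mp$pathway <- ifelse(types[mp$a] == "pathway", mp$a, mp$b)
  mp$mirna <- ifelse(types[mp$a] == "pathway", mp$b, mp$a)
  shared <- list()
  for (p in unique(mp$pathway)) {
    for (s in c("+", "-")) {
      ms <- sort(mp$mirna[mp$pathway == p & mp$sign == s])
      if (length(ms) < 2) next
      pr <- t(combn(ms, 2))
      for (i in seq_len(nrow(pr))) {
        key <- paste(pr[i, 1], pr[i, 2])
        shared[[key]] <- unique(c(shared[[key]], p))
      }
    }
  }
  if (length(shared) == 0) return(empty)
  keys <- names(shared)
  parts <- strsplit(keys, " ", fixed = TRUE)
  data.frame(mirna1 = vapply(parts, `[`, character(1), 1),
             mirna2 = vapply(parts, `[`, character(1), 2),
             pathways = vapply(shared, function(x)
               paste(sort(x), collapse = ";"), character(1)),
             n_shared = lengths(shared), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Genomic-cluster enrichment among pathway-cotargeted miRNA pairs
#'
#' Tests whether miRNA pairs from the same genomic cluster are more likely
#' to be jointly correlated (same sign) with a common pathway than pairs
#' from different clusters.
#'
#' @param net A [signed_network()].
#' @param cluster_of Named character vector, miRNA -> genomic cluster id.
#' @param yates Continuity correction.
#' @return List with `table` (same/different cluster x cotargeted yes/no),
#'   `statistic`, `p`, `proportions`.
#' @export
cluster_cotargeting_test <- function(net, cluster_of, yates = TRUE) {
  mir <- net$nodes$id[net$nodes$type == "miRNA"]
  mir <- mir[mir %in% names(cluster_of) & !is.na(cluster_of[mir])]
  pairs <- all_pairs(mir)
  if (nrow(pairs) == 0) stop("no annotated miRNA pairs in the network")
  same <- cluster_of[pairs[, 1]] == cluster_of[pairs[, 2]]
  if (length(unique(same)) < 2) {
    stop("need both same-cluster and different-cluster pairs")
  }
  co <- cotarget_lookup(net)
  is_co <- paste(pairs[, 1], pairs[, 2]) %in% co
  res <- contingency_result(same, is_co,
                            c("same_cluster", "different_cluster"), yates)
  colnames(res$table) <- c("cotargeted", "not_cotargeted")
  res
}

#' Target-overlap enrichment among pathway-cotargeted miRNA pairs
#'
#' As [cluster_cotargeting_test()], but rows are the large/small
#' target-overlap classes (intermediate pairs excluded).
#'
#' @inheritParams overlap_redundancy_test
#' @return As [cluster_cotargeting_test()].
#' @export
overlap_cotargeting_test <- function(net, targets_of, large = 0.6,
                                     small = 0.4, yates = TRUE) {
  cls <- overlap_classes(net, targets_of, large, small)
  co <- cotarget_lookup(net)
  is_co <- paste(cls$pairs[, 1], cls$pairs[, 2]) %in% co
  res <- contingency_result(cls$is_large, is_co,
                            c("large_overlap", "small_overlap"), yates)
  colnames(res$table) <- c("cotargeted", "not_cotargeted")
  res
}

cotarget_lookup <- function(net) {
  cp <- pathway_cotarget_pairs(net)
  paste(cp$mirna1, cp$mirna2)
}

#' Global pairwise sequence similarity score
#'
#' Needleman-Wunsch global alignment score between two mature miRNA
#' sequences under a scheme with zero reward for a match and unit penalties
#' for mismatches and gaps (configurable), so identical sequences score
#' exactly 0 and any difference is negative. Alignment is computed with
#' [Biostrings::pairwiseAlignment()].
#'
#' @param seq1,seq2 RNA sequences (strings over A, C, G, U; T is accepted
#'   and read as U).
#' @param match,mismatch,gap Scoring parameters (defaults 0, -1, -1).
#' @return The optimal global alignment score.
#' @export
sequence_similarity <- function(seq1, seq2, match = 0, mismatch = -1,
                                gap = -1) {
  s1 <- normalize_rna(seq1)
  s2 <- normalize_rna(seq2)
  ab <- c("A", "C", "G", "U")
  mat <- matrix(mismatch, 4, 4, dimnames = list(ab, ab))
  diag(mat) <- match
  Biostrings::pairwiseAlignment(
    Biostrings::RNAString(s1), Biostrings::RNAString(s2),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap,
    type = "global", scoreOnly = TRUE)
}

normalize_rna <- function(s) {
  s <- chartr("tu", "TU", toupper(s))
  s <- gsub("T", "U", s, fixed = TRUE)
  if (!nzchar(s)) stop("empty sequence")
  if (grepl("[^ACGU]", s)) {
    stop("invalid character in RNA sequence: ", s)
  }
  s
}

#' Drop sequence-similar miRNA pairs
#'
#' Retains only pairs whose global similarity score is strictly below
#' `threshold` (default -5), removing pairs of closely related sequences
#' whose target-set overlap could be explained by sequence identity alone.
#' Pairs with a missing sequence are dropped with a warning.
#'
#' @param pairs Data frame with columns `mirna1`, `mirna2` (e.g. from
#'   [pathway_cotarget_pairs()]).
#' @param sequences Named character vector of mature sequences.
#' @param threshold Strict retention cutoff on the score.
#' @return The filtered pairs with a `similarity` column appended.
#' @export
filter_dissimilar_pairs <- function(pairs, sequences, threshold = -5) {
  if (nrow(pairs) == 0) {
    pairs$similarity <- numeric(0)
    return(pairs)
  }
  have <- pairs$mirna1 %in% names(sequences) &
    pairs$mirna2 %in% names(sequences)
  if (any(!have)) {
    warning(sum(!have), " pair(s) dropped for missing sequences")
    pairs <- pairs[have, , drop = FALSE]
  }
  pairs$similarity <- vapply(seq_len(nrow(pairs)), function(i) {
    sequence_similarity(sequences[[pairs$mirna1[i]]],
                        sequences[[pairs$mirna2[i]]])
  }, numeric(1))
  out <- pairs[pairs$similarity < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read mature miRNA sequences from a FASTA file
#'
#' @param path Path to a (plain-text) FASTA file of mature RNA sequences.
#' @return Named character vector of sequences; names are the first token
#'   of each FASTA header.
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs
}
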