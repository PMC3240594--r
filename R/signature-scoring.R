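#' Rank-based single-sample activation score
#'
#' For each sample, all `G` genes of the matrix are ranked by expression
#' (ascending, ties receive average ranks) and the score is the difference
#' between the mean rank of the signature's up-genes and the mean rank of
#' its down-genes, divided by `G`. An absent component is replaced by the
#' expected mean rank fraction `(G + 1) / (2G)`, so one-sided signatures
#' remain scoreable. The score is invariant under any strictly monotone
#' per-sample transform of the expression values and flips sign when the up
#' and down sets are swapped.
#'
#' @param mrna Expression matrix (genes x samples).
#' @param sig A [gene_signature()]; genes absent from the matrix are dropped
#'   with a warning, and an error is raised if none remain.
#' @return Named numeric vector of per-sample scores.
#' @export
activation_score <- function(mrna, sig) {
  check_expression_matrix(mrna)
  scores <- score_signatures(mrna, setNames(list(sig), sig$name))
  scores[1, ]
}

#' Score several signatures on one cohort
#'
#' Shared-rank implementation of [activation_score()] for a list of
#' signatures; the gene ranking per sample is computed once.
#'
#' @param mrna Expression matrix (genes x samples).
#' @param sigs Named list of [gene_signature()] objects.
#' @return Score matrix, signatures x samples.
#' @export
score_signatures <- function(mrna, sigs) {
  check_expression_matrix(mrna)
  if (length(sigs) == 0) stop("no signatures to score")
  if (is.null(names(sigs))) {
    names(sigs) <- vapply(sigs, `[[`, character(1), "name")
  }
  G <- nrow(mrna)
  R <- apply(mrna, 2, rank) / G
  expected <- (G + 1) / (2 * G)
  out <- matrix(NA_real_, length(sigs), ncol(mrna),
                dimnames = list(names(sigs), colnames(mrna)))
  for (i in seq_along(sigs)) {
    sig <- sigs[[i]]
    up <- intersect(sig$up, rownames(mrna))
    dn <- intersect(sig$down, rownames(mrna))
    missing <- signature_size(sig) - length(up) - length(dn)
    if (missing > 0) {
      warning(sprintf("signature '%s': %d gene(s) absent from the matrix",
                      sig$name, missing))
    }
    if (length(up) + length(dn) == 0) {
      stop("no gene of signature '", sig$name, "' is present in the matrix")
    }
    up_term <- if (length(up) > 0) {
      colMeans(R[up, , drop = FALSE])
    } else rep(expected, ncol(mrna))
    dn_term <- if (length(dn) > 0) {
      colMeans(R[dn, , drop = FALSE])
    } else rep(expected, ncol(mrna))
    out[i, ] <- up_term - dn_term
  }
  out
}

#' Spearman correlation with closed-form p-value
#'
#' The correlation is the Pearson correlation of the (average-tie) ranks;
#' the two-sided p-value comes from the Student t distribution via
#' `t = R / sqrt((1 - R^2) / (N - 2))` with `N - 2` degrees of freedom.
#' `|R| = 1` yields `p = 0`; a constant vector yields `NA` for both.
#'
#' @param x,y Numeric vectors of equal length `N >= 3`; ties allowed.
#' @return List with elements `R` and `p`.
#' @export
spearman_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) return(list(R = NA_real_, p = NA_real_))
  r <- cor(rank(x), rank(y))
  list(R = r, p = spearman_p(r, length(x)))
}

# vectorizable closed-form p for a Spearman/rank correlation
spearman_p <- function(r, n) {
  p <- rep(NA_real_, length(r))
  one <- !is.na(r) & abs(r) >= 1 - 1e-12
  p[one] <- 0
  ok <- !is.na(r) & !one
  tt <- r[ok] / sqrt((1 - r[ok]^2) / (n - 2))
  p[ok] <- 2 * pt(-abs(tt), df = n - 2)
  p
}

#' Validate signature scores against measured miRNA expression
#'
#' For every miRNA with both a score row and a measured expression row, the
#' Spearman correlation between the score and the measured values across
#' shared samples is computed; p-values are Benjamini-Hochberg adjusted
#' across the tested miRNAs, and a signature passes when `R > 0` and
#' `q < q_threshold`.
#'
#' @param scores Score matrix (signatures x samples), rows named by miRNA.
#' @param mirna Measured miRNA expression matrix (miRNAs x samples).
#' @param q_threshold Passing q-value cutoff (paper default 0.25).
#' @return Data frame (`mirna`, `R`, `p`, `q`, `pass`) with attributes
#'   `n_pass` and `frac_pass`.
#' @export
validate_signatures <- function(scores, mirna, q_threshold = 0.25) {
  shared_m <- intersect(rownames(scores), rownames(mirna))
  shared_s <- intersect(colnames(scores), colnames(mirna))
  if (length(shared_s) < 3) stop("need at least 3 shared samples")
  if (length(shared_m) == 0) stop("no shared miRNA identifiers")
  res <- lapply(shared_m, function(m) {
    sp <- spearman_with_p(scores[m, shared_s], mirna[m, shared_s])
    data.frame(mirna = m, R = sp$R, p = sp$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out$pass <- !is.na(out$R) & out$R > 0 & out$q < q_threshold
  attr(out, "n_pass") <- sum(out$pass)
  attr(out, "frac_pass") <- mean(out$pass)
  out
}

#' Global label-scramble permutation test for signature validation
#'
#' Scrambles the assignment of signatures to miRNAs (not the sample labels)
#' `n_perm` times, recomputes the number of validated signatures
#' (`R > 0`, `q < q_threshold` after per-permutation BH adjustment) each
#' time, and reports `p = #\{null count >= actual count\} / n_perm`
#' (ties count against significance; the attainable minimum is
#' `1 / n_perm`).
#'
#' @inheritParams validate_signatures
#' @param n_perm Number of label permutations (paper default 10000).
#' @param seed Integer seed.
#' @return List with `p_value`, `actual_count`, `null_counts` (length
#'   `n_perm`), and `n_tested`.
#' @export
global_permutation_test <- function(scores, mirna, n_perm = 10000,
                                    seed = 1L, q_threshold = 0.25) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  shared_m <- intersect(rownames(scores), rownames(mirna))
  if (length(shared_m) < 2) stop("need at least 2 shared miRNAs")
  shared_s <- intersect(colnames(scores), colnames(mirna))
  if (length(shared_s) < 3) stop("need at least 3 shared samples")
  n <- length(shared_s)
  # all score-row x miRNA-row rank correlations once; a permutation of the
  # signature labels then just re-pairs rows of this matrix
  rs <- t(apply(scores[shared_m, shared_s, drop = FALSE], 1, rank))
  rm_ <- t(apply(mirna[shared_m, shared_s, drop = FALSE], 1, rank))
  C <- suppressWarnings(cor(t(rs), t(rm_)))
  P <- matrix(spearman_p(as.vector(C), n), nrow(C), ncol(C))
  m <- length(shared_m)
  count_pass <- function(idx) {
    r <- C[cbind(idx, seq_len(m))]
    p <- P[cbind(idx, seq_len(m))]
    q <- p.adjust(p, method = "BH")
    sum(!is.na(r) & r > 0 & q < q_threshold)
  }
  actual <- count_pass(seq_len(m))
  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) count_pass(sample(m)), numeric(1))
  })
  list(p_value = sum(null_counts >= actual) / n_perm,
       actual_count = actual, null_counts = null_counts, n_tested = m)
}
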