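#' Split samples into miRNA-high and miRNA-low groups
#'
#' Samples at or above the `pct_high` percentile of the miRNA's expression
#' form the high group, samples at or below the `pct_low` percentile the low
#' group. Percentiles use linear interpolation between order statistics
#' (R's default quantile type). A split is eligible only when both groups
#' have at least `min_n` members and are disjoint; near-constant vectors are
#' ineligible because the two thresholds coincide.
#'
#' @param x Named numeric vector of per-sample miRNA expression (>= 6
#'   samples).
#' @param pct_high,pct_low High/low percentile cutoffs (defaults 80/20).
#' @param min_n Minimum group size (default 3).
#' @return A list with elements `high`, `low` (sample id vectors),
#'   `eligible` (logical) and `reason` (character, when ineligible).
#' @export
split_high_low <- function(x, pct_high = 80, pct_low = 20, min_n = 3) {
  if (length(x) < 6) stop("need at least 6 samples to split")
  if (is.null(names(x))) names(x) <- paste0("S", seq_along(x))
  hi_thr <- quantile(x, pct_high / 100, names = FALSE, type = 7)
  lo_thr <- quantile(x, pct_low / 100, names = FALSE, type = 7)
  high <- names(x)[x >= hi_thr]
  low <- names(x)[x <= lo_thr]
  out <- list(high = high, low = low, eligible = TRUE, reason = NA_character_)
  if (length(intersect(high, low)) > 0) {
    out$eligible <- FALSE
    out$reason <- "high and low groups overlap (degenerate expression vector)"
  } else if (length(high) < min_n || length(low) < min_n) {
    out$eligible <- FALSE
    out$reason <- sprintf("group below minimum size %d (high %d, low %d)",
                          min_n, length(high), length(low))
  }
  out
}

#' Moderated t-test between two sample groups
#'
#' Gene-wise two-sample comparison with empirical-Bayes variance shrinkage:
#' the pooled within-group variance of each gene is squeezed towards a
#' common prior (hyperparameters `d0`, `s0sq` estimated from the observed
#' variances via [limma::squeezeVar()] unless supplied), the moderated t
#' statistic uses the posterior variance, and p-values come from a t
#' distribution with `d0 + d_g` degrees of freedom. Genes with zero pooled
#' variance are assigned the smallest positive observed variance before
#' shrinkage. q-values are Benjamini-Hochberg adjusted across genes.
#'
#' @param mrna Expression matrix (genes x samples).
#' @param high,low Disjoint sample id vectors, each of length >= 2.
#' @param d0,s0sq Optional prior degrees of freedom and prior variance;
#'   `d0 = 0` recovers the ordinary pooled t-test, `d0 = Inf` a
#'   common-variance test.
#' @return Data frame with columns `gene`, `mean_diff` (high minus low, log
#'   units), `t_mod`, `df_total`, `p`, `q`; hyperparameters are attached as
#'   attributes `d0` and `s0sq`.
#' @export
moderated_t_test <- function(mrna, high, low, d0 = NULL, s0sq = NULL) {
  check_expression_matrix(mrna)
  if (nrow(mrna) < 2) stop("hyperparameter estimation needs at least 2 genes")
  if (length(high) < 2 || length(low) < 2) {
    stop("both groups need at least 2 samples")
  }
  if (length(intersect(high, low)) > 0) stop("groups must be disjoint")
  res <- mod_t_core(mrna[, high, drop = FALSE], mrna[, low, drop = FALSE],
                    d0 = d0, s0sq = s0sq)
  out <- data.frame(gene = rownames(mrna), mean_diff = res$mean_diff,
                    t_mod = res$t, df_total = res$df_total, p = res$p,
                    q = p.adjust(res$p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- res$d0
  attr(out, "s0sq") <- res$s0sq
  out
}

# vectorized core shared with the permutation loop
mod_t_core <- function(x1, x0, d0 = NULL, s0sq = NULL) {
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  ss1 <- rowSums((x1 - m1)^2); ss0 <- rowSums((x0 - m0)^2)
  dg <- n1 + n0 - 2
  s2 <- (ss1 + ss0) / dg
  pos <- s2 > 0
  if (!all(pos)) {
    if (!any(pos)) stop("all genes have zero pooled variance")
    s2[!pos] <- min(s2[pos])
  }
  if (is.null(d0)) {
    sq <- limma::squeezeVar(s2, df = dg)
    d0 <- sq$df.prior
    s0sq <- sq$var.prior
    post <- sq$var.post
  } else {
    if (is.null(s0sq)) s0sq <- mean(s2)
    post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else {
      (d0 * s0sq + dg * s2) / (d0 + dg)
    }
  }
  mean_diff <- m1 - m0
  tt <- mean_diff / sqrt(post * (1 / n1 + 1 / n0))
  df_total <- d0 + dg
  p <- 2 * pt(-abs(tt), df = df_total)
  list(mean_diff = mean_diff, t = tt, p = p, d0 = d0, s0sq = s0sq,
       df_total = df_total)
}

# signature size at threshold alpha for a given split (permutation workhorse)
signature_size_for_split <- function(mrna, high, low, alpha, adjust) {
  res <- mod_t_core(mrna[, high, drop = FALSE], mrna[, low, drop = FALSE])
  pv <- if (adjust) p.adjust(res$p, method = "BH") else res$p
  sum(pv < alpha)
}

#' Derive a miRNA gene-expression signature
#'
#' Splits the cohort's samples by the measured expression of one miRNA
#' (80th/20th percentiles, minimum group size 3), runs the moderated t-test
#' on the mRNA matrix, and keeps genes significant at `alpha`
#' (Benjamini-Hochberg adjusted by default): up-genes are higher in the
#' miRNA-high group, down-genes lower. Returns `NULL` (a skipped miRNA, not
#' an error) when the split is ineligible.
#'
#' @param cohort A [cohort()] with paired `mrna` and `mirna` matrices.
#' @param mirna miRNA identifier (row of `cohort$mirna`).
#' @param alpha Significance level (paper default 1e-4).
#' @param adjust Apply the threshold to BH-adjusted values (default) rather
#'   than nominal p-values.
#' @param pct_high,pct_low,min_n Passed to [split_high_low()].
#' @return A [gene_signature()] (possibly empty), or `NULL` if ineligible.
#' @export
derive_signature <- function(cohort, mirna, alpha = 1e-4, adjust = TRUE,
                             pct_high = 80, pct_low = 20, min_n = 3) {
  stopifnot(inherits(cohort, "mir_cohort"), !is.null(cohort$mirna))
  if (!mirna %in% rownames(cohort$mirna)) stop("unknown miRNA: ", mirna)
  sp <- split_high_low(cohort$mirna[mirna, ], pct_high, pct_low, min_n)
  if (!sp$eligible) return(NULL)
  res <- moderated_t_test(cohort$mrna, sp$high, sp$low)
  crit <- if (adjust) res$q else res$p
  gene_signature(mirna,
                 up = res$gene[crit < alpha & res$mean_diff > 0],
                 down = res$gene[crit < alpha & res$mean_diff < 0],
                 source = "derived_miRNA")
}

#' Permutation robustness test for a derived signature
#'
#' Shuffles the high/low labels over the union of the two groups (group
#' sizes preserved) `n_perm` times, recomputes the signature size at the
#' same threshold each time, and reports
#' `fdr = #\{permuted size > actual size\} / n_perm` (strict inequality).
#' A signature is retained when `fdr` is below `fdr_threshold`.
#'
#' @param mrna Expression matrix used for the derivation.
#' @param split An eligible split from [split_high_low()].
#' @param actual_size Size of the actually derived signature; computed from
#'   the split when missing.
#' @param alpha,adjust Thresholding as in [derive_signature()].
#' @param n_perm Number of permutations (paper default 1000).
#' @param fdr_threshold Retention cutoff (paper default 0.05).
#' @param seed Integer seed.
#' @return List with `actual_size`, `permuted_sizes`, `fdr`, `retained`.
#' @export
robustness_test <- function(mrna, split, actual_size = NULL, alpha = 1e-4,
                            adjust = TRUE, n_perm = 1000,
                            fdr_threshold = 0.05, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  stopifnot(isTRUE(split$eligible))
  if (is.null(actual_size)) {
    actual_size <- signature_size_for_split(mrna, split$high, split$low,
                                            alpha, adjust)
  }
  pool <- c(split$high, split$low)
  n_hi <- length(split$high)
  sub <- mrna[, pool, drop = FALSE]
  sizes <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample(length(pool), n_hi)
      signature_size_for_split(sub, pool[idx], pool[-idx], alpha, adjust)
    }, numeric(1))
  })
  fdr <- sum(sizes > actual_size) / n_perm
  list(actual_size = actual_size, permuted_sizes = sizes, fdr = fdr,
       retained = fdr < fdr_threshold)
}

#' Derive and robustness-filter signatures for every miRNA in a cohort
#'
#' Runs the full derivation funnel: eligibility of the 80/20 split, signature
#' derivation at `alpha`, and the permutation robustness filter for every
#' non-empty signature. Counts are monotone along the funnel
#' (robust <= derived <= eligible <= total).
#'
#' @inheritParams derive_signature
#' @inheritParams robustness_test
#' @param seed Integer seed; each miRNA's permutations use an offset
#'   substream.
#' @return List with `signatures` (retained [gene_signature()]s) and
#'   `report` (data frame: `mirna`, `eligible`, `size`, `fdr`, `retained`).
#' @export
derive_all_signatures <- function(cohort, alpha = 1e-4, adjust = TRUE,
                                  pct_high = 80, pct_low = 20, min_n = 3,
                                  n_perm = 1000, fdr_threshold = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(cohort, "mir_cohort"), !is.null(cohort$mirna))
  mirnas <- rownames(cohort$mirna)
  report <- data.frame(mirna = mirnas, eligible = FALSE, size = 0L,
                       fdr = NA_real_, retained = FALSE,
                       stringsAsFactors = FALSE)
  signatures <- list()
  for (i in seq_along(mirnas)) {
    m <- mirnas[i]
    sp <- split_high_low(cohort$mirna[m, ], pct_high, pct_low, min_n)
    if (!sp$eligible) next
    report$eligible[i] <- TRUE
    sig <- derive_signature(cohort, m, alpha, adjust, pct_high, pct_low,
                            min_n)
    report$size[i] <- signature_size(sig)
    if (signature_size(sig) == 0) next  # nothing above threshold
    rb <- robustness_test(cohort$mrna, sp, actual_size = signature_size(sig),
                          alpha = alpha, adjust = adjust, n_perm = n_perm,
                          fdr_threshold = fdr_threshold,
                          seed = seed_stream(seed, i))
    report$fdr[i] <- rb$fdr
    report$retained[i] <- rb$retained
    if (rb$retained) signatures[[m]] <- sig
  }
  list(signatures = signatures, report = report)
}

# derive a bounded substream seed from a base seed and an index
seed_stream <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647L)
}
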