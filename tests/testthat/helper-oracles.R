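# Independent oracles used to cross-check the package implementations.

# Two-sided Fisher p by direct enumeration over all tables with the
# observed margins: sum the hypergeometric point masses of tables no more
# probable than the observed one.
brute_force_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
  }, numeric(1))
  obs <- probs[a_range == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Ordinary two-sample pooled-variance t-test, gene-wise.
pooled_t_oracle <- function(x1, x0) {
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)) / (n1 + n0 - 2)
  tt <- (m1 - m0) / sqrt(s2 * (1 / n1 + 1 / n0))
  list(t = tt, p = 2 * pt(-abs(tt), df = n1 + n0 - 2))
}

# Step-up Benjamini-Hochberg written directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Needleman-Wunsch global alignment score by dynamic programming.
nw_oracle <- function(s1, s2, match = 0, mismatch = -1, gap = -1) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * (0:n); D[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (a[i] == b[j]) match else mismatch
    D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap, D[i + 1, j] + gap)
  }
  D[n + 1, m + 1]
}

# Small helper: a named expression matrix filled with N(0, 1) noise.
random_expr <- function(n_genes, n_samples, prefix = "G", sd = 1) {
  expression_matrix(matrix(rnorm(n_genes * n_samples, sd = sd), n_genes,
                           n_samples),
                    feature_ids = sprintf("%s%03d", prefix, seq_len(n_genes)),
                    sample_ids = sprintf("S%03d", seq_len(n_samples)))
}

# Tiny deterministic network fixture: 4 miRNAs, 2 pathways.
fixture_network <- function() {
  nodes <- data.frame(id = c("mirA", "mirB", "mirC", "mirD", "PW1", "PW2"),
                      type = c(rep("miRNA", 4), rep("pathway", 2)))
  edges <- data.frame(
    a = c("mirA", "mirA", "mirB", "mirC", "mirA"),
    b = c("mirB", "PW1", "PW1", "PW2", "mirC"),
    sign = c("+", "+", "+", "-", "-"),
    support_count = c(3L, 5L, 4L, 2L, 1L),
    stringsAsFactors = FALSE)
  signed_network(nodes, edges)
}
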