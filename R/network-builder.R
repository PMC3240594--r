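#' Storey q-values
#'
#' Estimates the null proportion `pi0` as the median over the lambda grid
#' of `#\{p > lambda\} / (m (1 - lambda))`, clipped to (0, 1], and applies
#' the step-up transformation `q_(i) = pi0 * m * p_(i) / i` with
#' monotonization. Forcing `pi0 = 1` reproduces Benjamini-Hochberg exactly.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param lambda Grid for the `pi0` estimator.
#' @param pi0 Optional fixed null proportion overriding the estimator.
#' @return Vector of q-values, same order as `p`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                          pi0 = NULL) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- median(vapply(lambda,
                         function(l) mean(p > l, na.rm = TRUE) / (1 - l),
                         numeric(1)))
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out[is.na(p)] <- NA_real_
  out
}

#' Pairwise Spearman correlations among score rows of one cohort
#'
#' Computes the Spearman correlation, closed-form p-value, Storey q-value
#' (within the cohort), and sign call for every unordered pair of score
#' rows. A pair is called `"+"`/`"-"` when `q < fdr` with the corresponding
#' sign, `"ns"` otherwise; pairs involving a constant score vector carry
#' `NA` statistics and an `"ns"` call.
#'
#' @param scores Score matrix (entities x samples) for one cohort with at
#'   least 3 samples.
#' @param cohort Cohort name recorded in the output.
#' @param fdr Significance threshold on the q-value (paper default 0.05).
#' @return Data frame with columns `a`, `b`, `cohort`, `R`, `p`, `q`,
#'   `call`.
#' @export
pairwise_correlations <- function(scores, cohort = "cohort", fdr = 0.05) {
  if (ncol(scores) < 3) stop("need at least 3 samples")
  if (nrow(scores) < 2) stop("need at least 2 score rows")
  n <- ncol(scores)
  ranks <- t(apply(scores, 1, rank))
  C <- suppressWarnings(cor(t(ranks)))
  idx <- which(upper.tri(C), arr.ind = TRUE)
  R <- C[idx]
  p <- spearman_p(R, n)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- storey_qvalue(p[ok])
  call <- rep("ns", length(p))
  sig <- ok & q < fdr
  call[sig & R > 0] <- "+"
  call[sig & R < 0] <- "-"
  data.frame(a = rownames(scores)[idx[, 1]], b = rownames(scores)[idx[, 2]],
             cohort = cohort, R = R, p = p, q = q, call = call,
             stringsAsFactors = FALSE)
}

#' Aggregate signature-level calls to pathway-level calls
#'
#' Signatures assigned to a pathway are collapsed per partner entity and
#' cohort: the pathway-partner association carries a sign when at least one
#' member signature is significantly correlated with the partner and no two
#' member signatures are significant with opposite signs; significantly
#' discordant members yield `"conflict"` (treated as no call downstream);
#' otherwise `"ns"`. The rule is applied symmetrically, so pathway-pathway
#' associations aggregate the member signatures of both sides.
#'
#' @param records Output of [pairwise_correlations()] (one or more cohorts).
#' @param assignment Data frame mapping `signature` to `pathway`; every
#'   signature name appearing in `records` that is not listed is treated as
#'   a miRNA entity of its own.
#' @return Data frame with columns `a`, `b` (entity names, `a < b`),
#'   `cohort`, `call` (`"+"`, `"-"`, `"ns"`, `"conflict"`), and `R` (the
#'   member correlation of largest magnitude among significant members, else
#'   `NA`).
#' @export
aggregate_pathway <- function(records, assignment) {
  ent <- setNames(assignment$pathway, assignment$signature)
  entity_of <- function(x) ifelse(x %in% names(ent), ent[x], x)
  ea <- entity_of(records$a)
  eb <- entity_of(records$b)
  swap <- ea > eb
  a <- ifelse(swap, eb, ea)
  b <- ifelse(swap, ea, eb)
  keep <- a != b  # drop within-pathway signature pairs
  df <- data.frame(a = a[keep], b = b[keep], cohort = records$cohort[keep],
                   call = records$call[keep], R = records$R[keep],
                   stringsAsFactors = FALSE)
  key <- paste(df$a, df$b, df$cohort, sep = "\r")
  out <- lapply(split(df, key), function(g) {
    sig <- g$call %in% c("+", "-")
    call <- if (!any(sig)) "ns"
    else if (length(unique(g$call[sig])) > 1) "conflict"
    else unique(g$call[sig])
    R <- if (any(sig)) g$R[sig][which.max(abs(g$R[sig]))] else NA_real_
    data.frame(a = g$a[1], b = g$b[1], cohort = g$cohort[1], call = call,
               R = R, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Merge per-cohort calls into a signed cross-cohort network
#'
#' An edge is emitted when some cohort calls the association with a sign and
#' no cohort calls it with the opposite sign (discordant associations are
#' discarded); `support_count` is the number of concordant cohorts, and the
#' per-cohort calls are retained as `call.<cohort>` columns. When
#' `require_cohort` is given, miRNA-pathway edges must additionally be
#' called in that cohort (the paper restricts miRNA-pathway associations to
#' those present in the cell-line cohort to allow in vitro follow-up).
#' Within-cohort conflicts count as no call. The merge is order-invariant
#' over cohorts.
#'
#' @param calls Aggregated calls from [aggregate_pathway()] (or raw
#'   signature-level records with columns `a`, `b`, `cohort`, `call`, `R`).
#' @param node_types Named character vector, entity id -> `"miRNA"` or
#'   `"pathway"`.
#' @param require_cohort Optional cohort name applied to miRNA-pathway
#'   edges.
#' @param keep_isolated Keep nodes without any edge (default drops them).
#' @return A [signed_network()]; edge `R` is the mean member correlation
#'   over supporting cohorts.
#' @export
cross_cohort_merge <- function(calls, node_types, require_cohort = NULL,
                               keep_isolated = FALSE) {
  cohorts <- sort(unique(calls$cohort))
  key <- paste(calls$a, calls$b, sep = "\r")
  edges <- lapply(split(calls, key), function(g) {
    signs <- g$call[g$call %in% c("+", "-")]
    if (length(signs) == 0 || length(unique(signs)) > 1) return(NULL)
    s <- signs[1]
    is_mp <- length(unique(node_types[c(g$a[1], g$b[1])])) == 2
    if (!is.null(require_cohort) && is_mp) {
      rc <- g$call[g$cohort == require_cohort]
      if (length(rc) == 0 || rc != s) return(NULL)
    }
    per <- setNames(rep("ns", length(cohorts)), cohorts)
    per[g$cohort] <- ifelse(g$call == "conflict", "ns", g$call)
    row <- data.frame(a = g$a[1], b = g$b[1], sign = s,
                      support_count = sum(g$call == s),
                      R = mean(g$R[g$call == s], na.rm = TRUE),
                      stringsAsFactors = FALSE)
    for (cn in cohorts) row[[paste0("call.", cn)]] <- per[[cn]]
    row
  })
  edges <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  if (is.null(edges)) {
    edges <- data.frame(a = character(), b = character(), sign = character(),
                        support_count = integer(), R = numeric(),
                        stringsAsFactors = FALSE)
  }
  ids <- if (keep_isolated) names(node_types) else {
    intersect(names(node_types), unique(c(edges$a, edges$b)))
  }
  net <- signed_network(
    nodes = data.frame(id = ids, type = unname(node_types[ids]),
                       stringsAsFactors = FALSE),
    edges = edges)
  net
}

#' Nominate candidate upstream pathway modulators
#'
#' Selects miRNAs positively connected to the pathway in every cohort
#' (`support_count == n_cohorts`) whose expression is unaffected by a
#' knockdown of the pathway (`p >= 0.05` in the knockdown table), i.e.
#' miRNAs more plausibly acting upstream of the pathway than downstream of
#' it. Results are ordered by support then by correlation magnitude.
#'
#' @param net A [signed_network()].
#' @param pathway Pathway node id.
#' @param knockdown Data frame with columns `mirna` and `p` (e.g. from
#'   [generate_knockdown_table()]).
#' @param n_cohorts Number of cohorts in the merge.
#' @return Character vector of nominated miRNA ids.
#' @export
nominate_modulators <- function(net, pathway, knockdown, n_cohorts) {
  stopifnot(inherits(net, "signed_network"))
  if (!pathway %in% net$nodes$id) stop("unknown pathway: ", pathway)
  e <- net$edges
  e <- e[(e$a == pathway | e$b == pathway) & e$sign == "+" &
           e$support_count == n_cohorts, , drop = FALSE]
  if (nrow(e) == 0) return(character())
  e$mirna <- ifelse(e$a == pathway, e$b, e$a)
  types <- setNames(net$nodes$type, net$nodes$id)
  e <- e[types[e$mirna] == "miRNA", , drop = FALSE]
  kd <- setNames(knockdown$p, knockdown$mirna)
  unaffected <- !is.na(kd[e$mirna]) & kd[e$mirna] >= 0.05
  e <- e[unaffected, , drop = FALSE]
  e <- e[order(-e$support_count, -abs(e$R)), , drop = FALSE]
  e$mirna
}

#' Build the signed miRNA-pathway network from per-cohort score matrices
#'
#' Convenience wrapper: per-cohort pairwise Spearman correlations with
#' Storey FDR control, aggregation of pathway member signatures, and the
#' cross-cohort concordance merge.
#'
#' @param score_list Named list of per-cohort score matrices whose rows are
#'   miRNA signature names and pathway member signature names.
#' @param assignment Data frame mapping `signature` to `pathway`.
#' @param fdr Within-cohort significance threshold (default 0.05).
#' @param require_cohort Optional cohort required for miRNA-pathway edges.
#' @param keep_isolated Passed to [cross_cohort_merge()].
#' @return List with `network` ([signed_network()]), `records` (per-cohort
#'   signature-level correlations) and `calls` (aggregated entity calls).
#' @export
build_network <- function(score_list, assignment, fdr = 0.05,
                          require_cohort = NULL, keep_isolated = FALSE) {
  records <- do.call(rbind, lapply(names(score_list), function(cn) {
    pairwise_correlations(score_list[[cn]], cohort = cn, fdr = fdr)
  }))
  calls <- aggregate_pathway(records, assignment)
  entities <- unique(c(calls$a, calls$b))
  node_types <- setNames(
    ifelse(entities %in% assignment$pathway, "pathway", "miRNA"), entities)
  net <- cross_cohort_merge(calls, node_types, require_cohort,
                            keep_isolated)
  list(network = net, records = records, calls = calls)
}
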