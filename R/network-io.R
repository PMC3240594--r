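#' Construct a signed miRNA-pathway network
#'
#' Nodes are typed (`"miRNA"` or `"pathway"`); edges are undirected and carry
#' a single sign, the number of supporting cohorts, and the per-cohort calls.
#' Edge endpoints are stored in canonical order (`a < b`); self-edges are
#' rejected.
#'
#' @param nodes Data frame with columns `id` and `type`.
#' @param edges Data frame with columns `a`, `b`, `sign` (`"+"` or `"-"`),
#'   `support_count`, optionally `R` (mean correlation over supporting
#'   cohorts) and per-cohort call columns named `call.<cohort>` holding
#'   `"+"`, `"-"` or `"ns"`.
#' @return An object of class `"signed_network"`.
#' @export
signed_network <- function(nodes, edges) {
  nodes <- data.frame(id = as.character(nodes$id),
                      type = as.character(nodes$type),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(nodes$type %in% c("miRNA", "pathway"))) {
    stop("node types must be 'miRNA' or 'pathway'")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (any(edges$a == edges$b)) stop("self-edges are not allowed")
    flip <- edges$a > edges$b
    tmp <- edges$a[flip]; edges$a[flip] <- edges$b[flip]; edges$b[flip] <- tmp
    if (!all(edges$sign %in% c("+", "-"))) stop("edge signs must be '+' or '-'")
    key <- paste(edges$a, edges$b)
    if (anyDuplicated(key)) stop("an edge may carry only one sign")
    if (!all(c(edges$a, edges$b) %in% nodes$id)) {
      stop("edge endpoints missing from node table")
    }
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d nodes (%d miRNA, %d pathway), %d edges (%d +, %d -)\n",
              nrow(x$nodes), sum(x$nodes$type == "miRNA"),
              sum(x$nodes$type == "pathway"), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  invisible(x)
}

#' Write a signed network as an edge-list TSV
#'
#' Columns: `a`, `b`, `type_a`, `type_b`, `sign`, `support_count`, then any
#' further edge columns (mean correlation, per-cohort calls).
#'
#' @param net A [signed_network()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  type_of <- setNames(net$nodes$type, net$nodes$id)
  e <- net$edges
  base <- data.frame(a = character(0), b = character(0),
                     type_a = character(0), type_b = character(0),
                     sign = character(0), support_count = integer(0),
                     stringsAsFactors = FALSE)
  if (nrow(e) > 0) {
    extra <- e[, setdiff(colnames(e), c("a", "b", "sign", "support_count")),
               drop = FALSE]
    base <- data.frame(a = e$a, b = e$b,
                       type_a = unname(type_of[e$a]),
                       type_b = unname(type_of[e$b]),
                       sign = e$sign, support_count = e$support_count,
                       extra, check.names = FALSE, stringsAsFactors = FALSE)
  }
  write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signed network from an edge-list TSV
#'
#' Nodes are reconstructed from edge endpoints; isolated nodes are not
#' representable in an edge list and are therefore absent after a round
#' trip.
#'
#' @param path Path to a TSV written by [write_network()].
#' @return A [signed_network()].
#' @export
read_network <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  nodes <- unique(data.frame(
    id = c(df$a, df$b), type = c(df$type_a, df$type_b),
    stringsAsFactors = FALSE))
  edges <- df[, setdiff(colnames(df), c("type_a", "type_b")), drop = FALSE]
  signed_network(nodes, edges)
}
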