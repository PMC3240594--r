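#' Convert a signed network to an igraph object
#'
#' Drops signs and keeps the simple undirected topology, the representation
#' used by all topology statistics.
#'
#' @param net A [signed_network()] or an igraph object (returned as is).
#' @return An undirected simple igraph graph.
#' @export
as_topology_graph <- function(net) {
  if (igraph::is_igraph(net)) return(net)
  stopifnot(inherits(net, "signed_network"))
  g <- igraph::graph_from_data_frame(net$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = net$nodes$id)
  igraph::simplify(g)
}

#' Node clustering coefficients
#'
#' `C_i = 2 n_i / (k_i (k_i - 1))` where `n_i` counts the edges among the
#' `k_i` neighbors of node `i`; nodes of degree < 2 get `C_i = 0`. The graph
#' coefficient `C_S` is the mean over all nodes.
#'
#' @param g An igraph graph or [signed_network()].
#' @return List with `local` (per-node vector) and `mean` (`C_S`).
#' @export
clustering_coefficient <- function(g) {
  g <- as_topology_graph(g)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(ci) <- igraph::V(g)$name
  list(local = ci, mean = mean(ci))
}

#' Characteristic path length
#'
#' Average of breadth-first shortest-path distances. By default the average
#' runs over all `n^2` ordered node pairs including the zero-distance
#' self-pairs, the convention under which a dense random graph with edge
#' density `p` has expected length `(2 - p)(n - 1)/n`; set
#' `include_self = FALSE` for the pairs-only convention.
#'
#' @param g An igraph graph or [signed_network()].
#' @param include_self Include self-pairs at distance 0 (default `TRUE`).
#' @param largest_component Restrict to the largest connected component
#'   instead of raising an error on disconnected graphs.
#' @return The characteristic path length.
#' @export
characteristic_path_length <- function(g, include_self = TRUE,
                                       largest_component = FALSE) {
  g <- as_topology_graph(g)
  if (!igraph::is_connected(g)) {
    if (!largest_component) {
      comp <- igraph::components(g)
      stop("graph is disconnected (", comp$no, " components of sizes ",
           paste(comp$csize, collapse = ", "), ")")
    }
    g <- largest_comp(g)
  }
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  if (include_self) sum(d) / n^2 else sum(d) / (n * (n - 1))
}

largest_comp <- function(g) {
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership ==
                                      which.max(comp$csize)))
}

#' Erdos-Renyi random graph
#'
#' G(n, p): each unordered node pair is connected independently with
#' probability `p`.
#'
#' @param n Number of nodes (>= 2).
#' @param p Edge probability in (0, 1].
#' @param seed Optional integer seed.
#' @return An igraph graph.
#' @export
erdos_renyi <- function(n, p, seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  gen <- function() igraph::sample_gnp(n, p)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Erdos-Renyi null ensemble summaries
#'
#' Generates `n_graphs` G(n, p) graphs and summarizes the clustering
#' coefficient, the characteristic path length (self-pair convention,
#' largest component if needed), and the realized mean degree, each as
#' ensemble mean and standard deviation.
#'
#' @inheritParams erdos_renyi
#' @param n_graphs Ensemble size (default 1000).
#' @return List of `clustering`, `path_length`, `mean_degree`, each with
#'   `mean` and `sd`, plus `n_graphs`.
#' @export
er_ensemble <- function(n, p, n_graphs = 1000, seed = NULL) {
  run <- function() {
    cs <- numeric(n_graphs); ls <- numeric(n_graphs); ks <- numeric(n_graphs)
    for (i in seq_len(n_graphs)) {
      g <- igraph::sample_gnp(n, p)
      cs[i] <- clustering_coefficient(g)$mean
      ls[i] <- characteristic_path_length(g, largest_component = TRUE)
      ks[i] <- mean(igraph::degree(g))
    }
    list(clustering = list(mean = mean(cs), sd = sd(cs)),
         path_length = list(mean = mean(ls), sd = sd(ls)),
         mean_degree = list(mean = mean(ks), sd = sd(ks)),
         n_graphs = n_graphs)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Ravasz-style hierarchical scale-free module
#'
#' Iterative construction from a fully connected cluster of `clique_size`
#' nodes (node 1 the central node): at each of `levels - 1` iterations the
#' current module is replicated `clique_size - 1` times and the peripheral
#' (outermost) nodes of the replicas are connected to the original central
#' node. The result has `clique_size^levels` nodes; vertex attribute
#' `periphery` marks the outermost shell after the last iteration.
#'
#' @param clique_size Size of the fully connected construction unit.
#' @param levels Number of hierarchy levels (1 = the bare clique).
#' @return An igraph graph with logical vertex attribute `periphery`.
#' @export
ravasz_network <- function(clique_size, levels) {
  stopifnot(clique_size >= 2, levels >= 1)
  el <- t(combn(seq_len(clique_size), 2))
  n <- clique_size
  periph <- seq_len(clique_size)[-1]
  for (lev in seq_len(levels - 1)) {
    base_el <- el; base_n <- n; new_periph <- integer(0)
    for (r in seq_len(clique_size - 1)) {
      off <- n
      rep_periph <- periph + off
      el <- rbind(el, base_el + off, cbind(rep_periph, 1L))
      new_periph <- c(new_periph, rep_periph)
      n <- n + base_n
    }
    periph <- new_periph
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$periphery <- seq_len(n) %in% periph
  g
}

#' 302-node hierarchical scale-free null network
#'
#' Deterministic null model matched in size to the miRNA-pathway network: a
#' 4-level module built from a fully connected 4-node cluster (256 nodes)
#' and a 2-level module built from a fully connected 7-node cluster (49
#' nodes) are joined by connecting the outer nodes of the 2-level module's
#' outer clusters to the 4-level module's central node; 3 outer nodes of the
#' 2-level module (lowest index among the lowest-degree periphery) are then
#' removed, leaving exactly 302 nodes.
#'
#' @return An igraph graph with 302 nodes.
#' @export
hsfn_302 <- function() {
  g4 <- ravasz_network(4, 4)
  g7 <- ravasz_network(7, 2)
  n4 <- igraph::vcount(g4)
  g <- igraph::disjoint_union(g4, g7)
  periph7 <- which(igraph::V(g7)$periphery) + n4
  g <- igraph::add_edges(g, as.vector(rbind(periph7, 1L)))
  deg <- igraph::degree(g)[periph7]
  drop <- periph7[order(deg, periph7)][1:3]
  g <- igraph::delete_vertices(g, drop)
  stopifnot(igraph::vcount(g) == 302)
  g
}

#' Topological overlap matrix
#'
#' `OT(i, j) = |N(i) inter N(j)| / min(k_i, k_j)` for distinct nodes,
#' 1 on the diagonal, 0 in rows of isolated nodes.
#'
#' @param g An igraph graph or [signed_network()].
#' @return A symmetric numeric matrix with node names as dimnames.
#' @export
topological_overlap <- function(g) {
  g <- as_topology_graph(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- igraph::degree(g)
  cn <- A %*% A
  denom <- outer(k, k, pmin)
  ot <- ifelse(denom > 0, cn / denom, 0)
  diag(ot) <- 1
  nm <- igraph::V(g)$name
  if (!is.null(nm)) dimnames(ot) <- list(nm, nm)
  ot
}

#' Display order for a topological overlap matrix
#'
#' Hierarchical clustering of the matrix rows with a Euclidean distance
#' metric and complete linkage; the returned permutation places nodes with
#' large topological overlap next to each other.
#'
#' @param ot A matrix from [topological_overlap()].
#' @return Integer permutation of the rows.
#' @export
tom_order <- function(ot) {
  hclust(dist(ot), method = "complete")$order
}

#' Small-world test against a degree-matched random-graph ensemble
#'
#' Compares the graph's characteristic path length and clustering
#' coefficient with an Erdos-Renyi ensemble matched on node count and mean
#' degree (`p = mean degree / (n - 1)`). The small-world verdict requires
#' `L_S >= L_rand` together with `C_S > 2 C_rand` (the qualitative
#' "much larger" criterion operationalized as more than twice).
#'
#' @param g An igraph graph or [signed_network()]; must be connected.
#' @param n_random Ensemble size (default 1000).
#' @param seed Optional seed for the ensemble.
#' @return List with the observed and null statistics and the booleans
#'   `L_ok`, `C_ok`, `small_world`.
#' @export
small_world_test <- function(g, n_random = 1000, seed = NULL) {
  g <- as_topology_graph(g)
  n <- igraph::vcount(g)
  mean_k <- mean(igraph::degree(g))
  p <- mean_k / (n - 1)
  ens <- er_ensemble(n, p, n_graphs = n_random, seed = seed)
  L <- characteristic_path_length(g)
  C <- clustering_coefficient(g)$mean
  L_ok <- L >= ens$path_length$mean
  C_ok <- C > 2 * ens$clustering$mean
  list(n = n, mean_degree = mean_k, L = L, C = C,
       L_rand = ens$path_length$mean, L_rand_sd = ens$path_length$sd,
       C_rand = ens$clustering$mean, C_rand_sd = ens$clustering$sd,
       L_ok = L_ok, C_ok = C_ok, small_world = L_ok && C_ok)
}

#' Topology summary of a network
#'
#' @param g An igraph graph or [signed_network()].
#' @param include_self Self-pair convention for the path length.
#' @return List with `n`, `m`, `mean_degree` (= 2m/n), `clustering` (C_S),
#'   `path_length` (largest component), and `degree_histogram` (named
#'   counts).
#' @export
topology_summary <- function(g, include_self = TRUE) {
  g <- as_topology_graph(g)
  deg <- igraph::degree(g)
  list(n = igraph::vcount(g), m = igraph::ecount(g),
       mean_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
       clustering = clustering_coefficient(g)$mean,
       path_length = characteristic_path_length(
         g, include_self = include_self, largest_component = TRUE),
       degree_histogram = table(deg))
}
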