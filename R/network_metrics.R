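# Small-world network measures on unweighted graphs: clustering coefficient,
# average shortest path length, Louvain modularity, small-world-ness.

#' Mean local clustering coefficient
#'
#' Watts-Strogatz clustering: for each node, the fraction of closed pairs
#' among its neighbours; nodes with degree < 2 contribute 0. The graph-level
#' value is the mean over nodes.
#'
#' @param g Undirected graph.
#' @return Numeric scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  g <- as_unweighted(g)
  if (igraph::vcount(g) == 0) stop_stage("cc", "empty graph")
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' Average shortest path length
#'
#' Mean hop distance over all unordered node pairs. Disconnected graphs are
#' reduced to their largest connected component with a warning (TMFG output
#' is always connected).
#'
#' @param g Undirected graph with at least one edge.
#' @return Numeric scalar (>= 1).
#' @export
aspl <- function(g) {
  g <- as_unweighted(g)
  if (igraph::ecount(g) == 0) stop_stage("aspl", "graph has no edges")
  if (!igraph::is_connected(g)) {
    warning("graph is disconnected: ASPL computed on largest component")
    g <- largest_component(g)
  }
  igraph::mean_distance(g, directed = FALSE)
}

largest_component <- function(g) {
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
}

#' Louvain modularity with restarts
#'
#' Runs Louvain community detection `restarts` times, each on a random
#' permutation of the vertex order (Louvain is order-sensitive), and keeps
#' the partition with the highest Newman modularity
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)`.
#'
#' @param g Undirected graph with at least one edge. Weights are ignored;
#'   measures are defined on the binarized graph.
#' @param restarts Number of restarts (default 10).
#' @param seed Optional integer seed for the restart permutations.
#' @return List with `q` (best modularity) and `membership` (integer vector
#'   over vertices in input order).
#' @export
modularity_louvain <- function(g, restarts = 10, seed = NULL) {
  g <- as_unweighted(g)
  if (igraph::ecount(g) == 0) stop_stage("modularity", "graph has no edges")
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(g)
  best_q <- -Inf
  best_m <- NULL
  for (r in seq_len(restarts)) {
    perm <- sample.int(n)
    cl <- igraph::cluster_louvain(igraph::permute(g, perm))
    memb <- igraph::membership(cl)[perm]
    q <- igraph::modularity(g, memb)
    if (q > best_q) {
      best_q <- q
      best_m <- as.integer(memb)
    }
  }
  list(q = best_q, membership = best_m)
}

#' Humphries-Gurney small-world-ness
#'
#' `S = (CC / CC_rand) / (ASPL / ASPL_rand)`, where the reference terms are
#' means over an ensemble of Erdos-Renyi G(n, m) graphs with the same number
#' of nodes and edges as `g`. Random graphs score about 1; small-world
#' graphs score well above 1.
#'
#' @param g Connected undirected graph.
#' @param n_ref Number of reference random graphs (default 100).
#' @param seed Optional integer seed for the reference ensemble.
#' @param ref_stats Optional precomputed reference list with elements `cc`
#'   and `aspl` (as returned by [er_reference_stats()]); overrides `n_ref`.
#' @return Numeric scalar.
#' @export
small_worldness <- function(g, n_ref = 100, seed = NULL, ref_stats = NULL) {
  g <- as_unweighted(g)
  if (is.null(ref_stats)) {
    ref_stats <- er_reference_stats(igraph::vcount(g), igraph::ecount(g),
                                    n_ref = n_ref, seed = seed)
  }
  if (ref_stats$cc <= 0) {
    stop_stage("small_worldness", "reference clustering is zero; S undefined")
  }
  (clustering_coefficient(g) / ref_stats$cc) / (aspl(g) / ref_stats$aspl)
}

#' Mean clustering and path length of an Erdos-Renyi G(n, m) ensemble
#'
#' @param n_nodes,n_edges Size of the reference graphs.
#' @param n_ref Ensemble size.
#' @param seed Optional integer seed.
#' @return List with mean `cc` and mean `aspl` (largest component when a
#'   draw is disconnected) over the ensemble.
#' @export
er_reference_stats <- function(n_nodes, n_edges, n_ref = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- numeric(n_ref); ap <- numeric(n_ref)
  for (i in seq_len(n_ref)) {
    r <- igraph::sample_gnm(n_nodes, n_edges)
    cc[i] <- clustering_coefficient(r)
    ap[i] <- suppressWarnings(aspl(r))
  }
  list(cc = mean(cc), aspl = mean(ap))
}

#' All four network measures of a graph
#'
#' @param g Connected undirected graph.
#' @param restarts Louvain restarts (default 10).
#' @param seed Optional integer seed covering the Louvain restarts and the
#'   small-world reference ensemble.
#' @param n_ref Reference ensemble size for S.
#' @param ref_stats Optional precomputed reference stats for S.
#' @return One-row data frame: `cc`, `aspl`, `q`, `s`, `n`, `m`.
#' @export
network_measures <- function(g, restarts = 10, seed = NULL, n_ref = 100,
                             ref_stats = NULL) {
  g <- as_unweighted(g)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    cc = clustering_coefficient(g),
    aspl = aspl(g),
    q = modularity_louvain(g, restarts = restarts)$q,
    s = small_worldness(g, n_ref = n_ref, ref_stats = ref_stats),
    n = igraph::vcount(g),
    m = igraph::ecount(g))
}

# Definitional Newman modularity of a given partition; used for validation.
modularity_from_partition <- function(g, membership) {
  g <- as_unweighted(g)
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  same <- membership[el[, 1]] == membership[el[, 2]]
  deg <- igraph::degree(g)
  q <- 0
  for (c in unique(membership)) {
    e_c <- sum(same & membership[el[, 1]] == c)
    d_c <- sum(deg[membership == c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}
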