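# Cosine-similarity network estimation with TMFG sparsification.

#' Cosine similarity between word columns of an incidence matrix
#'
#' For binary columns A and B over participants j,
#' `cos(A, B) = sum_j A_j B_j / (sqrt(sum_j A_j^2) * sqrt(sum_j B_j^2))`.
#' All values lie in \[0, 1\]: two words never produced together score 0, so
#' no negative association is ever assumed.
#'
#' @param mat Binary participants x words matrix; every column must have at
#'   least one 1 (guaranteed after group equating).
#' @return Symmetric words x words similarity matrix with unit diagonal.
#' @export
cosine_similarity <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop_stage("cosine", "need at least 2 word columns")
  norms <- sqrt(colSums(mat^2))
  zero <- norms == 0
  if (any(zero)) {
    stop_stage("cosine", "all-zero column(s): ",
               paste(colnames(mat)[zero], collapse = ", "))
  }
  s <- crossprod(mat) / tcrossprod(norms)
  s <- pmin(pmax(s, 0), 1)     # guard fp drift
  diag(s) <- 1
  0.5 * (s + t(s))
}

#' Triangulated Maximally Filtered Graph
#'
#' Greedy planar sparsification of a similarity matrix. The graph is seeded
#' with the 4-clique of maximal total pairwise similarity (exact enumeration
#' for up to `exact_max` nodes, highest weighted-degree heuristic above), and
#' the remaining nodes are inserted one at a time: at each step the
#' (node, triangular face) pair maximizing the summed similarity of the node
#' to the face's three vertices is chosen, the three edges are added, and the
#' face is replaced by three new faces. The result is a connected planar
#' graph with exactly `3n - 6` edges and minimum degree 3, holding the
#' original similarities as edge weights. Ties in the seed and insertion
#' gains are broken by node (token) order, so the output is reproducible.
#'
#' @param sim Symmetric non-negative similarity matrix with at least 4 rows;
#'   row/column names become node names.
#' @param exact_max Largest size for which the seed clique is found by exact
#'   enumeration of all 4-subsets (default 25).
#' @return An [igraph][igraph::graph_from_edgelist] undirected graph with a
#'   `weight` edge attribute.
#' @export
tmfg_filter <- function(sim, exact_max = 25) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n < 4) stop_stage("tmfg", "TMFG needs at least 4 nodes, got ", n)
  if (!isSymmetric(unname(sim), tol = 1e-8)) {
    stop_stage("tmfg", "similarity matrix must be symmetric")
  }
  if (any(sim < 0)) stop_stage("tmfg", "similarities must be non-negative")
  labels <- colnames(sim) %||% paste0("v", seq_len(n))
  w <- sim
  diag(w) <- 0

  if (n <= exact_max) {
    quads <- utils::combn(n, 4)
    score <- apply(quads, 2, function(q) sum(w[q, q]) / 2)
    seed <- quads[, which.max(score)]     # which.max -> first, i.e. lexicographic
  } else {
    deg <- rowSums(w)
    seed <- sort(order(-deg, seq_len(n))[1:4])
  }

  edges <- matrix(NA_integer_, nrow = 3 * n - 6, ncol = 2)
  pairs <- utils::combn(seed, 2)
  edges[1:6, ] <- t(pairs)
  n_edges <- 6L
  # triangular faces as a growing 3-column matrix
  faces <- t(utils::combn(seed, 3))
  inserted <- logical(n)
  inserted[seed] <- TRUE

  while (any(!inserted)) {
    outside <- which(!inserted)
    # gain[f, v] = similarity of node v to the three vertices of face f
    gain <- w[faces[, 1], outside, drop = FALSE] +
      w[faces[, 2], outside, drop = FALSE] +
      w[faces[, 3], outside, drop = FALSE]
    best <- max(gain)
    hits <- which(gain == best, arr.ind = TRUE)
    # deterministic tie-break: lowest node index, then lowest face index
    hits <- hits[order(outside[hits[, 2]], hits[, 1]), , drop = FALSE]
    f <- hits[1, 1]; v <- outside[hits[1, 2]]
    tri <- faces[f, ]
    edges[n_edges + 1:3, ] <- cbind(v, tri)
    n_edges <- n_edges + 3L
    faces <- rbind(faces[-f, , drop = FALSE],
                   c(v, tri[1], tri[2]), c(v, tri[2], tri[3]),
                   c(v, tri[1], tri[3]))
    inserted[v] <- TRUE
  }

  g <- igraph::graph_from_edgelist(
    cbind(labels[edges[, 1]], labels[edges[, 2]]), directed = FALSE)
  g <- igraph::permute(g, match(igraph::V(g)$name, labels))
  igraph::E(g)$weight <- sim[cbind(edges[, 1], edges[, 2])]
  g
}

#' Binarize a weighted semantic graph
#'
#' Drops edge weights, keeping the edge set untouched: adjacency is defined
#' by edge presence, so even a zero-weight edge retained by the TMFG stays.
#'
#' @param g Weighted undirected graph (typically [tmfg_filter()] output).
#' @return The same graph without a `weight` attribute.
#' @export
binarize <- function(g) {
  as_unweighted(g)
}

#' Estimate a group's unweighted semantic network from an incidence matrix
#'
#' Convenience wrapper: cosine similarity, TMFG filtering, binarization.
#'
#' @param mat Binary incidence matrix (equated across groups upstream).
#' @return Unweighted undirected igraph object.
#' @export
estimate_network <- function(mat) {
  binarize(tmfg_filter(cosine_similarity(mat)))
}
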