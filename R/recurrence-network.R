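# Cluster-level fuzzy recurrence networks: pairwise cluster similarity by
# max-min composition over the phase-space points, alpha-cut binarization
# into an unweighted graph on the c cluster centres, and the two standard
# small-world descriptors (characteristic path length, average clustering
# coefficient).

#' Fuzzy similarity between cluster pairs
#'
#' Point-to-cluster grades below `beta` are floored to 0 first (a pruning
#' threshold that removes negligible memberships from the inference), then
#' for `k != q`, `S(k, q) = max_i min( mu(v_k, y_i), mu(y_i, v_q) )`;
#' `S(k, k) = 1` by reflexivity.
#'
#' @param partition a `fuzzy_partition`.
#' @param beta membership floor in \[0, 1\] (default 0.08, the conventional
#'   setting for this analysis).
#' @return A `cluster_similarity`: c x c symmetric matrix with unit
#'   diagonal; `beta` recorded as an attribute.
#' @export
cluster_similarity <- function(partition, beta = 0.08) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  if (!is_prob(beta)) stop_input("beta must lie in [0, 1]")
  U <- partition$memberships
  U[U < beta] <- 0
  c_ <- ncol(U)
  S <- diag(1, c_)
  if (c_ > 1L) {
    for (k in seq_len(c_ - 1L)) {
      for (q in (k + 1L):c_) {
        S[k, q] <- S[q, k] <- max(pmin(U[, k], U[, q]))
      }
    }
  }
  structure(S, class = c("cluster_similarity", class(S)), beta = beta)
}

#' Alpha-cut adjacency of a fuzzy recurrence network
#'
#' `G(k, q) = 1` iff `S(k, q) >= alpha`; the adjacency is `A = G - I`
#' (self-loops removed).
#'
#' @param S a [cluster_similarity()] matrix.
#' @param alpha cut level in \[0, 1\] (default 0.4, the conventional
#'   setting for this analysis).
#' @return A `recurrence_network`: c x c symmetric 0/1 adjacency with zero
#'   diagonal; `alpha` recorded as an attribute.
#' @export
alpha_cut_adjacency <- function(S, alpha = 0.4) {
  if (!is_prob(alpha)) stop_input("alpha must lie in [0, 1]")
  S <- unclass(S)
  A <- matrix(as.integer(S >= alpha), nrow(S), ncol(S))
  diag(A) <- 0L
  structure(A, class = c("recurrence_network", class(A)), alpha = alpha)
}

#' Graph properties of a recurrence network
#'
#' Characteristic path length: mean shortest-path length (hops) over all
#' ordered node pairs at finite distance; disconnected pairs are excluded
#' (the Watts-Strogatz convention), and a graph with no edges reports 0.
#' Average clustering coefficient: mean over nodes of
#' `2 * triangles / (degree * (degree - 1))`, nodes of degree < 2
#' contributing 0.
#'
#' @param net a [alpha_cut_adjacency()] result (or any symmetric 0/1
#'   adjacency matrix with zero diagonal).
#' @return `list(characteristic_path_length, average_clustering_coefficient)`.
#' @export
graph_properties <- function(net) {
  A <- unclass(net)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  if (igraph::ecount(g) == 0L)
    return(list(characteristic_path_length = 0,
                average_clustering_coefficient = 0))
  cpl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  list(characteristic_path_length = cpl,
       average_clustering_coefficient = mean(cc))
}
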