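#' Build a PPI network from positive pairs
#'
#' Undirected graph with one edge per unique unordered pair, all edges
#' carrying a constant weight. Self-pairs become self-loops.
#'
#' @param positive_pairs data.frame with columns `idA`, `idB` (training
#'   positives only).
#' @param default_weight Edge weight, strictly positive (default 1.0).
#' @return An [igraph::igraph] with a `weight` edge attribute.
#' @export
build_network <- function(positive_pairs, default_weight = 1.0) {
  if (!is.numeric(default_weight) || default_weight <= 0) {
    stop("edge weight must be a positive number")
  }
  pairs <- canonicalize_pairs(positive_pairs)
  pairs <- pairs[!duplicated(pair_key(pairs$idA, pairs$idB)), , drop = FALSE]
  edges <- data.frame(from = pairs$idA, to = pairs$idB,
                      weight = default_weight)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Shortest-path weight between two proteins
#'
#' Sum of edge weights along the shortest (Dijkstra) path. `spw(x, x)` is 0
#' for any node present in the network; `Inf` denotes "no path" (including
#' when either id is absent from the network).
#'
#' @param network Graph from [build_network()].
#' @param src,dst Protein ids.
#' @return Non-negative numeric, or `Inf` when no path exists.
#' @export
spw <- function(network, src, dst) {
  nodes <- igraph::V(network)$name
  if (!(src %in% nodes) || !(dst %in% nodes)) return(Inf)
  unname(igraph::distances(network, v = src, to = dst,
                           weights = igraph::E(network)$weight,
                           algorithm = "dijkstra")[1L, 1L])
}

#' Network-proximity feature (F_Net)
#'
#' The minimum shortest-path weight over all pairs of network homologs
#' `(pA, pB)`, where `pA` ranges over the hits for the first protein and
#' `pB` over the hits for the second, both restricted to e-value at or
#' below the cutoff. Returns -1 when either filtered hit set is empty or
#' every combination has no path.
#'
#' @param hitsA,hitsB Hit tables (columns `subject_id`, `evalue`).
#' @param network Graph from [build_network()].
#' @param evalue_cutoff Stringent homolog cutoff (default 1e-3).
#' @return Minimum shortest-path weight, or -1.
#' @export
fnet_score <- function(hitsA, hitsB, network, evalue_cutoff = 1e-3) {
  pA <- unique(hitsA$subject_id[hitsA$evalue <= evalue_cutoff])
  pB <- unique(hitsB$subject_id[hitsB$evalue <= evalue_cutoff])
  if (length(pA) == 0L || length(pB) == 0L) return(-1)
  nodes <- igraph::V(network)$name
  pA <- pA[pA %in% nodes]
  pB <- pB[pB %in% nodes]
  if (length(pA) == 0L || length(pB) == 0L) return(-1)
  d <- igraph::distances(network, v = pA, to = pB,
                         weights = igraph::E(network)$weight,
                         algorithm = "dijkstra")
  m <- min(d)
  if (!is.finite(m)) -1 else m
}
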