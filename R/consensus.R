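# Family-level graphs and the cross-species consensus ("ancestral") network.
#
# Collapsing a gene network to families turns recurring intra-family
# co-expression into a self-loop: the loop (f, f) exists iff at least two
# distinct genes of family f are adjacent in the gene network. The consensus
# keeps nodes/edges supported in at least a threshold number of species
# networks, with the support counts recorded as attributes.

#' Collapse a gene network to a family-level graph
#'
#' A family node is present iff the network contains at least one mapped gene
#' of that family. An edge (f, g) with f != g is present iff any gene of f is
#' adjacent to any gene of g; a self-loop (f, f) iff two distinct genes of f
#' are adjacent. Unmapped (`"UNASSIGNED"`) genes are excluded entirely.
#'
#' @param net A [gene_network()].
#' @param fam A [family_map()].
#' @return Object of class `family_network`: `species_id` plus an undirected
#'   igraph on family identifiers in which self-loops are allowed.
#' @export
collapse_to_family_graph <- function(net, fam) {
  stopifnot(inherits(net, "gene_network"))
  genes <- network_nodes(net)
  fams <- setNames(family_of(fam, genes), genes)
  keep_nodes <- sort(unique(fams[fams != UNASSIGNED]))
  el <- network_edges(net)
  fedges <- matrix(character(), ncol = 2L)
  if (nrow(el)) {
    fa <- unname(fams[el[, 1L]])
    fb <- unname(fams[el[, 2L]])
    ok <- fa != UNASSIGNED & fb != UNASSIGNED
    if (any(ok)) {
      fedges <- unique(cbind(pmin(fa[ok], fb[ok]), pmax(fa[ok], fb[ok])))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(keep_nodes), name = keep_nodes)
  if (nrow(fedges)) g <- igraph::add_edges(g, as.vector(t(fedges)))
  structure(list(species_id = net$species_id, graph = g),
            class = "family_network")
}

#' @export
print.family_network <- function(x, ...) {
  nl <- sum(igraph::which_loop(x$graph))
  cat(sprintf("<family_network> species=%s  %d families, %d edges (%d self-loops)\n",
              x$species_id, igraph::vcount(x$graph), igraph::ecount(x$graph), nl))
  invisible(x)
}

#' Build the cross-species consensus network of gene families
#'
#' Nodes are families whose conservation count reaches `min_node_support`;
#' edges (self-loops included) are family pairs present in at least
#' `min_edge_support` of the per-species family networks, restricted to
#' retained nodes. Node support (`support` vertex attribute) is the family's
#' conservation count; edge support (`support` edge attribute) the number of
#' family networks containing the edge. At thresholds (1, 1) the consensus is
#' exactly the union of the family networks with occurrence counts.
#'
#' @param family_nets List of [collapse_to_family_graph()] results, one per
#'   species network.
#' @param profile The [conservation_profile()] over the same networks.
#' @param min_node_support,min_edge_support Integer thresholds in `[1, S]`.
#' @return Object of class `consensus_network` with elements `graph` and `S`.
#' @export
build_consensus <- function(family_nets, profile,
                            min_node_support = 3L, min_edge_support = 3L) {
  stopifnot(length(family_nets) >= 1L,
            all(vapply(family_nets, inherits, TRUE, "family_network")),
            inherits(profile, "conservation_profile"))
  S <- length(family_nets)
  for (thr in c(min_node_support, min_edge_support)) {
    if (!is.numeric(thr) || length(thr) != 1L || thr < 1L || thr > S) {
      stop(sprintf("support thresholds must be in [1, %d]", S), call. = FALSE)
    }
  }
  nodes <- names(profile$counts)[profile$counts >= min_node_support]
  nodes <- sort(nodes)
  edge_keys <- unlist(lapply(family_nets, function(fn) {
    el <- network_edges(fn)
    if (!nrow(el)) character() else paste(el[, 1L], el[, 2L], sep = "\r")
  }))
  etab <- table(edge_keys)
  keep <- names(etab)[as.integer(etab) >= min_edge_support]
  if (length(keep)) {
    em <- do.call(rbind, strsplit(keep, "\r", fixed = TRUE))
    inside <- em[, 1L] %in% nodes & em[, 2L] %in% nodes
    em <- em[inside, , drop = FALSE]
    esup <- as.integer(etab[keep])[inside]
  } else {
    em <- matrix(character(), ncol = 2L)
    esup <- integer()
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes,
                            support = unname(profile$counts[nodes]))
  if (nrow(em)) {
    g <- igraph::add_edges(g, as.vector(t(em)), support = esup)
  }
  structure(list(graph = g, S = S), class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  nl <- sum(igraph::which_loop(x$graph))
  cat(sprintf("<consensus_network> %d families, %d edges (%d self-loops), S=%d\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), nl, x$S))
  invisible(x)
}

#' Node and edge supports of a consensus network
#'
#' @param consensus A [build_consensus()] result.
#' @return List with `nodes` (data frame family/support) and `edges` (data
#'   frame a/b/support, endpoints sorted within each row).
#' @export
consensus_supports <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_network"))
  g <- consensus$graph
  nodes <- data.frame(family = igraph::V(g)$name,
                      support = igraph::V(g)$support)
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(a = pmin(el[, 1L], el[, 2L]),
                      b = pmax(el[, 1L], el[, 2L]),
                      support = igraph::E(g)$support %||% integer())
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  nodes <- nodes[order(nodes$family), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
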