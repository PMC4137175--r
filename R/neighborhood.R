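# Bait-centered neighborhood extraction: the per-species "pathway network" is
# the induced subgraph on all genes within `steps` hops of any bait gene.

#' Define a set of bait (query) genes for one species network
#'
#' Baits are known pathway members (e.g. the cellulose synthases of primary
#' and secondary cell wall formation) used to seed neighborhood extraction.
#'
#' @param species_id Species/network label the baits refer to.
#' @param baits Non-empty character vector of gene identifiers.
#' @return Object of class `bait_set`.
#' @export
bait_set <- function(species_id, baits) {
  baits <- unique(as.character(baits))
  if (!length(baits) || any(!nzchar(baits))) {
    abort_io("bait set must contain at least one non-empty gene identifier")
  }
  structure(list(species_id = species_id, baits = baits), class = "bait_set")
}

#' Extract the k-step neighborhood of a set of bait genes
#'
#' Performs a multi-source unweighted breadth-first search from all baits that
#' are present in the network (distance of a gene = minimum hop count over
#' baits) and returns the induced subgraph on genes at distance <= `steps`:
#' all original edges among collected genes are kept, including edges between
#' two non-bait genes at the periphery. With `steps = 0` the result is the
#' baits themselves plus any edges among them.
#'
#' Baits absent from the network are reported in the `missing_baits` attribute
#' of the result (and via a message), never silently dropped; if no bait is
#' present at all this is an error.
#'
#' @param net A [gene_network()].
#' @param baits A [bait_set()] (or character vector of gene ids).
#' @param steps Non-negative integer number of hops (default 2).
#' @return A [gene_network()]; `attr(, "missing_baits")` lists baits not found
#'   in `net` and `attr(, "baits")` the baits used.
#' @export
extract_neighborhood <- function(net, baits, steps = 2L) {
  stopifnot(inherits(net, "gene_network"))
  if (is.character(baits)) baits <- bait_set(net$species_id, baits)
  if (!is.numeric(steps) || length(steps) != 1L || is.na(steps) || steps < 0) {
    stop("steps must be a single non-negative integer", call. = FALSE)
  }
  steps <- as.integer(steps)
  present <- intersect(baits$baits, network_nodes(net))
  missing <- setdiff(baits$baits, present)
  if (!length(present)) {
    stop(sprintf("none of the %d bait(s) are present in network %s",
                 length(baits$baits), net$species_id), call. = FALSE)
  }
  if (length(missing)) {
    message(sprintf("%d bait(s) not found in network %s: %s",
                    length(missing), net$species_id,
                    paste(missing, collapse = ", ")))
  }
  d <- igraph::distances(net$graph, v = present, mode = "all")
  reach <- igraph::V(net$graph)$name[apply(d, 2L, min) <= steps]
  sub <- igraph::induced_subgraph(net$graph, reach)
  out <- structure(list(species_id = net$species_id, graph = sub),
                   class = class(net))
  attr(out, "baits") <- present
  attr(out, "missing_baits") <- missing
  out
}
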