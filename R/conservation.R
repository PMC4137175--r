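# Gene-family conservation scoring across species networks.
#
# The conservation count of a family is the number of input networks that
# contain at least one gene of that family -- multiplicity within a network is
# deliberately ignored (a family with five peroxidases in one network still
# counts once for that network).

#' Count in how many networks each gene family occurs
#'
#' @param networks List of [gene_network()] objects with distinct species ids
#'   (typically the extracted bait neighborhoods, one per species/context).
#' @param fam A [family_map()].
#' @return Object of class `conservation_profile`: list with `counts` (named
#'   integer vector, family -> number of networks, each in `[1, S]`), `S`
#'   (number of networks) and `species` (their ids). Unmapped genes
#'   (family `"UNASSIGNED"`) are never listed.
#' @export
conservation_profile <- function(networks, fam) {
  stopifnot(length(networks) >= 1L,
            all(vapply(networks, inherits, TRUE, "gene_network")))
  ids <- vapply(networks, `[[`, "", "species_id")
  if (anyDuplicated(ids)) {
    stop("networks must have distinct species_ids: ",
         paste(ids[duplicated(ids)], collapse = ", "), call. = FALSE)
  }
  per_net <- lapply(networks, function(n) {
    setdiff(unique(family_of(fam, network_nodes(n))), UNASSIGNED)
  })
  tab <- table(unlist(per_net))
  counts <- setNames(as.integer(tab), names(tab))
  counts <- counts[order(names(counts))]
  structure(list(counts = counts, S = length(networks), species = unname(ids)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d families over %d networks (%s)\n",
              length(x$counts), x$S, paste(x$species, collapse = ", ")))
  print(table(factor(x$counts, levels = seq_len(x$S))))
  invisible(x)
}

#' Annotate network nodes with family and conservation class
#'
#' Every node gains a `family` attribute (from the map, `"UNASSIGNED"` when
#' unmapped) and a `conservation_class` attribute: the family's conservation
#' count, or class 0 for unassigned genes.
#'
#' @param net A [gene_network()].
#' @param fam A [family_map()].
#' @param profile A [conservation_profile()] computed over a network set that
#'   includes this network's genes' families.
#' @return A `labeled_network` (also a `gene_network`).
#' @export
label_network <- function(net, fam, profile) {
  stopifnot(inherits(net, "gene_network"), inherits(profile, "conservation_profile"))
  genes <- network_nodes(net)
  fams <- family_of(fam, genes)
  cls <- unname(profile$counts[fams])
  cls[is.na(cls) | fams == UNASSIGNED] <- 0L
  g <- igraph::set_vertex_attr(net$graph, "family", value = fams)
  g <- igraph::set_vertex_attr(g, "conservation_class", value = as.integer(cls))
  g <- igraph::set_graph_attr(g, "S", profile$S)
  structure(list(species_id = net$species_id, graph = g),
            class = unique(c("labeled_network", class(net))))
}

#' Conservation class of each node in a labeled network
#' @param net A `labeled_network`.
#' @return Named integer vector (names = genes).
#' @export
conservation_classes <- function(net) {
  stopifnot(inherits(net, "labeled_network"))
  setNames(igraph::V(net$graph)$conservation_class, igraph::V(net$graph)$name)
}

#' Filter a labeled network down to its conserved core
#'
#' Keeps the induced subgraph on genes whose family occurs in at least
#' `min_networks` of the compared networks. At `min_networks = S` only
#' families found in every network remain; at 1, all family-assigned genes
#' remain and unassigned (class 0) genes are dropped.
#'
#' @param net A `labeled_network` (see [label_network()]).
#' @param min_networks Integer threshold in `[1, S]`.
#' @return A `labeled_network` restricted to the core.
#' @export
conserved_core <- function(net, min_networks) {
  stopifnot(inherits(net, "labeled_network"))
  S <- igraph::graph_attr(net$graph, "S") %||%
    max(igraph::V(net$graph)$conservation_class, 1L)
  if (!is.numeric(min_networks) || length(min_networks) != 1L ||
      min_networks < 1L || min_networks > S) {
    stop(sprintf("min_networks must be in [1, %d]", S), call. = FALSE)
  }
  keep <- igraph::V(net$graph)$conservation_class >= min_networks
  sub <- igraph::induced_subgraph(net$graph, which(keep))
  structure(list(species_id = net$species_id, graph = sub), class = class(net))
}

#' Histogram of conservation classes in a labeled network
#'
#' @param net A `labeled_network`.
#' @return Data frame with columns `conservation_class` and `genes`; counts
#'   sum to the node count. Empty for an empty network.
#' @export
class_distribution <- function(net) {
  cls <- conservation_classes(net)
  if (!length(cls)) {
    return(data.frame(conservation_class = integer(), genes = integer()))
  }
  tab <- table(cls)
  data.frame(conservation_class = as.integer(names(tab)),
             genes = as.integer(tab))
}

#' Conservation profile as a sorted report table
#'
#' One row per family, sorted by descending count then family id -- the
#' analogue of a "number of times present" table, with member genes per
#' network listed for inspection.
#'
#' @param profile A [conservation_profile()].
#' @param networks The networks the profile was computed from (optional; adds
#'   per-network member-gene columns).
#' @param fam The [family_map()] used (required with `networks`).
#' @return Data frame with columns `family`, `n_networks` and, if networks are
#'   given, one comma-separated member column per species.
#' @export
profile_table <- function(profile, networks = NULL, fam = NULL) {
  df <- data.frame(family = names(profile$counts),
                   n_networks = unname(profile$counts))
  df <- df[order(-df$n_networks, df$family), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(networks)) {
    stopifnot(!is.null(fam))
    for (n in networks) {
      genes <- network_nodes(n)
      fams <- family_of(fam, genes)
      members <- vapply(df$family, function(f) {
        paste(sort(genes[fams == f]), collapse = ",")
      }, "")
      df[[paste0("genes_", n$species_id)]] <- unname(members)
    }
  }
  df
}
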