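# First appearance of gene families along an ordered series of clades.
#
# If a family is absent from the oldest clade but present from some later
# clade on, its origin is placed at the oldest clade where it is recorded
# present (single-origin reading: later absences are treated as losses).

#' Assign each family its first-appearance clade
#'
#' @param lineage A [lineage_table()] (clades ordered oldest first).
#' @return Named character vector of class `stratum_assignment`: family ->
#'   clade label of the oldest clade with recorded presence, or `"ABSENT"`
#'   for an all-absent family.
#' @export
first_appearance <- function(lineage) {
  stopifnot(inherits(lineage, "lineage_table"))
  idx <- apply(lineage$presence, 1L, function(v) {
    w <- which(v)
    if (length(w)) w[1L] else NA_integer_
  })
  out <- ifelse(is.na(idx), "ABSENT", lineage$clades[idx])
  structure(setNames(out, rownames(lineage$presence)),
            class = "stratum_assignment")
}

#' Annotate consensus network nodes with their phylostratum
#'
#' Adds a `stratum` vertex attribute to every consensus node: the family's
#' first-appearance clade, or `"UNKNOWN"` for families missing from the
#' assignment.
#'
#' @param consensus A [build_consensus()] result.
#' @param strata A [first_appearance()] result.
#' @return The annotated `consensus_network`.
#' @export
annotate_strata <- function(consensus, strata) {
  stopifnot(inherits(consensus, "consensus_network"),
            inherits(strata, "stratum_assignment"))
  fams <- igraph::V(consensus$graph)$name
  s <- unclass(strata)[fams]
  s[is.na(s)] <- "UNKNOWN"
  consensus$graph <- igraph::set_vertex_attr(consensus$graph, "stratum",
                                             value = unname(s))
  consensus
}

#' Family counts per phylostratum in an annotated consensus network
#'
#' @param consensus An [annotate_strata()] result.
#' @param clades Optional clade order for the output rows (strata not listed,
#'   e.g. `"UNKNOWN"`/`"ABSENT"`, are appended alphabetically).
#' @return Data frame with columns `stratum` and `families`; counts sum to the
#'   consensus node count. Zero rows for an empty consensus.
#' @export
stratum_summary <- function(consensus, clades = NULL) {
  stopifnot(inherits(consensus, "consensus_network"))
  s <- igraph::vertex_attr(consensus$graph, "stratum")
  if (is.null(s) || !length(s)) {
    return(data.frame(stratum = character(), families = integer()))
  }
  tab <- table(s)
  out <- data.frame(stratum = names(tab), families = as.integer(tab))
  lv <- c(intersect(clades, out$stratum),
          sort(setdiff(out$stratum, clades)))
  out <- out[match(lv, out$stratum), , drop = FALSE]
  rownames(out) <- NULL
  out
}
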