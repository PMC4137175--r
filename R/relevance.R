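# Annotation composition per conservation class: for each class, how many
# genes carry a target bin (e.g. Mapman 10 "cell wall"), how many only the
# "unknown function" bin (35), and how many anything else.

# Top-level Mapman code of a (possibly hierarchical) bin: "10.2.1" -> "10".
bin_top_level <- function(bins) sub("\\..*$", "", bins)

#' Classify one gene's bins into target / unknown / other
#' @noRd
classify_bins <- function(bins, target_bins, unknown_bins) {
  if (length(bins)) {
    top <- bin_top_level(bins)
    if (any(top %in% target_bins)) return("target")
    if (any(top %in% unknown_bins)) return("unknown")
  }
  "other"
}

#' Tally annotation categories per conservation class
#'
#' Each gene is put in exactly one category with precedence
#' target > unknown > other: `target` if any of its bins has a top-level code
#' in `target_bins`, else `unknown` if any lies in `unknown_bins`, else
#' `other` (which also collects genes with no annotation record at all).
#' Hierarchical bins match by their prefix before the first dot, so `"10.2.1"`
#' matches target `"10"`.
#'
#' By default genes are counted once per network they occur in (the compared
#' networks are pooled); with `dedupe = TRUE` every distinct gene identifier
#' is counted once, using its first occurrence.
#'
#' @param nets List of `labeled_network` objects (see [label_network()]).
#' @param ann An [annotation_table()].
#' @param target_bins Character vector of top-level bin codes of the studied
#'   process (default `"10"`, cell wall).
#' @param unknown_bins Character vector of top-level codes meaning "function
#'   unknown" (default `"35"`). Must be disjoint from `target_bins`.
#' @param dedupe Count each gene once across all networks instead of once per
#'   network.
#' @return Data frame of class `relevance_table` with columns
#'   `conservation_class`, `category` (`target`/`unknown`/`other`) and
#'   `genes`; within each class the three counts sum to the class size.
#' @export
tally_by_class <- function(nets, ann, target_bins = "10", unknown_bins = "35",
                           dedupe = FALSE) {
  stopifnot(length(nets) >= 1L,
            all(vapply(nets, inherits, TRUE, "labeled_network")),
            inherits(ann, "annotation_table"))
  target_bins <- as.character(target_bins)
  unknown_bins <- as.character(unknown_bins)
  if (length(intersect(target_bins, unknown_bins))) {
    stop("target_bins and unknown_bins must be disjoint", call. = FALSE)
  }
  genes <- unlist(lapply(nets, function(n) names(conservation_classes(n))))
  cls <- unlist(lapply(nets, function(n) unname(conservation_classes(n))))
  if (dedupe) {
    keep <- !duplicated(genes)
    genes <- genes[keep]
    cls <- cls[keep]
  }
  cat_of <- vapply(genes, function(g) {
    classify_bins(ann[[g]], target_bins, unknown_bins)
  }, "")
  df <- as.data.frame(table(
    conservation_class = factor(cls, levels = sort(unique(cls))),
    category = factor(cat_of, levels = c("target", "unknown", "other"))
  ), responseName = "genes")
  df$conservation_class <- as.integer(as.character(df$conservation_class))
  df$category <- as.character(df$category)
  df <- df[order(df$conservation_class, match(df$category,
                                              c("target", "unknown", "other"))), ]
  rownames(df) <- NULL
  class(df) <- c("relevance_table", class(df))
  df
}

#' Fraction of "other"-category genes per conservation class
#'
#' The qualitative signal of a conservation-implies-relevance analysis: as the
#' conservation class rises, the share of genes unrelated to the studied
#' process should fall.
#'
#' @param tab A [tally_by_class()] result.
#' @return Named numeric vector, fraction of `other` genes per class (names =
#'   classes, ascending).
#' @export
other_fraction <- function(tab) {
  stopifnot(inherits(tab, "relevance_table"))
  tot <- tapply(tab$genes, tab$conservation_class, sum)
  oth <- tapply(tab$genes[tab$category == "other"],
                tab$conservation_class[tab$category == "other"], sum)
  out <- as.numeric(oth) / as.numeric(tot)
  setNames(out, names(tot))
}
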