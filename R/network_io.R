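# Domain types and readers/writers for all file formats the pipeline touches.
#
# A gene_network wraps an undirected simple igraph (no self-edges, no
# multi-edges) plus a species label. Family-level graphs (family_network,
# consensus_network) allow self-loops and live in consensus.R.

#' Construct a gene co-expression network
#'
#' An undirected, unweighted graph whose nodes are gene identifiers. Self-edges
#' are dropped with a warning and duplicate edges (in either orientation) are
#' collapsed, so the result always satisfies the network invariants.
#'
#' @param species_id Single string labelling the species/network.
#' @param edges Two-column character matrix or data frame of gene pairs
#'   (may be empty).
#' @param nodes Character vector of additional (possibly isolated) node names.
#' @return An object of class `gene_network` with elements `species_id` and
#'   `graph` (an [igraph::graph] object).
#' @examples
#' net <- gene_network("ath", rbind(c("g1", "g2"), c("g2", "g3")))
#' network_nodes(net)
#' @export
gene_network <- function(species_id, edges = NULL, nodes = character()) {
  stopifnot(is.character(species_id), length(species_id) == 1L, nzchar(species_id))
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
  }
  self <- em[, 1L] == em[, 2L]
  all_nodes <- unique(c(as.character(nodes), as.vector(t(em))))
  if (any(self)) {
    warning(sprintf("dropping %d self-edge(s): %s", sum(self),
                    paste(unique(em[self, 1L]), collapse = ", ")),
            call. = FALSE)
    em <- em[!self, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (nrow(em) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(em)))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  structure(list(species_id = species_id, graph = g), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> species=%s  %d nodes, %d edges\n",
              x$species_id, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node names of a network
#' @param net A `gene_network`, `family_network` or `consensus_network`.
#' @return Character vector of node identifiers.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Edge list of a network as a canonical two-column matrix
#'
#' Endpoints of each undirected edge are sorted within the row and rows are
#' sorted lexicographically, so two equal edge sets always compare identical.
#' Self-loops (family-level graphs) appear as rows with equal endpoints.
#'
#' @inheritParams network_nodes
#' @return Character matrix with columns `a`, `b`; zero rows if edgeless.
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  if (nrow(el) == 0L) {
    return(matrix(character(), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  el <- t(apply(el, 1L, sort))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  dimnames(el) <- list(NULL, c("a", "b"))
  el
}

#' Read an undirected edge list (TSV)
#'
#' Expects `gene_a<TAB>gene_b` rows; lines starting with `#` are skipped.
#' One-column lines declare isolated (singleton) nodes. A third column, if
#' present (e.g. a co-expression weight), is ignored with a note: the analysis
#' is purely topological. Self-edges are dropped with a warning and duplicate
#' pairs collapse to one edge.
#'
#' @param path Path to the TSV file.
#' @param species_id Label for the resulting network.
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path, species_id) {
  lines <- readLines(check_readable(path))
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf > 3L | nf == 0L)) {
    bad <- idx[which(nf > 3L | nf == 0L)[1L]]
    abort_io(sprintf("%s: malformed line %d (expected 1-3 tab-separated fields)", path, bad))
  }
  if (any(nf == 3L)) {
    message(sprintf("%s: third column present on %d line(s); ignored (networks are unweighted)",
                    path, sum(nf == 3L)))
  }
  singles <- vapply(fields[nf == 1L], `[`, "", 1L)
  pairs <- fields[nf >= 2L]
  em <- if (length(pairs)) {
    matrix(unlist(lapply(pairs, `[`, 1:2)), ncol = 2L, byrow = TRUE)
  } else {
    NULL
  }
  if (!is.null(em) && any(!nzchar(em))) {
    bad <- idx[nf >= 2L][which(rowSums(!nzchar(em)) > 0L)[1L]]
    abort_io(sprintf("%s: empty gene identifier on line %d", path, bad))
  }
  gene_network(species_id, edges = em, nodes = singles)
}

#' Construct a gene-to-family map
#'
#' @param genes Character vector of gene identifiers.
#' @param families Character vector of family identifiers, same length.
#' @return Named character vector of class `family_map` (names = genes).
#' @export
family_map <- function(genes = character(), families = character()) {
  stopifnot(length(genes) == length(families))
  if (any(!nzchar(families))) abort_io("family identifiers must be non-empty strings")
  dup <- duplicated(cbind(genes, families))
  genes <- genes[!dup]; families <- families[!dup]
  conflict <- unique(genes[duplicated(genes)])
  if (length(conflict)) {
    abort_io(sprintf("gene(s) mapped to conflicting families: %s",
                     paste(conflict, collapse = ", ")))
  }
  structure(setNames(as.character(families), genes), class = "family_map")
}

#' Read a PLAZA-style gene-to-family table (TSV: gene, family)
#'
#' Duplicate identical rows are deduplicated silently; a gene listed with two
#' different families is an error naming the gene.
#'
#' @param path Path to the TSV file.
#' @return A [family_map()].
#' @export
read_family_map <- function(path) {
  df <- read_two_col(path, "family map")
  family_map(df[[1L]], df[[2L]])
}

#' Look up families for genes, with "UNASSIGNED" for unmapped genes
#' @param fam A [family_map()].
#' @param genes Character vector of gene identifiers.
#' @return Character vector of family identifiers.
#' @export
family_of <- function(fam, genes) {
  out <- unclass(fam)[genes]
  out[is.na(out)] <- UNASSIGNED
  unname(out)
}

#' Read a Mapman-style annotation table (TSV: gene, bin)
#'
#' Multiple rows per gene accumulate into a set of bins; bins are opaque
#' strings (hierarchical codes like `"10.2.1"` are kept verbatim).
#'
#' @param path Path to the TSV file.
#' @return Object of class `annotation_table`: a named list gene -> character
#'   vector of bins.
#' @export
read_annotation <- function(path) {
  df <- read_two_col(path, "annotation")
  if (nrow(df) && any(!nzchar(df[[2L]]))) {
    abort_io(sprintf("%s: empty bin field for gene %s", path,
                     df[[1L]][which(!nzchar(df[[2L]]))[1L]]))
  }
  annotation_table(df[[1L]], df[[2L]])
}

#' Construct an annotation table from parallel gene/bin vectors
#' @param genes Character vector (repeats allowed).
#' @param bins Character vector of bin codes, same length.
#' @return An `annotation_table`.
#' @export
annotation_table <- function(genes = character(), bins = character()) {
  stopifnot(length(genes) == length(bins))
  out <- lapply(split(as.character(bins), factor(genes, levels = unique(genes))),
                unique)
  structure(out, class = "annotation_table")
}

# Shared TSV reader for (key, value) files; skips '#' lines, checks field count.
read_two_col <- function(path, what) {
  lines <- readLines(check_readable(path))
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- idx[which(nf != 2L)[1L]]
    abort_io(sprintf("%s: malformed %s line %d (expected 2 tab-separated fields)",
                     path, what, bad))
  }
  data.frame(a = vapply(fields, `[`, "", 1L),
             b = vapply(fields, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Construct a lineage (phylostratigraphy) table
#'
#' @param clades Character vector of clade labels, oldest first, unique.
#' @param presence Logical matrix, one row per family (rownames = family ids),
#'   one column per clade.
#' @return Object of class `lineage_table` with elements `clades` and
#'   `presence`.
#' @export
lineage_table <- function(clades, presence) {
  stopifnot(is.character(clades), length(clades) >= 1L)
  if (anyDuplicated(clades)) abort_io("clade labels must be unique")
  presence <- as.matrix(presence)
  if (ncol(presence) != length(clades)) {
    abort_io("presence matrix must have one column per clade")
  }
  storage.mode(presence) <- "logical"
  colnames(presence) <- clades
  structure(list(clades = clades, presence = presence), class = "lineage_table")
}

#' Read a family-by-clade presence/absence table
#'
#' The header row lists clade labels oldest to newest after a leading `family`
#' column; body rows are a family identifier followed by 0/1 per clade.
#'
#' @param path Path to the TSV file.
#' @return A [lineage_table()].
#' @export
read_lineage_table <- function(path) {
  lines <- readLines(check_readable(path))
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort_io(sprintf("%s: empty lineage table", path))
  header <- strsplit(sub("^#", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
  clades <- header[-1L]
  if (!length(clades)) abort_io(sprintf("%s: lineage header lists no clades", path))
  body <- lines[-1L]
  fams <- character(length(body))
  pres <- matrix(NA, nrow = length(body), ncol = length(clades))
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(clades) + 1L) {
      abort_io(sprintf("%s: row for family %s has %d presence values (expected %d)",
                       path, f[1L], length(f) - 1L, length(clades)))
    }
    vals <- f[-1L]
    if (!all(vals %in% c("0", "1"))) {
      abort_io(sprintf("%s: non-0/1 presence value for family %s", path, f[1L]))
    }
    fams[i] <- f[1L]
    pres[i, ] <- vals == "1"
  }
  rownames(pres) <- fams
  lineage_table(clades, pres)
}

#' Write a lineage table (inverse of [read_lineage_table()])
#' @param lin A [lineage_table()].
#' @param path Output path.
#' @export
write_lineage_table <- function(lin, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("family", lin$clades), collapse = "\t"), con)
  fams <- rownames(lin$presence)
  for (i in seq_along(fams)) {
    writeLines(paste(c(fams[i], as.integer(lin$presence[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a gene or family map / annotation table as TSV
#' @param x A `family_map` or `annotation_table`.
#' @param path Output path.
#' @export
write_mapping <- function(x, path) {
  if (inherits(x, "family_map")) {
    df <- data.frame(gene = names(x), value = unclass(x))
  } else if (inherits(x, "annotation_table")) {
    df <- data.frame(gene = rep(names(x), lengths(x)),
                     value = unlist(x, use.names = FALSE))
  } else {
    abort_io("write_mapping() expects a family_map or annotation_table")
  }
  df <- df[order(df$gene, df$value), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a network to disk
#'
#' `edge_tsv` writes the canonical sorted edge list plus one-column lines for
#' isolated nodes; for gene networks `read_edge_list()` of that file is a
#' lossless round trip. `graphml` emits any node attributes present
#' (`family`, `conservation_class`, `stratum`, `support`) and the `support`
#' edge attribute of consensus networks, for use in Cytoscape and friends.
#'
#' @param net A `gene_network`, `family_network` or `consensus_network`.
#' @param path Output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("edge_tsv", "graphml")) {
    format <- tryCatch(match.arg(format),
                       error = function(e) abort_io("unknown network format"))
  }
  if (format == "edge_tsv") {
    el <- network_edges(net)
    iso <- setdiff(network_nodes(net), as.vector(el))
    con <- file(path, "w")
    on.exit(close(con))
    sup <- igraph::edge_attr(net$graph, "support")
    if (!is.null(sup)) {
      # keep support alongside the pair; readers ignore the third column
      key <- paste(el[, 1L], el[, 2L])
      raw <- igraph::as_edgelist(net$graph, names = TRUE)
      raw_key <- paste(pmin(raw[, 1L], raw[, 2L]), pmax(raw[, 1L], raw[, 2L]))
      sup <- sup[match(key, raw_key)]
      writeLines(paste(el[, 1L], el[, 2L], sup, sep = "\t"), con)
    } else if (nrow(el)) {
      writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
    }
    if (length(iso)) writeLines(sort(iso), con)
  } else {
    igraph::write_graph(net$graph, path, format = "graphml")
  }
  invisible(path)
}
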