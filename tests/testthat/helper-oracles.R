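# Independent brute-force oracles and random-instance generators. These stay
# deliberately naive (queues, double loops, exhaustive membership checks) and
# share no code with the implementation they check.

rand_gene_network <- function(species_id = "sp", n_nodes = 20L,
                              n_edges = 30L) {
  nodes <- sprintf("%s_g%02d", species_id, seq_len(n_nodes))
  a <- sample(nodes, n_edges, replace = TRUE)
  b <- sample(nodes, n_edges, replace = TRUE)
  keep <- a != b
  suppressWarnings(gene_network(species_id, cbind(a[keep], b[keep]),
                                nodes = nodes))
}

rand_family_map <- function(genes, n_families = 6L, p_unmapped = 0.2) {
  mapped <- genes[runif(length(genes)) >= p_unmapped]
  if (!length(mapped)) mapped <- genes[1L]
  family_map(mapped, sample(sprintf("F%02d", seq_len(n_families)),
                            length(mapped), replace = TRUE))
}

# Plain queue-based BFS hop distances from a set of sources.
oracle_distances <- function(net, sources) {
  nodes <- network_nodes(net)
  el <- network_edges(net)
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1L]; b <- el[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- setNames(rep(Inf, length(nodes)), nodes)
  queue <- intersect(sources, nodes)
  d[queue] <- 0
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

oracle_neighborhood_nodes <- function(net, baits, steps) {
  d <- oracle_distances(net, baits)
  names(d)[d <= steps]
}

# family -> number of networks with >= 1 mapped gene, by exhaustive loops.
oracle_conservation <- function(networks, fam) {
  fams <- sort(unique(unclass(fam)))
  counts <- integer(0)
  for (f in fams) {
    genes_of_f <- names(fam)[unclass(fam) == f]
    n <- 0L
    for (net in networks) {
      if (any(genes_of_f %in% network_nodes(net))) n <- n + 1L
    }
    if (n > 0L) counts[f] <- n
  }
  counts
}

# family edge set of one network by the exhaustive gene-pair double loop.
oracle_family_edges <- function(net, fam) {
  el <- network_edges(net)
  nodes <- network_nodes(net)
  mapped <- nodes[nodes %in% names(fam)]
  out <- character()
  adjacent <- function(x, y) {
    any((el[, 1L] == x & el[, 2L] == y) | (el[, 1L] == y & el[, 2L] == x))
  }
  for (i in seq_along(mapped)) {
    for (j in seq_along(mapped)) {
      if (j <= i) next
      if (adjacent(mapped[i], mapped[j])) {
        fa <- unclass(fam)[[mapped[i]]]
        fb <- unclass(fam)[[mapped[j]]]
        out <- c(out, paste(min(fa, fb), max(fa, fb), sep = "|"))
      }
    }
  }
  sort(unique(out))
}

consensus_edge_keys <- function(cons) {
  el <- consensus_supports(cons)$edges
  if (!nrow(el)) character() else
    sort(paste(el$a, el$b, el$support, sep = "|"))
}

# per-gene classification by exhaustive lookup, for relevance tallies.
oracle_tally <- function(labeled_nets, ann, target, unknown, dedupe = FALSE) {
  rows <- list()
  seen <- character()
  for (net in labeled_nets) {
    for (g in network_nodes(net)) {
      if (dedupe && g %in% seen) next
      seen <- c(seen, g)
      cls <- conservation_classes(net)[[g]]
      bins <- ann[[g]]
      top <- if (length(bins)) sub("\\..*$", "", bins) else character()
      cat <- if (any(top %in% target)) "target"
             else if (any(top %in% unknown)) "unknown" else "other"
      rows[[length(rows) + 1L]] <- data.frame(conservation_class = cls,
                                              category = cat)
    }
  }
  df <- do.call(rbind, rows)
  stats::aggregate(list(genes = rep(1L, nrow(df))),
                   df[c("conservation_class", "category")], sum)
}

expect_same_tally <- function(tab, oracle) {
  got <- tab[tab$genes > 0L, c("conservation_class", "category", "genes")]
  got <- got[order(got$conservation_class, got$category), ]
  want <- oracle[order(oracle$conservation_class, oracle$category), ]
  rownames(got) <- rownames(want) <- NULL
  class(got) <- "data.frame"
  expect_equal(got, want)
}

# tiny convenience: write lines to a temp TSV and return the path
tsv_fixture <- function(...) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(...), path)
  path
}
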