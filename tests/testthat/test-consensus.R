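test_that("two adjacent same-family genes collapse to a self-loop", {
  net <- gene_network("sp", rbind(c("cesa1", "cesa2"), c("cesa2", "cob1")))
  fam <- family_map(c("cesa1", "cesa2", "cob1"), c("CESA", "CESA", "COBRA"))
  fn <- collapse_to_family_graph(net, fam)
  el <- network_edges(fn)
  expect_true(any(el[, 1] == "CESA" & el[, 2] == "CESA"))   # self-loop
  expect_true(any(el[, 1] == "CESA" & el[, 2] == "COBRA"))
  # no loop without two distinct adjacent members
  net2 <- gene_network("sp", rbind(c("cesa1", "cob1")))
  el2 <- network_edges(collapse_to_family_graph(net2, fam))
  expect_false(any(el2[, 1] == el2[, 2]))
})

test_that("isolated mapped genes yield family nodes without edges; UNASSIGNED excluded", {
  net <- gene_network("sp", rbind(c("x", "y")), nodes = "cesa1")
  fam <- family_map("cesa1", "CESA")
  fn <- collapse_to_family_graph(net, fam)
  expect_equal(network_nodes(fn), "CESA")
  expect_equal(nrow(network_edges(fn)), 0L)
})

test_that("family edges equal the exhaustive gene-pair double loop", {
  set.seed(404)
  for (rep in 1:25) {
    net <- rand_gene_network("sp", n_nodes = sample(5:30, 1),
                             n_edges = sample(5:40, 1))
    fam <- rand_family_map(network_nodes(net))
    fn <- collapse_to_family_graph(net, fam)
    el <- network_edges(fn)
    got <- sort(paste(el[, 1], el[, 2], sep = "|"))
    expect_equal(got, oracle_family_edges(net, fam))
    mapped_present <- intersect(network_nodes(net), names(fam))
    expect_setequal(network_nodes(fn),
                    unique(family_of(fam, mapped_present)))
  }
})

make_family_nets <- function(S = 4L, seed = NULL) {
  nets <- lapply(sprintf("sp%d", seq_len(S)), function(s) {
    rand_gene_network(s, n_nodes = 15L, n_edges = 20L)
  })
  fam <- family_map(unlist(lapply(nets, network_nodes)),
                    sample(sprintf("F%02d", 1:8),
                           length(unlist(lapply(nets, network_nodes))),
                           replace = TRUE))
  list(nets = nets, fam = fam,
       fnets = lapply(nets, collapse_to_family_graph, fam = fam),
       profile = conservation_profile(nets, fam))
}

test_that("edge support counts networks and thresholds drop edges", {
  fam <- family_map(c("a1", "b1"), c("A", "B"))
  with_edge <- lapply(sprintf("sp%d", 1:3), function(s) {
    collapse_to_family_graph(gene_network(s, rbind(c("a1", "b1"))), fam)
  })
  without <- collapse_to_family_graph(
    gene_network("sp4", NULL, nodes = c("a1", "b1")), fam)
  fnets <- c(with_edge, list(without))
  nets4 <- lapply(sprintf("sp%d", 1:4), function(s) {
    if (s == "sp4") gene_network(s, NULL, nodes = c("a1", "b1"))
    else gene_network(s, rbind(c("a1", "b1")))
  })
  profile <- conservation_profile(nets4, fam)

  kept <- build_consensus(fnets, profile, 1L, 3L)
  sup <- consensus_supports(kept)
  expect_equal(sup$edges$support, 3L)
  dropped <- build_consensus(fnets, profile, 1L, 4L)
  expect_equal(nrow(consensus_supports(dropped)$edges), 0L)
  expect_error(build_consensus(fnets, profile, 0L, 1L), "thresholds")
  expect_error(build_consensus(fnets, profile, 1L, 5L), "thresholds")
})

test_that("S identical family networks give back that network with supports S", {
  set.seed(505)
  net <- rand_gene_network("sp", n_nodes = 12L, n_edges = 16L)
  fam <- rand_family_map(network_nodes(net), p_unmapped = 0)
  nets <- lapply(sprintf("c%d", 1:4), function(s) {
    structure(list(species_id = s, graph = net$graph), class = "gene_network")
  })
  fnets <- lapply(nets, collapse_to_family_graph, fam = fam)
  cons <- build_consensus(fnets, conservation_profile(nets, fam), 4L, 4L)
  sup <- consensus_supports(cons)
  expect_setequal(sup$nodes$family, network_nodes(fnets[[1]]))
  expect_true(all(sup$nodes$support == 4L))
  expect_true(all(sup$edges$support == 4L))
  el <- network_edges(fnets[[1]])
  expect_equal(nrow(sup$edges), nrow(el))
})

test_that("consensus at thresholds (1,1) equals the brute-force union", {
  set.seed(606)
  for (rep in 1:15) {
    inst <- make_family_nets(S = 3L)
    cons <- build_consensus(inst$fnets, inst$profile, 1L, 1L)
    sup <- consensus_supports(cons)
    # union of nodes with occurrence counts
    expect_setequal(sup$nodes$family, names(inst$profile$counts))
    expect_equal(setNames(sup$nodes$support, sup$nodes$family)[names(inst$profile$counts)],
                 inst$profile$counts)
    # union of edges with occurrence counts, by brute force over networks
    keys <- unlist(lapply(inst$fnets, function(fn) {
      el <- network_edges(fn)
      if (nrow(el)) paste(el[, 1], el[, 2], sep = "|") else character()
    }))
    want <- table(keys)
    got <- consensus_edge_keys(cons)
    expect_setequal(got, paste(names(want), as.integer(want), sep = "|"))
  }
})

test_that("raising either threshold never adds nodes or edges; order irrelevant", {
  set.seed(707)
  for (rep in 1:10) {
    inst <- make_family_nets(S = 4L)
    prev_nodes <- NULL
    for (tn in 1:4) {
      for (te in 1:4) {
        cons <- build_consensus(inst$fnets, inst$profile, tn, te)
        sup <- consensus_supports(cons)
        base <- consensus_supports(
          build_consensus(inst$fnets, inst$profile, 1L, 1L))
        expect_true(all(sup$nodes$family %in% base$nodes$family))
        expect_true(all(sup$nodes$support >= tn))
        if (nrow(sup$edges)) expect_true(all(sup$edges$support >= te))
        # monotone vs one step lower in each threshold
        if (tn > 1) {
          wider <- consensus_supports(
            build_consensus(inst$fnets, inst$profile, tn - 1L, te))
          expect_true(all(sup$nodes$family %in% wider$nodes$family))
        }
        if (te > 1) {
          wider <- consensus_supports(
            build_consensus(inst$fnets, inst$profile, tn, te - 1L))
          expect_true(all(consensus_edge_keys(cons) %in% consensus_edge_keys(
            build_consensus(inst$fnets, inst$profile, tn, te - 1L))))
        }
      }
    }
    shuffled <- build_consensus(rev(inst$fnets), inst$profile, 2L, 2L)
    straight <- build_consensus(inst$fnets, inst$profile, 2L, 2L)
    expect_equal(consensus_supports(shuffled), consensus_supports(straight))
  }
})
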