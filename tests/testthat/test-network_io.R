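test_that("read_edge_list deduplicates unordered pairs and drops self-edges", {
  p <- tsv_fixture("g1\tg2", "g2\tg3", "g3\tg2")
  net <- read_edge_list(p, "ath")
  expect_setequal(network_nodes(net), c("g1", "g2", "g3"))
  expect_equal(nrow(network_edges(net)), 2L)

  p2 <- tsv_fixture("g1\tg1")
  expect_warning(net2 <- read_edge_list(p2, "ath"), "self-edge")
  expect_equal(network_nodes(net2), "g1")
  expect_equal(nrow(network_edges(net2)), 0L)
})

test_that("read_edge_list handles comments, singletons, weights and bad lines", {
  p <- tsv_fixture("# gene_a\tgene_b", "g1\tg2", "lonely")
  net <- read_edge_list(p, "sp")
  expect_setequal(network_nodes(net), c("g1", "g2", "lonely"))
  expect_equal(nrow(network_edges(net)), 1L)

  p3 <- tsv_fixture("g1\tg2\t0.87")
  expect_message(net3 <- read_edge_list(p3, "sp"), "unweighted")
  expect_equal(nrow(network_edges(net3)), 1L)

  p4 <- tsv_fixture("g1\tg2", "a\tb\tc\td")
  expect_error(read_edge_list(p4, "sp"), "line 2")
})

test_that("parsed edge count equals brute-force distinct unordered pairs", {
  set.seed(42)
  for (rep in 1:10) {
    genes <- sprintf("g%d", 1:6)
    a <- sample(genes, 10, replace = TRUE)
    b <- sample(genes, 10, replace = TRUE)
    p <- tsv_fixture(paste(a, b, sep = "\t"))
    net <- suppressWarnings(read_edge_list(p, "sp"))
    keys <- unique(paste(pmin(a, b), pmax(a, b))[a != b])
    expect_equal(nrow(network_edges(net)), length(keys))
    expect_lte(nrow(network_edges(net)), 10L)
  }
})

test_that("read_family_map dedups identical rows and rejects conflicts", {
  p <- tsv_fixture("g1\tHOM000082", "g2\tHOM000082", "g1\tHOM000082")
  fam <- read_family_map(p)
  expect_equal(family_of(fam, c("g1", "g2", "gX")),
               c("HOM000082", "HOM000082", "UNASSIGNED"))

  expect_error(read_family_map(tsv_fixture("g1\tF1", "g1\tF2")), "g1")

  set.seed(1)
  genes <- sprintf("g%03d", 1:100)
  fams <- sample(sprintf("F%d", 1:10), 100, replace = TRUE)
  rows <- paste(genes, fams, sep = "\t")
  p2 <- tsv_fixture(c(rows, rows[sample(100, 5)]))  # 5 verbatim duplicates
  expect_length(read_family_map(p2), 100L)
})

test_that("read_annotation accumulates bin sets per gene", {
  ann <- read_annotation(tsv_fixture("g1\t10", "g1\t35", "g2\t26.3"))
  expect_setequal(ann[["g1"]], c("10", "35"))
  expect_equal(ann[["g2"]], "26.3")
  expect_null(ann[["gX"]])

  expect_length(read_annotation(tsv_fixture(character())), 0L)
  # a row with an empty bin field is a parse error naming the line
  expect_error(read_annotation(tsv_fixture("g1\t")), "line 1")
  expect_error(read_annotation(tsv_fixture("g1\t\t")), "empty bin.*g1")

  set.seed(7)
  genes <- sample(sprintf("g%d", 1:12), 50, replace = TRUE)
  bins <- sample(c("10", "35", "26", "10.2.1"), 50, replace = TRUE)
  ann2 <- read_annotation(tsv_fixture(paste(genes, bins, sep = "\t")))
  by_gene <- lapply(split(bins, genes), function(b) sort(unique(b)))
  for (g in names(by_gene)) expect_setequal(ann2[[g]], by_gene[[g]])
})

test_that("lineage tables parse, validate and round-trip", {
  p <- tsv_fixture("family\tchlorophytes\tmosses\tangiosperms", "F1\t0\t1\t1")
  lin <- read_lineage_table(p)
  expect_equal(lin$clades, c("chlorophytes", "mosses", "angiosperms"))
  expect_equal(unname(lin$presence["F1", ]), c(FALSE, TRUE, TRUE))

  expect_error(read_lineage_table(
    tsv_fixture("family\ta\tb\tc", "F2\t1\t1")), "F2")
  expect_error(read_lineage_table(
    tsv_fixture("family\ta\tb", "F1\t1\t2")), "non-0/1")

  set.seed(11)
  pres <- matrix(runif(20 * 4) < 0.5, nrow = 20,
                 dimnames = list(sprintf("F%02d", 1:20), NULL))
  lin2 <- lineage_table(letters[1:4], pres)
  out <- withr::local_tempfile()
  write_lineage_table(lin2, out)
  back <- read_lineage_table(out)
  expect_equal(back$clades, lin2$clades)
  expect_equal(back$presence, lin2$presence)
})

test_that("write_network edge_tsv round-trips gene networks exactly", {
  set.seed(3)
  for (rep in 1:10) {
    net <- rand_gene_network("sp", n_nodes = 12L, n_edges = 15L)
    p <- withr::local_tempfile()
    write_network(net, p, "edge_tsv")
    back <- read_edge_list(p, "sp")
    expect_setequal(network_nodes(back), network_nodes(net))
    expect_equal(network_edges(back), network_edges(net))
  }
  expect_error(write_network(rand_gene_network(), "x", "dot"), "unknown")
})

test_that("graphml export carries node and edge attributes", {
  skip_if_not_installed("xml2")
  net <- gene_network("sp", rbind(c("a", "b"), c("b", "c")))
  p <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, p, "graphml")
  doc <- xml2::read_xml(p)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='node']"), 3L)

  # consensus edge present in all 4 networks -> graphml support "4"
  fam <- family_map(c("a", "b", "c"), c("F1", "F1", "F2"))
  nets <- lapply(sprintf("sp%d", 1:4), function(s) {
    gene_network(s, rbind(c("a", "b"), c("b", "c")))
  })
  cons <- build_consensus(lapply(nets, collapse_to_family_graph, fam = fam),
                          conservation_profile(nets, fam), 1L, 1L)
  write_network(cons, p, "graphml")
  doc <- xml2::read_xml(p)
  data <- xml2::xml_text(xml2::xml_find_all(
    doc, "//*[local-name()='edge']/*[local-name()='data']"))
  expect_true("4" %in% data)  # edge support serialized at printed precision
})
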