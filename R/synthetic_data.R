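# Planted-core generator: multi-species networks sharing a conserved core of
# families, plus species-specific noise, with matching family map, annotation,
# and lineage tables. The statistical structure it emulates is the premise of
# comparative analysis: truly functional associations recur independently in
# every species, while spurious ones rarely do.
#
# Draw order (fixed, so a single seed determines the bundle byte-for-byte):
#   1. one stratum per core family (multinomial over core_stratum_weights);
#   2. per species, in order: Bernoulli draws over all core-gene pairs
#      (row-major over the upper triangle) with core_edge_prob; then the
#      logged repair pass; then per noise gene (in id order) Bernoulli
#      attachments to every node present before any noise gene was added,
#      with noise_edge_prob, plus a uniform fallback anchor edge if none;
#   3. per species, per core gene in id order: target-vs-unknown annotation
#      coin (P(target bin) = 0.9); noise-gene bins drawn uniformly from
#      other_bins.

#' Specification for a synthetic multi-species benchmark bundle
#'
#' Defaults describe a four-network comparison with 20 planted core families
#' of 3 genes each (gene families are redundant within a network), 200
#' species-specific noise genes per network, sparse noise attachment, and a
#' three-clade lineage in which about half the core predates land plants.
#'
#' @param n_species Number of species networks (>= 2).
#' @param n_core_families Number of planted conserved families (>= 1).
#' @param genes_per_family Genes per core family per species (>= 1).
#' @param n_noise_genes_per_species Species-specific noise genes per network.
#' @param core_edge_prob Probability of an edge between any two core genes of
#'   the same species, in (0, 1].
#' @param noise_edge_prob Probability that a noise gene attaches to any given
#'   pre-existing node, in \[0, 1).
#' @param bait_family Identifier of the core family whose genes are the baits.
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @param clades Ordered clade labels, oldest first.
#' @param core_stratum_weights Per-clade probabilities (sum 1) for a core
#'   family's first appearance.
#' @param target_bin,unknown_bin,other_bins Annotation bin codes for core
#'   genes (target with probability 0.9, else unknown) and noise genes.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species = 4L,
                           n_core_families = 20L,
                           genes_per_family = 3L,
                           n_noise_genes_per_species = 200L,
                           core_edge_prob = 0.3,
                           noise_edge_prob = 0.01,
                           bait_family = "FAM001",
                           seed = 1L,
                           clades = c("chlorophytes", "mosses", "angiosperms"),
                           core_stratum_weights = c(0.5, 0.4, 0.1),
                           target_bin = "10",
                           unknown_bin = "35",
                           other_bins = c("20", "26", "27", "29", "33")) {
  spec <- list(n_species = as.integer(n_species),
               n_core_families = as.integer(n_core_families),
               genes_per_family = as.integer(genes_per_family),
               n_noise_genes_per_species = as.integer(n_noise_genes_per_species),
               core_edge_prob = core_edge_prob,
               noise_edge_prob = noise_edge_prob,
               bait_family = bait_family,
               seed = as.integer(seed),
               clades = as.character(clades),
               core_stratum_weights = core_stratum_weights,
               target_bin = target_bin, unknown_bin = unknown_bin,
               other_bins = as.character(other_bins))
  if (spec$n_species < 2L) abort_io("n_species must be >= 2")
  if (spec$n_core_families < 1L) abort_io("need at least one core family (the bait family)")
  if (spec$genes_per_family < 1L) abort_io("genes_per_family must be >= 1")
  if (!(spec$core_edge_prob > 0 && spec$core_edge_prob <= 1)) {
    abort_io("core_edge_prob must be in (0, 1]")
  }
  if (!(spec$noise_edge_prob >= 0 && spec$noise_edge_prob < 1)) {
    abort_io("noise_edge_prob must be in [0, 1)")
  }
  if (length(spec$clades) < 1L || anyDuplicated(spec$clades)) {
    abort_io("clades must be a non-empty list of unique labels")
  }
  if (length(spec$core_stratum_weights) != length(spec$clades) ||
      abs(sum(spec$core_stratum_weights) - 1) > 1e-8 ||
      any(spec$core_stratum_weights < 0)) {
    abort_io("core_stratum_weights must be per-clade probabilities summing to 1")
  }
  fam_ids <- sprintf("FAM%03d", seq_len(spec$n_core_families))
  if (!spec$bait_family %in% fam_ids) {
    abort_io(sprintf("bait_family must be one of the core families (%s..%s)",
                     fam_ids[1L], fam_ids[length(fam_ids)]))
  }
  structure(spec, class = "synthetic_spec")
}

core_family_ids <- function(spec) sprintf("FAM%03d", seq_len(spec$n_core_families))

#' Generate a synthetic multi-species bundle with a planted conserved core
#'
#' Per species, every core family contributes `genes_per_family` genes
#' (species-prefixed ids, all mapped to the shared family id); edges among
#' core genes are i.i.d. Bernoulli(`core_edge_prob`). A repair pass then
#' guarantees each core family has a gene within 2 steps of the bait family's
#' genes (a minimal gene-bait edge is added and logged), so 2-step
#' neighborhood extraction recovers the full core by construction. Noise
#' genes are species-specific: each attaches independently to pre-existing
#' nodes with `noise_edge_prob` and carries its own single-species family, so
#' noise families are never forced to co-occur across species.
#'
#' Core genes are annotated with the target bin with probability 0.9 and the
#' unknown bin otherwise; noise genes get unrelated bins. The lineage table
#' marks each core family present from its sampled stratum onward and each
#' noise family only in the newest clade.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_bundle`: list with `networks` (list of
#'   [gene_network()]), `baits` (list of [bait_set()]), `family_map`,
#'   `annotation`, `lineage`, `ground_truth` (list: `core_families`, `strata`,
#'   `bait_family`) and `repair_log` (data frame of edges added by repair).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_synthetic_impl(spec))
}

generate_synthetic_impl <- function(spec) {
  fams <- core_family_ids(spec)
  n_clade <- length(spec$clades)
  stratum_idx <- sample.int(n_clade, spec$n_core_families, replace = TRUE,
                            prob = spec$core_stratum_weights)
  strata <- setNames(spec$clades[stratum_idx], fams)

  species <- sprintf("sp%d", seq_len(spec$n_species))
  map_genes <- character(); map_fams <- character()
  ann_genes <- character(); ann_bins <- character()
  networks <- vector("list", spec$n_species)
  baits <- vector("list", spec$n_species)
  repair_log <- list()

  for (si in seq_len(spec$n_species)) {
    sp <- species[si]
    core_genes <- as.vector(t(outer(fams, seq_len(spec$genes_per_family),
                                    function(f, k) sprintf("%s_%s_g%d", sp, f, k))))
    core_fam_of <- rep(fams, each = spec$genes_per_family)
    names(core_fam_of) <- core_genes
    bait_genes <- core_genes[core_fam_of == spec$bait_family]

    # Bernoulli over the upper triangle of the core-gene pair matrix
    n_core <- length(core_genes)
    pairs <- which(upper.tri(matrix(0, n_core, n_core)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    hit <- runif(nrow(pairs)) < spec$core_edge_prob
    em <- cbind(core_genes[pairs[hit, 1L]], core_genes[pairs[hit, 2L]])

    # repair: every core family must reach the baits within 2 steps
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, n_core, name = core_genes)
    if (nrow(em)) g <- igraph::add_edges(g, as.vector(t(em)))
    d <- igraph::distances(g, v = bait_genes)
    mind <- apply(d, 2L, min)
    for (f in fams) {
      if (min(mind[core_fam_of == f]) > 2) {
        gene <- core_genes[core_fam_of == f][1L]
        em <- rbind(em, c(gene, bait_genes[1L]))
        repair_log[[length(repair_log) + 1L]] <-
          data.frame(species = sp, family = f, gene = gene, bait = bait_genes[1L])
      }
    }

    # species-specific noise genes, attached to pre-noise nodes
    noise_genes <- sprintf("%s_noise%04d", sp, seq_len(spec$n_noise_genes_per_species))
    for (ng in noise_genes) {
      att <- core_genes[runif(n_core) < spec$noise_edge_prob]
      if (!length(att)) att <- core_genes[sample.int(n_core, 1L)]
      em <- rbind(em, cbind(ng, att))
    }
    networks[[si]] <- gene_network(sp, edges = em, nodes = noise_genes)
    baits[[si]] <- bait_set(sp, bait_genes)

    map_genes <- c(map_genes, core_genes, noise_genes)
    map_fams <- c(map_fams, unname(core_fam_of),
                  sprintf("NOISEFAM_%s_%04d", sp, seq_along(noise_genes)))
  }

  for (si in seq_len(spec$n_species)) {
    sp <- species[si]
    core_genes <- map_genes[startsWith(map_genes, paste0(sp, "_FAM"))]
    bins <- ifelse(runif(length(core_genes)) < 0.9,
                   spec$target_bin, spec$unknown_bin)
    noise_genes <- map_genes[startsWith(map_genes, paste0(sp, "_noise"))]
    nbins <- spec$other_bins[sample.int(length(spec$other_bins),
                                        length(noise_genes), replace = TRUE)]
    ann_genes <- c(ann_genes, core_genes, noise_genes)
    ann_bins <- c(ann_bins, bins, nbins)
  }

  fam_map <- family_map(map_genes, map_fams)
  ann <- annotation_table(ann_genes, ann_bins)

  noise_fams <- sort(unique(map_fams[startsWith(map_fams, "NOISEFAM_")]))
  all_fams <- c(fams, noise_fams)
  pres <- matrix(FALSE, nrow = length(all_fams), ncol = n_clade,
                 dimnames = list(all_fams, spec$clades))
  for (f in fams) pres[f, seq_len(n_clade) >= match(strata[f], spec$clades)] <- TRUE
  pres[noise_fams, n_clade] <- TRUE
  lin <- lineage_table(spec$clades, pres)

  truth_strata <- c(strata,
                    setNames(rep(spec$clades[n_clade], length(noise_fams)), noise_fams))
  structure(list(
    networks = networks,
    baits = baits,
    family_map = fam_map,
    annotation = ann,
    lineage = lin,
    ground_truth = list(core_families = fams, strata = truth_strata,
                        bait_family = spec$bait_family),
    repair_log = if (length(repair_log)) do.call(rbind, repair_log) else
      data.frame(species = character(), family = character(),
                 gene = character(), bait = character()),
    spec = spec
  ), class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d species, %d core families, seed=%d (%d repair edges)\n",
              x$spec$n_species, x$spec$n_core_families, x$spec$seed,
              nrow(x$repair_log)))
  invisible(x)
}

#' Write a synthetic bundle to a directory in pipeline input formats
#'
#' Emits per-species edge lists (`<sp>.network.tsv`) and bait lists
#' (`<sp>.baits.txt`), `families.tsv`, `annotation.tsv`, `lineage.tsv`,
#' `ground_truth.json`, and a ready-to-run `pipeline.yaml` config.
#'
#' @param bundle A [generate_synthetic()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net_entries <- list()
  for (i in seq_along(bundle$networks)) {
    sp <- bundle$networks[[i]]$species_id
    npath <- file.path(dir, paste0(sp, ".network.tsv"))
    bpath <- file.path(dir, paste0(sp, ".baits.txt"))
    write_network(bundle$networks[[i]], npath, "edge_tsv")
    writeLines(sort(bundle$baits[[i]]$baits), bpath)
    net_entries[[i]] <- list(path = paste0(sp, ".network.tsv"),
                             species_id = sp,
                             baits = paste0(sp, ".baits.txt"))
  }
  write_mapping(bundle$family_map, file.path(dir, "families.tsv"))
  write_mapping(bundle$annotation, file.path(dir, "annotation.tsv"))
  write_lineage_table(bundle$lineage, file.path(dir, "lineage.tsv"))
  jsonlite::write_json(
    list(core_families = bundle$ground_truth$core_families,
         strata = as.list(bundle$ground_truth$strata),
         bait_family = bundle$ground_truth$bait_family),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  cfg <- list(networks = net_entries,
              steps = 2L,
              family_map = "families.tsv",
              annotation = "annotation.tsv",
              lineage = "lineage.tsv",
              min_networks = bundle$spec$n_species,
              min_node_support = min(3L, bundle$spec$n_species),
              min_edge_support = min(3L, bundle$spec$n_species),
              target_bins = bundle$spec$target_bin,
              unknown_bins = bundle$spec$unknown_bin,
              out_dir = "results")
  yaml::write_yaml(cfg, file.path(dir, "pipeline.yaml"))
  invisible(dir)
}
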