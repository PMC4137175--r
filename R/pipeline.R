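# End-to-end orchestration: extract -> conserve -> consensus -> phylo ->
# relevance from a single YAML/JSON config, with all artifacts written as
# sorted TSV/GraphML so reruns on identical inputs are byte-identical.

#' Read and validate a pipeline configuration
#'
#' The config is a YAML (or JSON) file with fields: `networks` (list of
#' entries `path`, `species_id`, `baits` — inline gene vector or path to a
#' one-gene-per-line file), `steps`, `family_map`, `annotation`, `lineage`,
#' `min_networks`, `min_node_support`, `min_edge_support`, `target_bins`,
#' `unknown_bins`, `out_dir`. Relative paths are resolved against the config
#' file's directory. A comparison needs at least two networks.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(config) {
  base <- "."
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort_io(sprintf("config file not found: %s", config))
    base <- dirname(config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  nets <- config$networks
  if (is.null(nets) || length(nets) < 2L) {
    abort_io("config must list at least 2 networks (a comparison needs multiple species)")
  }
  resolve <- function(p) {
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
  }
  cfg <- list(
    networks = lapply(nets, function(e) {
      if (is.null(e$path) || is.null(e$species_id) || is.null(e$baits)) {
        abort_io("each network entry needs path, species_id and baits")
      }
      e$path <- resolve(e$path)
      if (length(e$baits) == 1L && file.exists(resolve(e$baits))) {
        e$baits_path <- resolve(e$baits)
      }
      e
    }),
    steps = as.integer(config$steps %||% 2L),
    family_map = resolve(config$family_map %||%
                           abort_io("config needs a family_map path")),
    annotation = if (!is.null(config$annotation)) resolve(config$annotation),
    lineage = if (!is.null(config$lineage)) resolve(config$lineage),
    min_networks = config$min_networks,
    min_node_support = as.integer(config$min_node_support %||% 3L),
    min_edge_support = as.integer(config$min_edge_support %||% 3L),
    target_bins = as.character(config$target_bins %||% "10"),
    unknown_bins = as.character(config$unknown_bins %||% "35"),
    dedupe = isTRUE(config$dedupe),
    out_dir = config$out_dir %||% "coexcompare_results"
  )
  if (!grepl("^/", cfg$out_dir)) cfg$out_dir <- file.path(base, cfg$out_dir)
  ids <- vapply(cfg$networks, `[[`, "", "species_id")
  if (anyDuplicated(ids)) abort_io("network species_ids must be distinct")
  cfg$min_networks <- as.integer(cfg$min_networks %||% length(cfg$networks))
  structure(cfg, class = "pipeline_config")
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

log_stage <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the full comparative co-expression pipeline
#'
#' Stages: read inputs; extract the `steps`-hop bait neighborhood per network;
#' score family conservation over the neighborhoods; label networks and filter
#' conserved cores at `min_networks`; collapse to family graphs and build the
#' consensus network at the support thresholds; overlay family first
#' appearance from the lineage table; tally annotation composition per
#' conservation class. All artifacts are written under `out_dir` (see the
#' returned bundle's `paths`); a JSON run summary records per-stage counts.
#'
#' @param config A config path or list, see [read_pipeline_config()].
#' @return Invisible `pipeline_report`: list with the in-memory objects
#'   (`neighborhoods`, `labeled`, `cores`, `profile`, `consensus`, `strata`,
#'   `relevance`, ...), a `paths` list of written files, and `summary`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  fam <- stage_wrap("read_inputs", read_family_map(cfg$family_map))
  ann <- if (!is.null(cfg$annotation)) {
    stage_wrap("read_inputs", read_annotation(cfg$annotation))
  }
  lin <- if (!is.null(cfg$lineage)) {
    stage_wrap("read_inputs", read_lineage_table(cfg$lineage))
  }

  log_stage("extract: %d networks, steps=%d", length(cfg$networks), cfg$steps)
  neighborhoods <- lapply(cfg$networks, function(e) {
    stage_wrap("extract", {
      net <- read_edge_list(e$path, e$species_id)
      bgenes <- if (!is.null(e$baits_path)) {
        readLines(e$baits_path)
      } else {
        as.character(e$baits)
      }
      bgenes <- bgenes[nzchar(trimws(bgenes))]
      extract_neighborhood(net, bait_set(e$species_id, bgenes), cfg$steps)
    })
  })
  for (nb in neighborhoods) {
    p <- file.path(cfg$out_dir, paste0(nb$species_id, ".neighborhood.tsv"))
    write_network(nb, p, "edge_tsv")
    paths$neighborhoods[[nb$species_id]] <- p
  }

  log_stage("conserve: scoring families over %d neighborhoods", length(neighborhoods))
  profile <- stage_wrap("conserve", conservation_profile(neighborhoods, fam))
  labeled <- lapply(neighborhoods, label_network, fam = fam, profile = profile)
  ptab <- profile_table(profile, neighborhoods, fam)
  paths$profile <- file.path(cfg$out_dir, "conservation_profile.tsv")
  write.table(ptab, paths$profile, sep = "\t", quote = FALSE, row.names = FALSE)
  cdist <- do.call(rbind, lapply(labeled, function(l) {
    cbind(species = l$species_id, class_distribution(l))
  }))
  paths$class_distribution <- file.path(cfg$out_dir, "class_distribution.tsv")
  write.table(cdist, paths$class_distribution, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cores <- lapply(labeled, conserved_core, min_networks = cfg$min_networks)
  for (l in labeled) {
    p <- file.path(cfg$out_dir, paste0(l$species_id, ".labeled.graphml"))
    write_network(l, p, "graphml")
    paths$labeled[[l$species_id]] <- p
  }
  for (co in cores) {
    p <- file.path(cfg$out_dir, paste0(co$species_id, ".core.graphml"))
    write_network(co, p, "graphml")
    paths$cores[[co$species_id]] <- p
  }

  log_stage("consensus: thresholds node>=%d edge>=%d",
            cfg$min_node_support, cfg$min_edge_support)
  family_nets <- lapply(neighborhoods, collapse_to_family_graph, fam = fam)
  consensus <- stage_wrap("consensus",
    build_consensus(family_nets, profile,
                    cfg$min_node_support, cfg$min_edge_support))

  strata <- NULL
  strata_tab <- NULL
  if (!is.null(lin)) {
    log_stage("phylo: %d clades", length(lin$clades))
    strata <- stage_wrap("phylo", first_appearance(lin))
    consensus <- annotate_strata(consensus, strata)
    strata_tab <- stratum_summary(consensus, lin$clades)
    paths$strata_summary <- file.path(cfg$out_dir, "strata_summary.tsv")
    write.table(strata_tab, paths$strata_summary, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  paths$consensus <- file.path(cfg$out_dir, "consensus.graphml")
  write_network(consensus, paths$consensus, "graphml")

  relevance <- NULL
  if (!is.null(ann)) {
    log_stage("relevance: target bins %s vs unknown %s",
              paste(cfg$target_bins, collapse = ","),
              paste(cfg$unknown_bins, collapse = ","))
    relevance <- stage_wrap("relevance",
      tally_by_class(labeled, ann, cfg$target_bins, cfg$unknown_bins,
                     dedupe = cfg$dedupe))
    paths$relevance <- file.path(cfg$out_dir, "relevance.tsv")
    write.table(relevance, paths$relevance, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  summary <- list(
    n_networks = length(neighborhoods),
    steps = cfg$steps,
    neighborhood_sizes = setNames(
      lapply(neighborhoods, function(n) list(genes = igraph::vcount(n$graph),
                                             edges = igraph::ecount(n$graph))),
      vapply(neighborhoods, `[[`, "", "species_id")),
    n_families = length(profile$counts),
    families_per_class = as.list(table(profile$counts)),
    min_networks = cfg$min_networks,
    core_sizes = setNames(vapply(cores, function(co) as.integer(igraph::vcount(co$graph)), 0L),
                          vapply(cores, `[[`, "", "species_id")),
    consensus = list(families = igraph::vcount(consensus$graph),
                     edges = igraph::ecount(consensus$graph),
                     self_loops = sum(igraph::which_loop(consensus$graph)),
                     min_node_support = cfg$min_node_support,
                     min_edge_support = cfg$min_edge_support),
    strata = if (!is.null(strata_tab)) {
      setNames(as.list(strata_tab$families), strata_tab$stratum)
    }
  )
  paths$summary <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, pretty = TRUE)
  log_stage("done: outputs in %s", cfg$out_dir)

  invisible(structure(list(
    config = cfg, neighborhoods = neighborhoods, labeled = labeled,
    cores = cores, profile = profile, family_nets = family_nets,
    consensus = consensus, strata = strata, strata_summary = strata_tab,
    relevance = relevance, paths = paths, summary = summary
  ), class = "pipeline_report"))
}

#' Human-readable summary of a pipeline run
#'
#' Prints per-stage counts: networks and neighborhood sizes, families per
#' conservation class, conserved-core sizes, consensus nodes/edges, and
#' stratum counts. Errors if an expected artifact has gone missing, naming
#' the stage it belongs to.
#'
#' @param object A `pipeline_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The summary lines, invisibly.
#' @export
summary.pipeline_report <- function(object, ...) {
  stages <- list(extract = object$paths$neighborhoods,
                 conserve = c(object$paths$profile, object$paths$class_distribution),
                 consensus = object$paths$consensus)
  for (stage in names(stages)) {
    missing <- !file.exists(unlist(stages[[stage]]))
    if (any(missing)) {
      stop(sprintf("[stage %s] missing output file: %s", stage,
                   paste(unlist(stages[[stage]])[missing], collapse = ", ")),
           call. = FALSE)
    }
  }
  s <- object$summary
  lines <- c(
    sprintf("Comparative co-expression run: %d networks, %d-step neighborhoods",
            s$n_networks, s$steps),
    vapply(names(s$neighborhood_sizes), function(sp) {
      sprintf("  %s: %d genes, %d edges (conserved core at >=%d: %d genes)",
              sp, s$neighborhood_sizes[[sp]]$genes, s$neighborhood_sizes[[sp]]$edges,
              s$min_networks, s$core_sizes[[sp]])
    }, ""),
    sprintf("Families: %d total; per conservation class: %s", s$n_families,
            paste(sprintf("%s:%s", names(s$families_per_class),
                          unlist(s$families_per_class)), collapse = "  ")),
    sprintf("Consensus: %d families, %d edges (%d self-loops) at node>=%d edge>=%d",
            s$consensus$families, s$consensus$edges, s$consensus$self_loops,
            s$consensus$min_node_support, s$consensus$min_edge_support),
    if (!is.null(s$strata)) {
      sprintf("First appearance: %s",
              paste(sprintf("%s:%s", names(s$strata), unlist(s$strata)),
                    collapse = "  "))
    }
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
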