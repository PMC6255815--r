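#' Pipeline configuration
#'
#' Collects every input path and every tunable of the screening chain into
#' a single validated list. Unknown keys are rejected; a fully-defaulted
#' configuration (paths only) is valid. A configuration can also be read
#' from a YAML file with \code{\link{read_pipeline_config}}.
#'
#' @param components Path to the herb-component ADME table (TSV).
#' @param pairs Path to the component-target pair table (TSV).
#' @param interactome Path to the background interactome edge list
#'   (TSV/SIF).
#' @param disease_dir Directory of per-source disease gene lists, or a
#'   single gene-list file.
#' @param gmt Path to the annotation GMT file (optional; enrichment is
#'   skipped when absent).
#' @param out_dir Output directory for stage artifacts and the run report.
#' @param ob_min,dl_min ADME screening thresholds (defaults 20, 0.18).
#' @param keep_manual Honour the \code{manual_keep} flag (default TRUE).
#' @param hops Seed-expansion radius (default 1).
#' @param combine \code{"intersect"} (default) or \code{"union"} of the two
#'   PPI subnetworks.
#' @param multiplier Stage-1 degree multiplier (default 2).
#' @param stage2_rule \code{"median"} or \code{"explicit"}.
#' @param stage2_cutoffs Named list of six explicit cutoffs, when
#'   \code{stage2_rule = "explicit"}.
#' @param mcode Parameters from \code{\link{mcode_params}}.
#' @param enrich_mode \code{"hypergeometric"} or \code{"ease"}.
#' @param enrich_criterion \code{"bonferroni_lt"} or \code{"raw_lt"}.
#' @param alpha Enrichment significance level (default 0.05).
#' @param seed Integer seed recorded in the report (the analysis stages are
#'   deterministic; the seed matters only when inputs are generated).
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(components, pairs, interactome, disease_dir,
                            gmt = NULL, out_dir = "netpharm_out",
                            ob_min = 20, dl_min = 0.18, keep_manual = TRUE,
                            hops = 1, combine = c("intersect", "union"),
                            multiplier = 2,
                            stage2_rule = c("median", "explicit"),
                            stage2_cutoffs = NULL,
                            mcode = mcode_params(),
                            enrich_mode = c("hypergeometric", "ease"),
                            enrich_criterion = c("bonferroni_lt", "raw_lt"),
                            alpha = 0.05, seed = 1) {
  structure(list(components = components, pairs = pairs,
                 interactome = interactome, disease_dir = disease_dir,
                 gmt = gmt, out_dir = out_dir,
                 ob_min = ob_min, dl_min = dl_min,
                 keep_manual = keep_manual, hops = hops,
                 combine = match.arg(combine),
                 multiplier = multiplier,
                 stage2_rule = match.arg(stage2_rule),
                 stage2_cutoffs = stage2_cutoffs,
                 mcode = mcode,
                 enrich_mode = match.arg(enrich_mode),
                 enrich_criterion = match.arg(enrich_criterion),
                 alpha = alpha, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; unknown keys
#' raise an error. The \code{mcode} key may be a mapping of
#' \code{\link{mcode_params}} arguments.
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$mcode)) raw$mcode <- do.call(mcode_params, raw$mcode)
  do.call(pipeline_config, raw)
}

log_stage <- function(stage, msg, quiet = FALSE) {
  if (!quiet) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full screening pipeline
#'
#' Executes, in order: ADME bioactivity screening; component-target
#' bipartite assembly and candidate-component ranking; disease target-set
#' union and formula/disease intersection; 1-hop (configurable) seed
#' expansion of both target sets over the background interactome;
#' combination of the two PPI subnetworks (intersection by default); the
#' two-stage six-statistic core-target screen; MCODE clustering of the core
#' network; and over-representation analysis of the core nodes. Every stage
#' writes its artifact under \code{config$out_dir} and the count trail is
#' returned (and written) as a machine-readable run report. The run is
#' deterministic given identical inputs and configuration.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param quiet Suppress per-stage log messages.
#' @return The run report, a list (also serialized to
#'   \code{report.json}).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(tool = "netpharm",
                 version = as.character(utils::packageVersion("netpharm")),
                 seed = config$seed,
                 config = config[setdiff(names(config), "mcode")],
                 mcode_params = unclass(config$mcode))

  # stage 1: ADME screen ---------------------------------------------------
  comps <- read_component_table(config$components)
  bio <- screen_bioactive(comps, ob_min = config$ob_min,
                          dl_min = config$dl_min,
                          keep_manual = config$keep_manual, quiet = TRUE)
  write_component_table(bio, file.path(out, "bioactive.tsv"))
  report$components <- list(total = nrow(comps), bioactive = nrow(bio),
                            per_herb = as.list(table(bio$herb)))
  log_stage("screen", sprintf("retained %d/%d components (ob >= %g, dl >= %g)",
                              nrow(bio), nrow(comps), config$ob_min,
                              config$dl_min), quiet)

  # stage 2: targets -------------------------------------------------------
  pairs <- read_pair_table(config$pairs)
  pairs <- pairs[pairs$component_id %in% bio$component_id, , drop = FALSE]
  bip <- build_bipartite(pairs)
  write_network(bip, file.path(out, "bipartite.graphml"), format = "graphml")
  cand <- candidate_components(bip, min_degree = "median")
  utils::write.table(cand, file.path(out, "candidate_components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  f_targets <- formula_targets(bip)
  dis_paths <- if (dir.exists(config$disease_dir)) {
    list.files(config$disease_dir, full.names = TRUE)
  } else config$disease_dir
  dis_sets <- lapply(dis_paths, function(p) {
    target_set(read_gene_list(p), label = basename(p))
  })
  d_targets <- union_targets(dis_sets, label = "disease")
  common <- intersect_targets(f_targets, d_targets)
  write_gene_list(common$members, file.path(out, "common_targets.tsv"))
  report$targets <- list(
    pairs = nrow(pairs),
    bipartite_nodes = igraph::vcount(bip),
    bipartite_edges = igraph::ecount(bip),
    candidate_components = nrow(cand),
    formula = length(f_targets),
    per_source = stats::setNames(lapply(dis_sets, length),
                                 vapply(dis_sets, `[[`, "", "label")),
    disease = length(d_targets),
    common = length(common))
  log_stage("targets", sprintf("formula %d, disease %d, common %d",
                               length(f_targets), length(d_targets),
                               length(common)), quiet)

  # stage 3: PPI assembly --------------------------------------------------
  inter <- read_edge_list(config$interactome, quiet = TRUE)
  net_f <- expand_seeds(inter, f_targets, max_hops = config$hops,
                        quiet = TRUE)
  net_d <- expand_seeds(inter, d_targets, max_hops = config$hops,
                        quiet = TRUE)
  combined <- if (config$combine == "intersect") {
    intersect_networks(net_f, net_d)
  } else {
    union_networks(net_f, net_d)
  }
  write_network(net_f, file.path(out, "ppi_formula.graphml"),
                format = "graphml")
  write_network(net_d, file.path(out, "ppi_disease.graphml"),
                format = "graphml")
  write_network(combined, file.path(out, "ppi_combined.graphml"),
                format = "graphml")
  report$ppi <- list(
    formula = list(nodes = igraph::vcount(net_f),
                   edges = igraph::ecount(net_f)),
    disease = list(nodes = igraph::vcount(net_d),
                   edges = igraph::ecount(net_d)),
    combined = list(nodes = igraph::vcount(combined),
                    edges = igraph::ecount(combined)))
  log_stage("ppi", sprintf("formula %d/%d, disease %d/%d, %s %d/%d",
                           igraph::vcount(net_f), igraph::ecount(net_f),
                           igraph::vcount(net_d), igraph::ecount(net_d),
                           config$combine,
                           igraph::vcount(combined),
                           igraph::ecount(combined)), quiet)

  # stage 4: core screen ---------------------------------------------------
  screen <- core_screen(combined, multiplier = config$multiplier,
                        rule = config$stage2_rule,
                        cutoffs = config$stage2_cutoffs, quiet = TRUE)
  write_centrality_table(screen$centrality,
                         file.path(out, "stage1_centrality.tsv"))
  if (igraph::vcount(screen$core_network) > 0L) {
    write_network(screen$core_network, file.path(out, "core.graphml"),
                  format = "graphml")
  }
  write_gene_list(screen$core_nodes, file.path(out, "core_targets.tsv"))
  report$core_screen <- list(
    stage1_threshold = screen$stage1_threshold,
    stage1_nodes = igraph::vcount(screen$stage1_network),
    stage1_edges = igraph::ecount(screen$stage1_network),
    stage2_thresholds = screen$stage2_thresholds,
    core_nodes = length(screen$core_nodes),
    core_edges = igraph::ecount(screen$core_network))
  log_stage("core-screen",
            sprintf("stage-1 %d nodes (dc >= %g), core %d nodes",
                    igraph::vcount(screen$stage1_network),
                    screen$stage1_threshold, length(screen$core_nodes)),
            quiet)

  # stage 5: clustering ----------------------------------------------------
  clusters <- if (igraph::vcount(screen$core_network) > 0L) {
    mcode(screen$core_network, params = config$mcode)
  } else list()
  write_clusters(clusters, file.path(out, "clusters.tsv"))
  report$clusters <- lapply(clusters, function(cl)
    list(seed = cl$seed, size = cl$size, score = cl$score))
  log_stage("cluster", sprintf("%d cluster(s)", length(clusters)), quiet)

  # stage 6: enrichment ----------------------------------------------------
  if (!is.null(config$gmt) && length(screen$core_nodes) > 0L) {
    ann <- read_gmt(config$gmt)
    rows <- enrich(target_set(screen$core_nodes, "core"), ann,
                   mode = config$enrich_mode, quiet = TRUE)
    sig <- filter_significant(rows, criterion = config$enrich_criterion,
                              alpha = config$alpha)
    utils::write.table(rows, file.path(out, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$enrichment <- list(terms_tested = nrow(rows),
                              significant = nrow(sig),
                              top_term = if (nrow(rows) > 0L)
                                rows$term_id[1L] else NA_character_)
    log_stage("enrich", sprintf("%d significant term(s) (%s < %g)",
                                nrow(sig), config$enrich_criterion,
                                config$alpha), quiet)
  } else {
    report$enrichment <- list(terms_tested = 0L, significant = 0L,
                              top_term = NA_character_)
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
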