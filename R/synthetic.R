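#' @title Synthetic pipeline inputs with known ground truth
#' @description Every input the pipeline consumes -- component ADME tables,
#'   component-target maps, per-source disease lists, background
#'   interactomes, GMT annotation collections -- can be generated with a
#'   controlled structure (pass rates, overlap fractions, planted dense
#'   modules, planted hubs, one spiked enriched term) so every stage is
#'   testable against exact expectations without any database access. All
#'   generators are pure functions of their parameters and a seed; the
#'   caller's RNG state is left untouched.
#' @name synthetic
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# fan a pipeline-wide seed out to per-generator seeds, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

#' Generate a herb-component ADME table
#'
#' Draws \code{round(pass_fraction * n)} components that satisfy the
#' screening criteria (OB uniform on [20, 60], DL uniform on [0.18, 0.5])
#' and makes the rest fail at least one criterion (low OB, low DL, both, or
#' a missing value). Optionally flags \code{n_manual_keep} failing
#' components as manually retained, emulating curated additions.
#'
#' @param n_per_herb Named integer vector, components per herb.
#' @param pass_fraction Fraction of components passing OB >= 20 and
#'   DL >= 0.18.
#' @param n_manual_keep Number of failing components flagged
#'   \code{manual_keep} (default 0).
#' @param seed Integer seed.
#' @return List with \code{table} (component data frame) and \code{truth}
#'   (fields \code{expected_pass} -- the ids passing the ADME filter --,
#'   \code{manual_keep} ids, \code{seed}, and the parameters).
#' @export
gen_components <- function(n_per_herb = c(herbA = 230, herbB = 85,
                                          herbC = 280, herbD = 5),
                           pass_fraction = 0.235, n_manual_keep = 0,
                           seed = 1) {
  stopifnot(all(n_per_herb >= 0))
  if (pass_fraction < 0 || pass_fraction > 1) {
    stop("pass_fraction must be in [0, 1]")
  }
  n <- sum(n_per_herb)
  with_seed(seed, {
    ids <- sprintf("MOL%05d", seq_len(n))
    herbs <- rep(names(n_per_herb), n_per_herb)
    n_pass <- round(pass_fraction * n)
    pass <- rep(FALSE, n)
    pass[sample.int(n, n_pass)] <- TRUE
    ob <- numeric(n); dl <- numeric(n)
    ob[pass] <- stats::runif(n_pass, 20, 60)
    dl[pass] <- stats::runif(n_pass, 0.18, 0.5)
    fail_idx <- which(!pass)
    fail_mode <- sample(c("ob", "dl", "both", "missing"),
                        length(fail_idx), replace = TRUE)
    for (j in seq_along(fail_idx)) {
      i <- fail_idx[j]
      switch(fail_mode[j],
        ob = { ob[i] <- stats::runif(1, 0, 19.99); dl[i] <- stats::runif(1, 0.18, 0.5) },
        dl = { ob[i] <- stats::runif(1, 20, 60); dl[i] <- stats::runif(1, 0, 0.179) },
        both = { ob[i] <- stats::runif(1, 0, 19.99); dl[i] <- stats::runif(1, 0, 0.179) },
        missing = { ob[i] <- NA_real_; dl[i] <- stats::runif(1, 0, 0.5) })
    }
    manual <- rep(FALSE, n)
    if (n_manual_keep > 0) {
      if (n_manual_keep > length(fail_idx)) {
        stop("n_manual_keep exceeds the number of failing components")
      }
      manual[sample(fail_idx, n_manual_keep)] <- TRUE
    }
    table <- data.frame(component_id = ids,
                        name = paste0("compound_", seq_len(n)),
                        herb = herbs, ob = round(ob, 2), dl = round(dl, 3),
                        manual_keep = manual, stringsAsFactors = FALSE)
    # bookkeeping from the realized (rounded) values, not the draw
    realized_pass <- !is.na(table$ob) & !is.na(table$dl) &
      table$ob >= 20 & table$dl >= 0.18
    list(table = table,
         truth = list(seed = seed,
                      expected_pass = ids[realized_pass],
                      manual_keep = ids[manual],
                      params = list(n_per_herb = as.list(n_per_herb),
                                    pass_fraction = pass_fraction,
                                    n_manual_keep = n_manual_keep)))
  })
}

#' Generate a component-target map with heavy-tailed component degrees
#'
#' Component degrees are drawn from a truncated discrete power law
#' (P(d) proportional to d^-exponent on 1..number of targets) and then
#' rescaled so the sample mean approximates \code{mean_degree}; each
#' component is linked to that many distinct targets drawn uniformly.
#'
#' @param component_ids Character vector of component identifiers.
#' @param targets Either a count (targets named \code{TG0001}, ...) or a
#'   character vector naming the target pool.
#' @param mean_degree Desired mean number of targets per component.
#' @param exponent Power-law exponent of the raw degree draw (default 2.5).
#' @param seed Integer seed.
#' @return List with \code{pairs} (component_id/target data frame) and
#'   \code{truth} (per-component \code{degrees}, the target pool, seed,
#'   parameters).
#' @export
gen_component_target <- function(component_ids, targets = 186,
                                 mean_degree = 18, exponent = 2.5, seed = 1) {
  stopifnot(length(component_ids) > 0L, mean_degree >= 1)
  pool <- if (is.character(targets)) {
    normalize_symbols(targets)
  } else {
    sprintf("TG%04d", seq_len(targets))
  }
  nt <- length(pool)
  with_seed(seed, {
    kk <- seq_len(nt)
    pr <- kk^(-exponent)
    d0 <- sample(kk, length(component_ids), replace = TRUE, prob = pr)
    d <- pmin(nt, pmax(1L, as.integer(round(d0 * mean_degree / mean(d0)))))
    pairs <- do.call(rbind, lapply(seq_along(component_ids), function(i) {
      data.frame(component_id = component_ids[i],
                 target = sample(pool, d[i]), stringsAsFactors = FALSE)
    }))
    list(pairs = pairs,
         truth = list(seed = seed,
                      degrees = stats::setNames(d, component_ids),
                      target_pool = pool,
                      params = list(mean_degree = mean_degree,
                                    exponent = exponent)))
  })
}

#' Generate a disease target list with a controlled overlap
#'
#' Draws exactly \code{round(overlap_fraction * n)} members from
#' \code{overlap_with} and the remainder from the rest of the universe, so
#' the intersection with \code{overlap_with} is known exactly. The list is
#' also split into overlapping per-source sublists (each member is assigned
#' to one or more of \code{n_sources} mock source databases), whose union
#' reproduces the full list.
#'
#' @param universe Character vector of all possible gene symbols.
#' @param n List size.
#' @param overlap_with \code{target_set} or character vector the overlap is
#'   planted against.
#' @param overlap_fraction Fraction of \code{n} drawn from
#'   \code{overlap_with}.
#' @param n_sources Number of mock per-source sublists (default 5).
#' @param seed Integer seed.
#' @return List with \code{targets} (a \code{target_set}), \code{sources}
#'   (list of \code{target_set}s whose union is \code{targets}) and
#'   \code{truth} (the planted \code{intersection}, seed, parameters).
#' @export
gen_disease_targets <- function(universe, n, overlap_with,
                                overlap_fraction = 0.1, n_sources = 5,
                                seed = 1) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]")
  }
  universe <- unique(normalize_symbols(universe))
  ov_pool <- as_target_members(overlap_with)
  k <- round(overlap_fraction * n)
  rest_pool <- setdiff(universe, ov_pool)
  if (k > length(ov_pool)) stop("overlap pool smaller than requested overlap")
  if (n - k > length(rest_pool)) stop("universe too small for requested list")
  with_seed(seed, {
    hits <- if (k > 0) sample(ov_pool, k) else character(0)
    rest <- if (n - k > 0) sample(rest_pool, n - k) else character(0)
    members <- sample(c(hits, rest))
    src_names <- sprintf("source%02d", seq_len(n_sources))
    assign_n <- sample(seq_len(min(3L, n_sources)), length(members),
                       replace = TRUE)
    src_members <- stats::setNames(
      lapply(src_names, function(s) character(0)), src_names)
    for (i in seq_along(members)) {
      for (s in sample(src_names, assign_n[i])) {
        src_members[[s]] <- c(src_members[[s]], members[i])
      }
    }
    list(targets = target_set(members, label = "disease"),
         sources = lapply(src_names, function(s)
           target_set(src_members[[s]], label = s)),
         truth = list(seed = seed, intersection = sort(hits),
                      params = list(n = n,
                                    overlap_fraction = overlap_fraction,
                                    n_sources = n_sources)))
  })
}

#' Generate a scale-free interactome with planted structure
#'
#' A preferential-attachment backbone (seeded with a complete graph on
#' \code{m} vertices, each later vertex attaching \code{m} edges), on top of
#' which dense modules (internal edges drawn with probability
#' \code{p_intra} over a sampled disjoint node set) and hub nodes (wired to
#' \code{hub_degree} distinct random nodes) are planted.
#'
#' @param n Number of nodes.
#' @param m Attachment parameter (edges per new vertex; default 3).
#' @param planted_modules List of \code{list(size =, p_intra =)} entries.
#' @param hub_degree Degree to wire each planted hub to (0 = no hubs).
#' @param n_hubs Number of planted hubs (default 1 when
#'   \code{hub_degree > 0}).
#' @param seed Integer seed.
#' @return List with \code{network} (an \code{igraph} network, roles
#'   \code{interactor}) and \code{truth} (fields \code{modules} -- list of
#'   node-name sets --, \code{hubs}, \code{backbone_edges}, seed,
#'   parameters).
#' @export
gen_interactome <- function(n, m = 3, planted_modules = list(),
                            hub_degree = 0,
                            n_hubs = if (hub_degree > 0) 1L else 0L,
                            seed = 1) {
  stopifnot(n > m, m >= 1)
  with_seed(seed, {
    g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE,
                           start.graph = igraph::make_full_graph(m))
    nms <- sprintf("G%04d", seq_len(n))
    igraph::V(g)$name <- nms
    em <- igraph::as_edgelist(g, names = TRUE)
    backbone_edges <- nrow(em)
    # plant hubs first so modules never overlap them
    hubs <- character(0)
    if (n_hubs > 0 && hub_degree > 0) {
      hubs <- sample(nms, n_hubs)
      for (h in hubs) {
        others <- sample(setdiff(nms, h), min(hub_degree, n - 1L))
        em <- rbind(em, cbind(h, others))
      }
    }
    # modules are planted on nodes non-adjacent to earlier modules, so each
    # planted complex is a separate unit and recovery against the truth is
    # well-posed (a background edge between two planted cliques would make
    # any density-based clusterer merge them)
    free <- setdiff(nms, hubs)
    modules <- list()
    for (mod in planted_modules) {
      stopifnot(mod$size <= length(free))
      mem <- sort(sample(free, mod$size))
      nbrs <- unique(c(em[em[, 1L] %in% mem, 2L], em[em[, 2L] %in% mem, 1L]))
      free <- setdiff(free, c(mem, nbrs))
      prs <- t(utils::combn(mem, 2L))
      keep <- stats::runif(nrow(prs)) <= mod$p_intra
      if (any(keep)) em <- rbind(em, prs[keep, , drop = FALSE])
      modules[[length(modules) + 1L]] <- mem
    }
    net <- make_network(em, nodes = nms, default_role = "interactor",
                        quiet = TRUE)
    list(network = net,
         truth = list(seed = seed, modules = modules, hubs = sort(hubs),
                      backbone_edges = backbone_edges,
                      params = list(n = n, m = m, hub_degree = hub_degree,
                                    n_hubs = n_hubs,
                                    planted_modules = planted_modules)))
  })
}

#' Generate an annotation collection with one spiked enriched term
#'
#' Terms are random subsets of the universe with sizes uniform over
#' \code{size_range}. One designated term is over-represented in the emitted
#' query: a fraction \code{spike_strength} of the query is drawn from that
#' term's genes, the rest from the remainder of the universe.
#'
#' @param universe Character vector of gene symbols.
#' @param n_terms Number of terms (default 50).
#' @param size_range Length-2 integer range of term sizes.
#' @param query_size Size of the emitted query set.
#' @param spike_strength Fraction of the query drawn from the spiked term
#'   (1 = maximal spike).
#' @param spiked_term Identifier of the spiked term.
#' @param seed Integer seed.
#' @return List with \code{annotations} (an
#'   \code{\link{annotation_collection}}), \code{query} (a
#'   \code{target_set}) and \code{truth} (the \code{spiked_term}, the
#'   planted overlap, seed, parameters).
#' @export
gen_annotations <- function(universe, n_terms = 50, size_range = c(10, 40),
                            query_size = 30, spike_strength = 0.8,
                            spiked_term = "TERM_SPIKED", seed = 1) {
  universe <- unique(normalize_symbols(universe))
  stopifnot(length(universe) >= max(size_range), n_terms >= 1,
            spike_strength >= 0, spike_strength <= 1)
  with_seed(seed, {
    ids <- c(spiked_term, sprintf("TERM%03d", seq_len(n_terms - 1L)))
    sizes <- sample(seq(size_range[1L], size_range[2L]), n_terms,
                    replace = TRUE)
    terms <- stats::setNames(
      lapply(sizes, function(s) sample(universe, s)), ids)
    n_hit <- round(spike_strength * query_size)
    n_hit <- min(n_hit, length(terms[[spiked_term]]))
    hits <- sample(terms[[spiked_term]], n_hit)
    miss_pool <- setdiff(universe, terms[[spiked_term]])
    miss <- sample(miss_pool, min(query_size - n_hit, length(miss_pool)))
    ann <- annotation_collection(
      terms,
      names = stats::setNames(paste("annotation term", ids), ids))
    list(annotations = ann,
         query = target_set(sample(c(hits, miss)), label = "query"),
         truth = list(seed = seed, spiked_term = spiked_term,
                      planted_overlap = sort(hits),
                      params = list(n_terms = n_terms,
                                    size_range = size_range,
                                    query_size = query_size,
                                    spike_strength = spike_strength)))
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Generates every input the pipeline reads, shaped like a realistic
#' four-herb formula study at desk scale, and writes them in the pipeline's
#' file formats along with a \code{truth.json} of all planted expectations:
#' a 600-component ADME table (pass fraction 0.22 plus 9 manual keeps, i.e.
#' 141 expected bioactives), a 186-target component-target map over a
#' 1000-node preferential-attachment interactome carrying two planted
#' 8-cliques and one dominant hub, a 546-gene disease list planting a
#' 52-gene overlap with the formula targets, and a 50-term GMT with one
#' spiked term.
#'
#' @param dir Output directory (created if needed).
#' @param seed Pipeline-wide seed; per-generator seeds are derived from it.
#' @return Invisibly, a list with all generated objects and the combined
#'   \code{truth}.
#' @export
write_synthetic_fixture <- function(dir, seed = 42) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- gen_components(n_per_herb = c(herbA = 230, herbB = 85,
                                        herbC = 280, herbD = 5),
                         pass_fraction = 0.22, n_manual_keep = 9,
                         seed = derive_seed(seed, 1))
  inter <- gen_interactome(n = 1000, m = 3,
                           planted_modules = list(
                             list(size = 8, p_intra = 1),
                             list(size = 8, p_intra = 1)),
                           hub_degree = 300, n_hubs = 1,
                           seed = derive_seed(seed, 2))
  genes <- igraph::V(inter$network)$name
  bioactive_ids <- sort(unique(c(comp$truth$expected_pass,
                                 comp$truth$manual_keep)))
  ct <- gen_component_target(bioactive_ids,
                             targets = with_seed(derive_seed(seed, 3),
                                                 sample(genes, 186)),
                             mean_degree = 18,
                             seed = derive_seed(seed, 4))
  formula_t <- sort(unique(ct$pairs$target))
  dis <- gen_disease_targets(genes, n = 546,
                             overlap_with = formula_t,
                             overlap_fraction = 52 / 546,
                             seed = derive_seed(seed, 5))
  ann <- gen_annotations(genes, n_terms = 50, size_range = c(10, 40),
                         query_size = 30, spike_strength = 0.8,
                         seed = derive_seed(seed, 6))
  write_component_table(comp$table, file.path(dir, "components.tsv"))
  utils::write.table(ct$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(inter$network, file.path(dir, "interactome.tsv"),
                format = "tsv")
  dis_dir <- file.path(dir, "disease")
  dir.create(dis_dir, showWarnings = FALSE)
  for (src in dis$sources) {
    write_gene_list(src$members, file.path(dis_dir, paste0(src$label, ".tsv")))
  }
  write_gmt(ann$annotations, file.path(dir, "annotations.gmt"))
  truth <- list(seed = seed,
                components = comp$truth,
                component_target = ct$truth[c("seed", "params")],
                pair_count = nrow(ct$pairs),
                n_formula_targets = length(unique(ct$pairs$target)),
                disease = dis$truth,
                interactome = inter$truth[c("seed", "hubs", "modules",
                                            "backbone_edges", "params")],
                annotations = ann$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(components = comp, component_target = ct, disease = dis,
                 interactome = inter, annotations = ann, truth = truth))
}
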