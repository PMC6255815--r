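#' Expand seed proteins over a background interactome
#'
#' Builds a seed-centred PPI subnetwork in the style of interactome
#' neighbourhood expansion: starting from the seed proteins present in the
#' interactome, all nodes within \code{max_hops} steps are collected, and
#' (by default) the full interactome subgraph induced on that node set is
#' returned -- including edges between two neighbours. With
#' \code{include_neighbor_edges = FALSE} only edges incident to a seed are
#' kept. Seeds absent from the interactome are retained as isolated nodes
#' (role \code{seed}) and their count is reported.
#'
#' With \code{max_hops = 0} the result is the subgraph induced on the seeds
#' themselves.
#'
#' @param interactome Simple undirected \code{igraph} network.
#' @param seeds A \code{target_set} or character vector of seed identifiers.
#' @param max_hops Expansion radius (default 1).
#' @param include_neighbor_edges Keep induced neighbour-neighbour edges
#'   (default \code{TRUE}).
#' @param quiet Suppress messages.
#' @return An \code{igraph} network; seed nodes carry role \code{seed},
#'   recruited neighbours role \code{interactor}.
#' @export
expand_seeds <- function(interactome, seeds, max_hops = 1,
                         include_neighbor_edges = TRUE, quiet = FALSE) {
  stopifnot(max_hops >= 0)
  seed_ids <- as_target_members(seeds)
  present <- intersect(seed_ids, igraph::V(interactome)$name)
  absent <- setdiff(seed_ids, present)
  if (!quiet && length(absent) > 0L) {
    message("expand_seeds: ", length(absent),
            " seed(s) absent from the interactome kept as isolated nodes")
  }
  if (igraph::vcount(interactome) == 0L || length(present) == 0L) {
    if (!quiet) warning("no seeds found in the interactome")
    return(make_network(NULL, nodes = seed_ids,
                        roles = stats::setNames(rep("seed", length(seed_ids)),
                                                seed_ids),
                        quiet = TRUE))
  }
  reach <- igraph::ego(interactome, order = max_hops, nodes = present)
  node_ids <- unique(unlist(lapply(reach, function(v) v$name)))
  sub <- igraph::induced_subgraph(interactome, node_ids)
  if (!include_neighbor_edges) {
    seed_v <- which(igraph::V(sub)$name %in% present)
    keep_e <- unique(unlist(igraph::incident_edges(sub, seed_v)))
    sub <- igraph::subgraph_from_edges(sub, keep_e, delete.vertices = FALSE)
  }
  em <- igraph::as_edgelist(sub, names = TRUE)
  all_nodes <- union(igraph::V(sub)$name, seed_ids)
  roles <- stats::setNames(rep("interactor", length(all_nodes)), all_nodes)
  roles[all_nodes %in% seed_ids] <- "seed"
  make_network(em, nodes = all_nodes, roles = roles, quiet = TRUE)
}

#' Intersection of two networks
#'
#' Nodes present in both and edges present in both; nodes isolated by the
#' edge intersection are removed by default. This is the default way the
#' pipeline combines the formula-side and disease-side PPI subnetworks into
#' a single interactive network, since a node or interaction supported by
#' only one side carries no joint evidence.
#'
#' @param a,b Simple undirected \code{igraph} networks.
#' @param drop_isolated Remove degree-0 nodes from the result (default TRUE).
#' @return An \code{igraph} network; roles carried over from \code{a}.
#' @export
intersect_networks <- function(a, b, drop_isolated = TRUE) {
  common_nodes <- intersect(igraph::V(a)$name, igraph::V(b)$name)
  ea <- edge_table(a)
  eb <- edge_table(b)
  key_a <- paste(ea[, 1L], ea[, 2L], sep = "\r")
  key_b <- paste(eb[, 1L], eb[, 2L], sep = "\r")
  em <- ea[key_a %in% key_b, , drop = FALSE]
  em <- em[em[, 1L] %in% common_nodes & em[, 2L] %in% common_nodes, ,
           drop = FALSE]
  nodes <- if (drop_isolated) unique(as.character(em)) else common_nodes
  roles_a <- stats::setNames(igraph::V(a)$role, igraph::V(a)$name)
  make_network(em, nodes = nodes, roles = roles_a, quiet = TRUE)
}

#' Union of two networks
#'
#' Node and edge union; offered as the alternative combination rule to
#' \code{\link{intersect_networks}}.
#'
#' @param a,b Simple undirected \code{igraph} networks.
#' @return An \code{igraph} network.
#' @export
union_networks <- function(a, b) {
  em <- rbind(edge_table(a), edge_table(b))
  nodes <- union(igraph::V(a)$name, igraph::V(b)$name)
  roles <- stats::setNames(igraph::V(b)$role, igraph::V(b)$name)
  roles_a <- stats::setNames(igraph::V(a)$role, igraph::V(a)$name)
  roles[names(roles_a)] <- roles_a
  make_network(em, nodes = nodes, roles = roles, quiet = TRUE)
}
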