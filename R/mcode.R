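#' MCODE parameter set
#'
#' Tunables of the molecular-complex-detection clusterer, defaulting to the
#' algorithm's published defaults: vertices below \code{degree_cutoff} are
#' not weighted; expansion admits neighbours whose weight is within
#' \code{node_score_cutoff} (the vertex weight percentage, VWP) of the seed
#' weight; complexes lacking a \code{k_core}-core are discarded;
#' \code{haircut} 2-cores the complex; \code{fluff} optionally adds boundary
#' neighbours whose own neighbourhood density exceeds \code{fluff_density}.
#'
#' @param degree_cutoff Minimum degree for a vertex to receive a weight
#'   (default 2).
#' @param node_score_cutoff VWP, in [0, 1] (default 0.2).
#' @param k_core Minimum core a complex must contain (default 2).
#' @param max_depth Breadth limit of the expansion from the seed
#'   (default 100).
#' @param haircut Remove singly-connected vertices, i.e. 2-core the complex
#'   (default TRUE).
#' @param fluff Add dense boundary neighbours (default FALSE); fluffed
#'   vertices may be shared between complexes.
#' @param fluff_density Neighbourhood-density threshold for fluff
#'   (default 0.5).
#' @return A list of class \code{mcode_params}.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, max_depth = 100, haircut = TRUE,
                         fluff = FALSE, fluff_density = 0.5) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff <= 1, k_core >= 2,
            degree_cutoff >= 0, max_depth >= 0)
  structure(list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff,
                 k_core = k_core, max_depth = max_depth,
                 haircut = haircut, fluff = fluff,
                 fluff_density = fluff_density),
            class = "mcode_params")
}

graph_density_simple <- function(n, m) {
  if (n < 2L) return(0)
  2 * m / (n * (n - 1))
}

# density of the highest k-core of the closed neighbourhood of vertex v
core_clustering_weight <- function(net, v, degree_cutoff) {
  nb <- igraph::neighbors(net, v)
  if (length(nb) < degree_cutoff) return(0)
  gv <- igraph::induced_subgraph(net, c(v, nb))
  cores <- igraph::coreness(gv)
  k <- max(cores)
  if (k == 0L) return(0)
  core_sub <- igraph::induced_subgraph(gv, which(cores >= k))
  k * graph_density_simple(igraph::vcount(core_sub), igraph::ecount(core_sub))
}

#' MCODE vertex weights
#'
#' Weight(v) = k x density of the highest k-core of the subgraph induced on
#' v and its neighbours (the core-clustering coefficient). Vertices with
#' degree below \code{params$degree_cutoff} get weight 0.
#'
#' @param net Simple undirected \code{igraph} network.
#' @param params An \code{\link{mcode_params}} object.
#' @return Named numeric vector over all nodes.
#' @export
mcode_vertex_weights <- function(net, params = mcode_params()) {
  n <- igraph::vcount(net)
  w <- stats::setNames(numeric(n), igraph::V(net)$name)
  for (v in seq_len(n)) {
    w[v] <- core_clustering_weight(net, v, params$degree_cutoff)
  }
  w
}

# largest-k-core style post-filter helpers -------------------------------

two_core_members <- function(sub) {
  igraph::V(sub)$name[igraph::coreness(sub) >= 2]
}

#' MCODE dense-module detection
#'
#' Greedy complex growth: seeds are taken in decreasing vertex-weight order
#' (ties broken lexicographically by node name); from each unvisited seed, a
#' breadth-limited traversal admits unvisited neighbours whose weight is at
#' least \code{seed weight x (1 - VWP)}. Complexes that do not contain a
#' \code{k_core}-core are discarded; the haircut option 2-cores each
#' complex; fluff optionally adds boundary neighbours with dense
#' neighbourhoods (such vertices may appear in several complexes). Each
#' complex is scored by \code{density x size} on its induced subgraph and
#' complexes are returned score-descending.
#'
#' @param net Simple undirected \code{igraph} network.
#' @param params An \code{\link{mcode_params}} object.
#' @param weights Optional precomputed \code{\link{mcode_vertex_weights}}.
#' @return List of clusters, each a list with \code{members} (sorted names),
#'   \code{seed}, \code{score}, \code{size}, \code{density}.
#' @export
mcode <- function(net, params = mcode_params(), weights = NULL) {
  if (is.null(weights)) weights <- mcode_vertex_weights(net, params)
  stopifnot(length(weights) == igraph::vcount(net))
  nms <- igraph::V(net)$name
  ord <- order(-weights, nms)
  visited <- stats::setNames(rep(FALSE, length(nms)), nms)
  clusters <- list()
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  adj <- lapply(adj, function(v) sort(v$name))
  names(adj) <- nms
  for (i in ord) {
    seed <- nms[i]
    if (visited[seed]) next
    thr <- weights[seed] * (1 - params$node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- character(0)
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (!visited[w] && weights[w] >= thr) {
            visited[w] <- TRUE
            members <- c(members, w)
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(net, members)
    core_ok <- any(igraph::coreness(sub) >= params$k_core)
    if (!core_ok) next
    if (params$fluff) {
      boundary <- setdiff(unique(unlist(adj[members], use.names = FALSE)),
                          members)
      dens <- vapply(boundary, function(b) {
        nb <- c(b, adj[[b]])
        g <- igraph::induced_subgraph(net, nb)
        graph_density_simple(igraph::vcount(g), igraph::ecount(g))
      }, numeric(1))
      members <- c(members, boundary[dens > params$fluff_density])
      sub <- igraph::induced_subgraph(net, members)
    }
    if (params$haircut) {
      kept <- two_core_members(sub)
      if (length(kept) == 0L) next
      members <- kept
      sub <- igraph::induced_subgraph(net, members)
    }
    dens <- graph_density_simple(igraph::vcount(sub), igraph::ecount(sub))
    clusters[[length(clusters) + 1L]] <- list(
      members = sort(members),
      seed = seed,
      score = dens * length(members),
      size = length(members),
      density = dens
    )
  }
  scores <- vapply(clusters, `[[`, numeric(1), "score")
  seeds <- vapply(clusters, `[[`, character(1), "seed")
  clusters[order(-scores, seeds)]
}

#' Write MCODE clusters to TSV
#'
#' Columns: cluster_id, score, size, seed, comma-joined members.
#'
#' @param clusters Result of \code{\link{mcode}}.
#' @param path Output path.
#' @return Invisibly \code{path}.
#' @export
write_clusters <- function(clusters, path) {
  df <- data.frame(
    cluster_id = seq_along(clusters),
    score = vapply(clusters, `[[`, numeric(1), "score"),
    size = vapply(clusters, `[[`, integer(1), "size"),
    seed = vapply(clusters, `[[`, character(1), "seed"),
    members = vapply(clusters, function(cl)
      paste(cl$members, collapse = ","), character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
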