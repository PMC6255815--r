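#' Node centrality statistics for core-target screening
#'
#' The topological screen ranks proteins by six standard node-importance
#' statistics on an unweighted, undirected simple graph:
#' \describe{
#'   \item{DC}{degree centrality -- number of neighbours.}
#'   \item{BC}{betweenness centrality -- summed fraction of shortest paths
#'     passing through the node, over unordered pairs, unnormalized.}
#'   \item{CC}{closeness centrality -- number of reachable nodes divided by
#'     the sum of shortest-path distances to them; 0 for isolated nodes.}
#'   \item{EC}{eigenvector centrality -- principal eigenvector of the
#'     adjacency matrix, L2-normalized; computed on the largest connected
#'     component with zeros elsewhere (the power iteration is ill-defined
#'     across components), or per component on request.}
#'   \item{LAC}{local average connectivity -- mean degree of a node's
#'     neighbours within the subgraph induced on those neighbours.}
#'   \item{NC}{network centrality -- sum over incident edges of the edge
#'     clustering coefficient ECC(u,v) = z / min(deg(u)-1, deg(v)-1), with
#'     z the number of common neighbours; a zero denominator gives ECC 0.}
#' }
#' Subgraph centrality (SC, the diagonal of the adjacency-matrix
#' exponential) is available as an optional extra.
#'
#' @name centrality
NULL

#' @describeIn centrality Degree centrality.
#' @param net Simple undirected \code{igraph} network.
#' @return Named numeric vector over all nodes.
#' @export
degree_centrality <- function(net) {
  igraph::degree(net)
}

#' @describeIn centrality Betweenness centrality (unweighted, unnormalized).
#' @export
betweenness_centrality <- function(net) {
  igraph::betweenness(net, directed = FALSE, weights = NA, normalized = FALSE)
}

#' @describeIn centrality Closeness centrality, normalized to the reachable
#'   set: cc(v) = r(v) / sum of d(v, u) over the r(v) nodes reachable from v.
#' @export
closeness_centrality <- function(net) {
  cc <- suppressWarnings(
    igraph::closeness(net, weights = NA, normalized = TRUE)
  )
  cc[!is.finite(cc)] <- 0
  cc
}

#' @describeIn centrality Eigenvector centrality, L2-normalized and
#'   nonnegative, computed by a deterministic shifted power iteration
#'   (iterating A + I preserves the principal eigenvector while ruling out
#'   the oscillation a plain iteration exhibits on bipartite components).
#' @param scope \code{"largest"} scores the largest connected component and
#'   assigns 0 elsewhere; \code{"components"} scores each component
#'   separately (each component's subvector has unit L2 norm).
#' @param tol Convergence tolerance on the max-norm change per iteration.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @export
eigenvector_centrality <- function(net, scope = c("largest", "components"),
                                   tol = 1e-10, max_iter = 1000) {
  scope <- match.arg(scope)
  n <- igraph::vcount(net)
  ec <- stats::setNames(numeric(n), igraph::V(net)$name)
  if (n == 0L) return(ec)
  comp <- igraph::components(net)
  comp_ids <- if (scope == "largest") which.max(comp$csize) else
    seq_len(comp$no)
  for (ci in comp_ids) {
    vs <- which(comp$membership == ci)
    if (length(vs) == 1L) {
      # an isolated node has eigenvector score 0 under the largest-component
      # convention; under per-component scoring its trivial component gets 1
      ec[vs] <- if (scope == "components") 1 else 0
      next
    }
    sub <- igraph::induced_subgraph(net, vs)
    A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
    m <- length(vs)
    x <- rep(1 / sqrt(m), m)
    converged <- FALSE
    residual <- NA_real_
    for (it in seq_len(max_iter)) {
      y <- as.numeric(A %*% x) + x
      nrm <- sqrt(sum(y^2))
      if (nrm == 0) break  # edgeless component; keep zeros
      y <- y / nrm
      residual <- max(abs(y - x))
      x <- y
      if (residual < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged && is.finite(residual) && residual >= tol) {
      stop(sprintf(
        "eigenvector centrality did not converge in %d iterations (residual %.3e)",
        max_iter, residual))
    }
    ec[igraph::V(sub)$name] <- abs(x)
  }
  ec
}

#' @describeIn centrality Local average connectivity. Each edge among the
#'   neighbours of v is a triangle through v, so LAC(v) reduces to
#'   2 T(v) / deg(v) with T(v) the triangle count at v.
#' @export
local_average_connectivity <- function(net) {
  deg <- igraph::degree(net)
  tri <- igraph::count_triangles(net)
  lac <- ifelse(deg > 0, 2 * tri / deg, 0)
  stats::setNames(as.numeric(lac), igraph::V(net)$name)
}

#' @describeIn centrality Network centrality (summed edge clustering
#'   coefficients over incident edges).
#' @param ecc_variant \code{"plain"} uses ECC = z/min(deg-1, deg-1);
#'   \code{"plus_one"} uses the (z+1)/min variant sometimes used to avoid
#'   zero scores on triangle-free edges. Zero denominators give ECC 0 in
#'   both variants.
#' @export
network_centrality <- function(net, ecc_variant = c("plain", "plus_one")) {
  ecc_variant <- match.arg(ecc_variant)
  n <- igraph::vcount(net)
  nc <- stats::setNames(numeric(n), igraph::V(net)$name)
  if (igraph::ecount(net) == 0L) return(nc)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  el <- igraph::as_edgelist(net, names = FALSE)
  deg <- igraph::degree(net)
  # z(u,v) = number of common neighbours = (A^2)[u,v] on a simple graph
  A2 <- A %*% A
  z <- A2[el]
  if (ecc_variant == "plus_one") z <- z + 1
  denom <- pmin(deg[el[, 1L]], deg[el[, 2L]]) - 1
  ecc <- ifelse(denom > 0, z / denom, 0)
  s <- rowsum(c(ecc, ecc), group = c(el[, 1L], el[, 2L]))
  nc[as.integer(rownames(s))] <- s[, 1L]
  nc
}

#' @describeIn centrality Subgraph centrality (optional extra): the diagonal
#'   of expm(A), computed by dense eigendecomposition.
#' @export
subgraph_centrality <- function(net) {
  n <- igraph::vcount(net)
  sc <- stats::setNames(numeric(n), igraph::V(net)$name)
  if (n == 0L) return(sc)
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = TRUE))
  e <- eigen(A, symmetric = TRUE)
  sc[] <- as.numeric((e$vectors^2) %*% exp(e$values))
  sc
}

#' Compute a table of centrality statistics
#'
#' One row per node with every requested measure; deterministic, rows in
#' node-name order of the network.
#'
#' @param net Simple undirected \code{igraph} network.
#' @param measures Character vector drawn from
#'   \code{c("dc","bc","cc","ec","lac","nc","sc")}; the six screening
#'   statistics by default.
#' @param ec_scope Passed to \code{\link{eigenvector_centrality}}.
#' @param ecc_variant Passed to \code{\link{network_centrality}}.
#' @return Data frame with columns \code{node}, \code{role}, and one column
#'   per measure.
#' @examples
#' compute_centralities(make_network(rbind(c("A","B"), c("B","C"), c("A","C"))))
#' @export
compute_centralities <- function(net,
                                 measures = c("dc", "bc", "cc", "ec", "lac", "nc"),
                                 ec_scope = "largest",
                                 ecc_variant = "plain") {
  known <- c("dc", "bc", "cc", "ec", "lac", "nc", "sc")
  bad <- setdiff(measures, known)
  if (length(bad) > 0L) {
    stop("unknown centrality measure(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(node = igraph::V(net)$name,
                    role = if (is.null(igraph::V(net)$role)) "generic"
                           else igraph::V(net)$role,
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    for (m in measures) out[[m]] <- numeric(0)
    return(out)
  }
  fns <- list(
    dc = function() as.numeric(degree_centrality(net)),
    bc = function() as.numeric(betweenness_centrality(net)),
    cc = function() as.numeric(closeness_centrality(net)),
    ec = function() as.numeric(eigenvector_centrality(net, scope = ec_scope)),
    lac = function() as.numeric(local_average_connectivity(net)),
    nc = function() as.numeric(network_centrality(net, ecc_variant = ecc_variant)),
    sc = function() as.numeric(subgraph_centrality(net))
  )
  for (m in measures) out[[m]] <- fns[[m]]()
  out
}

#' Write / read a centrality table
#'
#' Plain TSV round-trip of \code{\link{compute_centralities}} output.
#'
#' @param table Data frame from \code{\link{compute_centralities}}.
#' @param path File path.
#' @return \code{write_centrality_table} returns \code{path} invisibly;
#'   \code{read_centrality_table} returns the data frame.
#' @export
write_centrality_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centrality_table
#' @export
read_centrality_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
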