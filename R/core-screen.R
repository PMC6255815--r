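#' Stage-1 topological filter: degree versus median degree
#'
#' The primary screen keeps nodes whose degree is at least
#' \code{multiplier} times the (interpolated) median degree of the whole
#' network and returns the subgraph induced on them. With the default
#' multiplier of 2 this is the usual "DC >= 2 x median DC" hub criterion;
#' note that on any k-regular graph it necessarily returns an empty network.
#'
#' @param net Simple undirected \code{igraph} network.
#' @param table Optional precomputed centrality table (needs a \code{dc}
#'   column covering every node); degrees are computed from \code{net} when
#'   absent.
#' @param multiplier Threshold multiplier on the median degree (default 2).
#' @param quiet Suppress the threshold message.
#' @return Induced \code{igraph} subgraph (possibly empty).
#' @export
stage1_filter <- function(net, table = NULL, multiplier = 2, quiet = FALSE) {
  if (igraph::vcount(net) == 0L) {
    warning("stage1_filter: empty input network")
    return(net)
  }
  if (is.null(table)) {
    dc <- degree_centrality(net)
  } else {
    stopifnot(all(igraph::V(net)$name %in% table$node))
    dc <- stats::setNames(table$dc[match(igraph::V(net)$name, table$node)],
                          igraph::V(net)$name)
  }
  cutoff <- multiplier * stats::median(dc)
  if (!quiet) {
    message(sprintf("stage1_filter: median dc = %g, cutoff = %g",
                    stats::median(dc), cutoff))
  }
  igraph::induced_subgraph(net, which(dc >= cutoff))
}

#' Stage-2 cutoffs for the six centrality statistics
#'
#' Recomputes all six measures on the stage-1 subnetwork and, under the
#' \code{"median"} rule, sets each cutoff to that measure's interpolated
#' median over the subnetwork's nodes. Under the \code{"explicit"} rule the
#' user supplies all six cutoffs (e.g. values published for a particular
#' interactome snapshot).
#'
#' @param sub Stage-1 subnetwork.
#' @param rule \code{"median"} or \code{"explicit"}.
#' @param cutoffs Named numeric vector/list with entries
#'   \code{bc, cc, dc, ec, lac, nc}; required when \code{rule = "explicit"}.
#' @param table Optional precomputed centrality table for \code{sub}.
#' @return Named list of six cutoffs.
#' @export
stage2_thresholds <- function(sub, rule = c("median", "explicit"),
                              cutoffs = NULL, table = NULL) {
  rule <- match.arg(rule)
  six <- c("bc", "cc", "dc", "ec", "lac", "nc")
  if (rule == "explicit") {
    cutoffs <- as.list(cutoffs)
    missing_ms <- setdiff(six, names(cutoffs))
    if (length(missing_ms) > 0L) {
      stop("explicit cutoffs missing measure(s): ",
           paste(missing_ms, collapse = ", "))
    }
    return(lapply(cutoffs[six], as.numeric))
  }
  if (igraph::vcount(sub) == 0L) stop("stage-1 subnetwork is empty")
  if (is.null(table)) table <- compute_centralities(sub, measures = six)
  stats::setNames(lapply(six, function(m) stats::median(table[[m]])), six)
}

#' Stage-2 filter: six simultaneous strict centrality cutoffs
#'
#' A node enters the core only if it strictly exceeds every one of the six
#' cutoffs (BC, CC, DC, EC, LAC, NC) evaluated on the stage-1 subnetwork.
#' Strictness means that under the median rule a vertex-transitive
#' subnetwork yields an empty core: no node strictly exceeds its own
#' constant value.
#'
#' @param sub Stage-1 subnetwork.
#' @param cutoffs Named list/vector of six cutoffs (see
#'   \code{\link{stage2_thresholds}}).
#' @param table Optional precomputed centrality table for \code{sub}.
#' @return A \code{screen_result} list: \code{stage1_network},
#'   \code{stage2_thresholds}, \code{core_nodes}, \code{core_network},
#'   \code{centrality}.
#' @export
stage2_filter <- function(sub, cutoffs, table = NULL) {
  six <- c("bc", "cc", "dc", "ec", "lac", "nc")
  cutoffs <- lapply(as.list(cutoffs)[six], as.numeric)
  if (any(vapply(cutoffs, length, 1L) != 1L)) {
    stop("each cutoff must be a single number")
  }
  if (is.null(table)) table <- compute_centralities(sub, measures = six)
  pass <- rep(TRUE, nrow(table))
  for (m in six) pass <- pass & (table[[m]] > cutoffs[[m]])
  core_nodes <- sort(table$node[pass])
  structure(list(
    stage1_network = sub,
    stage2_thresholds = cutoffs,
    core_nodes = core_nodes,
    core_network = igraph::induced_subgraph(
      sub, which(igraph::V(sub)$name %in% core_nodes)),
    centrality = table
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat("  stage-1 network:", igraph::vcount(x$stage1_network), "nodes,",
      igraph::ecount(x$stage1_network), "edges\n")
  cat("  stage-2 cutoffs:",
      paste(names(x$stage2_thresholds),
            signif(unlist(x$stage2_thresholds), 6), sep = ">", collapse = ", "),
      "\n")
  cat("  core:", length(x$core_nodes), "nodes,",
      igraph::ecount(x$core_network), "edges\n")
  invisible(x)
}

#' Two-stage topological core-target screen
#'
#' Convenience wrapper chaining \code{\link{stage1_filter}},
#' \code{\link{stage2_thresholds}} and \code{\link{stage2_filter}}: nodes
#' with DC >= \code{multiplier} x median DC enter stage 1; the six
#' centrality statistics are recomputed on that reduced network; the core is
#' the set of nodes strictly exceeding all six stage-2 cutoffs at once.
#'
#' @param net Input network (typically the intersected PPI network).
#' @param multiplier Stage-1 degree multiplier (default 2).
#' @param rule Stage-2 cutoff rule (\code{"median"} or \code{"explicit"}).
#' @param cutoffs Explicit stage-2 cutoffs when \code{rule = "explicit"}.
#' @param quiet Suppress progress messages.
#' @return A \code{screen_result}; with an additional field
#'   \code{stage1_threshold}.
#' @export
core_screen <- function(net, multiplier = 2, rule = "median", cutoffs = NULL,
                        quiet = FALSE) {
  dc <- degree_centrality(net)
  sub <- stage1_filter(net, multiplier = multiplier, quiet = quiet)
  if (igraph::vcount(sub) == 0L) {
    res <- structure(list(stage1_network = sub,
                          stage2_thresholds = NULL,
                          core_nodes = character(0),
                          core_network = sub,
                          centrality = compute_centralities(sub)),
                     class = "screen_result")
    res$stage1_threshold <- multiplier * stats::median(dc)
    return(res)
  }
  table <- compute_centralities(sub)
  cuts <- stage2_thresholds(sub, rule = rule, cutoffs = cutoffs, table = table)
  res <- stage2_filter(sub, cuts, table = table)
  res$stage1_threshold <- multiplier * stats::median(dc)
  res
}
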