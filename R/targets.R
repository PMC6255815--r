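#' Construct a target set
#'
#' A labelled, deduplicated, normalized set of gene symbols -- the currency
#' of all set algebra in the pipeline (per-database disease lists, the
#' formula-side target union, the common-target intersection).
#'
#' @param members Character vector of gene symbols (normalized on entry).
#' @param label Short label, e.g. a source database name or \code{"common"}.
#' @return An object of class \code{target_set} with fields \code{label} and
#'   \code{members}.
#' @export
target_set <- function(members, label = "targets") {
  m <- unique(normalize_symbols(members))
  m <- m[nzchar(m)]
  structure(list(label = label, members = m), class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set>", x$label, "-", length(x$members), "symbols\n")
  invisible(x)
}

#' @export
length.target_set <- function(x) length(x$members)

as_target_members <- function(x) {
  if (inherits(x, "target_set")) x$members else unique(normalize_symbols(x))
}

#' Union of target sets
#'
#' Deduplicating union across any number of per-source target sets; this is
#' how a disease target list is assembled from several databases.
#'
#' @param lists A list of \code{target_set} objects (or character vectors).
#' @param label Label for the result.
#' @return A \code{target_set}.
#' @export
union_targets <- function(lists, label = "union") {
  stopifnot(length(lists) >= 1L)
  target_set(unlist(lapply(lists, as_target_members), use.names = FALSE),
             label = label)
}

#' Intersection of two target sets
#'
#' The common targets shared by a formula's predicted targets and a disease
#' target list. Membership order follows \code{a}.
#'
#' @param a,b \code{target_set} objects (or character vectors).
#' @param label Label for the result (default \code{"common"}).
#' @return A \code{target_set}.
#' @export
intersect_targets <- function(a, b, label = "common") {
  ma <- as_target_members(a)
  mb <- as_target_members(b)
  target_set(ma[ma %in% mb], label = label)
}

#' Read a component-target pair table
#'
#' Tab-separated with two columns, \code{component_id} and \code{target}
#' (header optional). Targets are normalized; exact duplicate pairs are
#' collapsed.
#'
#' @param path File path.
#' @return Data frame with columns \code{component_id}, \code{target}.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- strip_comment_blank(lines)
  if (length(idx) == 0L) {
    return(data.frame(component_id = character(0), target = character(0)))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed pair row at line %d of %s", idx[bad[1L]], path))
  }
  df <- data.frame(component_id = trimws(vapply(parts, `[`, "", 1L)),
                   target = vapply(parts, `[`, "", 2L))
  if (tolower(df$component_id[1L]) %in% c("component_id", "component", "mol")) {
    df <- df[-1L, , drop = FALSE]
  }
  normalize_pair_table(df)
}

normalize_pair_table <- function(pairs) {
  df <- data.frame(component_id = trimws(as.character(pairs[[1L]])),
                   target = normalize_symbols(pairs[[2L]]))
  if (any(!nzchar(df$component_id)) || any(!nzchar(df$target))) {
    stop("component-target pairs must not contain empty fields")
  }
  df[!duplicated(paste(df$component_id, df$target, sep = "\r")), , drop = FALSE]
}

#' Build the component-target bipartite network
#'
#' Nodes are the distinct components (role \code{component}) and distinct
#' targets (role \code{target}); each distinct normalized pair contributes
#' one edge. The graph is bipartite by construction.
#'
#' @param pairs Data frame with columns \code{component_id} and \code{target}
#'   (any two-column frame is accepted).
#' @return An \code{igraph} network.
#' @export
build_bipartite <- function(pairs) {
  df <- normalize_pair_table(pairs)
  comps <- unique(df$component_id)
  targs <- unique(df$target)
  roles <- c(stats::setNames(rep("component", length(comps)), comps),
             stats::setNames(rep("target", length(targs)), targs))
  make_network(cbind(df$component_id, df$target), roles = roles, quiet = TRUE)
}

#' Targets of the component-target network
#'
#' Convenience accessor: the formula-side target set of a bipartite network
#' (or pair table).
#'
#' @param x Bipartite \code{igraph} network or pair data frame.
#' @param label Label for the result.
#' @return A \code{target_set}.
#' @export
formula_targets <- function(x, label = "formula") {
  if (igraph::is_igraph(x)) {
    target_set(igraph::V(x)$name[igraph::V(x)$role == "target"], label = label)
  } else {
    target_set(normalize_pair_table(x)$target, label = label)
  }
}

#' Candidate components by bipartite degree
#'
#' Ranks component-role nodes by degree (number of predicted targets) and
#' retains those at or above a threshold. With \code{min_degree = "median"}
#' the threshold is the interpolated median of the component-node degrees
#' (target nodes excluded), the usual hub criterion for picking the
#' formula's crucial components.
#'
#' @param net Bipartite network from \code{\link{build_bipartite}}.
#' @param min_degree A count, or \code{"median"}.
#' @return Data frame (\code{component_id}, \code{degree}), degree-descending;
#'   ties broken by identifier.
#' @export
candidate_components <- function(net, min_degree = "median") {
  comp_idx <- which(igraph::V(net)$role == "component")
  if (length(comp_idx) == 0L) {
    warning("network has no component-role nodes")
    return(data.frame(component_id = character(0), degree = integer(0)))
  }
  deg <- igraph::degree(net, v = comp_idx)
  thr <- if (identical(min_degree, "median")) {
    stats::median(deg)
  } else {
    stopifnot(is.numeric(min_degree), length(min_degree) == 1L)
    min_degree
  }
  keep <- deg >= thr
  out <- data.frame(component_id = igraph::V(net)$name[comp_idx][keep],
                    degree = as.integer(deg[keep]))
  out[order(-out$degree, out$component_id), , drop = FALSE]
}
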