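#' Normalize gene symbols
#'
#' Gene identifiers arriving from heterogeneous sources (disease databases,
#' component-target prediction tables, annotation collections) are matched by
#' string identity, so they are brought to a single convention first:
#' surrounding whitespace is stripped and the symbol is uppercased.
#' Normalization is idempotent.
#'
#' @param x Character vector of raw gene identifiers.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_symbols(c("  il4", "IL4", "Tnf "))
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct a typed undirected network
#'
#' The pipeline's universal currency is a simple undirected graph whose nodes
#' carry a role tag (\code{"component"}, \code{"target"}, \code{"interactor"},
#' \code{"seed"} or \code{"generic"}). Self-loops and duplicate edges are
#' dropped (with a message giving the counts), so downstream centrality and
#' clustering code can assume a simple graph.
#'
#' @param edges Two-column matrix or data frame of endpoint identifiers, or
#'   \code{NULL} for an edgeless network.
#' @param nodes Optional character vector of node identifiers; endpoints of
#'   \code{edges} are always included.
#' @param roles Optional named character vector mapping node identifier to
#'   role; unnamed nodes get \code{default_role}.
#' @param default_role Role assigned to nodes not named in \code{roles}.
#' @param quiet Suppress the dropped-record message.
#' @return An \code{igraph} object with vertex attribute \code{role}.
#' @examples
#' net <- make_network(rbind(c("A", "B"), c("B", "A"), c("A", "A")))
#' igraph::vcount(net)  # 2
#' igraph::ecount(net)  # 1
#' @export
make_network <- function(edges = NULL, nodes = NULL, roles = NULL,
                         default_role = "generic", quiet = FALSE) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    mode(em) <- "character"
  }
  if (any(!nzchar(em)) || anyNA(em)) {
    stop("network edges contain empty or missing node identifiers")
  }
  n_self <- sum(em[, 1L] == em[, 2L])
  em <- em[em[, 1L] != em[, 2L], , drop = FALSE]
  # canonical ordering: lexicographic within each pair, then dedup
  canon <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
  dup <- duplicated(paste(canon[, 1L], canon[, 2L], sep = "\r"))
  n_dup <- sum(dup)
  canon <- canon[!dup, , drop = FALSE]
  all_nodes <- unique(c(as.character(canon), as.character(nodes)))
  if (any(!nzchar(all_nodes)) || anyNA(all_nodes)) {
    stop("node identifiers must be non-empty")
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (nrow(canon) > 0L) {
    g <- igraph::add_edges(g, t(matrix(match(canon, all_nodes), ncol = 2L)))
  }
  role <- rep(default_role, length(all_nodes))
  if (!is.null(roles)) {
    hit <- match(all_nodes, names(roles))
    role[!is.na(hit)] <- unname(roles[hit[!is.na(hit)]])
  }
  igraph::V(g)$role <- role
  if (!quiet && (n_self > 0L || n_dup > 0L)) {
    message(sprintf("make_network: dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_self, n_dup))
  }
  g
}

#' Validate the simple-network invariants
#'
#' Checks that a graph is undirected, has no self-loops or multi-edges, has
#' non-empty unique node names, and carries a \code{role} vertex attribute.
#'
#' @param net An \code{igraph} object.
#' @return Invisibly \code{TRUE}; errors otherwise.
#' @export
validate_network <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::is_directed(net)) stop("network must be undirected")
  if (igraph::any_loop(net)) stop("network must not contain self-loops")
  if (igraph::any_multiple(net)) stop("network must not contain duplicate edges")
  nm <- igraph::V(net)$name
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
    stop("all nodes must have non-empty names")
  }
  if (anyDuplicated(nm)) stop("node names must be unique")
  if (is.null(igraph::V(net)$role)) stop("nodes must carry a 'role' attribute")
  invisible(TRUE)
}

#' Canonical edge table of a network
#'
#' Returns the edge list with each pair sorted lexicographically and rows
#' ordered, so that equal networks serialize identically.
#'
#' @param net An \code{igraph} object.
#' @return Two-column character matrix (columns \code{from}, \code{to}).
#' @export
edge_table <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) {
    return(matrix(character(0), ncol = 2L, dimnames = list(NULL, c("from", "to"))))
  }
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  dimnames(el) <- list(NULL, c("from", "to"))
  el
}

#' Test two networks for equality
#'
#' Set equality on node names and canonical edges; roles are not compared.
#'
#' @param a,b \code{igraph} objects.
#' @return Logical scalar.
#' @export
networks_equal <- function(a, b) {
  setequal(igraph::V(a)$name, igraph::V(b)$name) &&
    identical(edge_table(a), edge_table(b))
}

strip_comment_blank <- function(lines) {
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  which(keep)
}

#' Read an undirected network from an edge-list file
#'
#' Supports two formats: a tab-separated edge list (first two columns are the
#' endpoints; \code{#}-prefixed comment lines ignored; an optional header row
#' is detected when its first field is one of a few conventional names) and
#' SIF (\code{nodeA relation nodeB [nodeC ...]}, which fans out to one edge
#' per trailing node). Self-loops and duplicate edges are dropped with a
#' message.
#'
#' @param path File path.
#' @param format \code{"auto"} (by extension), \code{"tsv"} or \code{"sif"}.
#' @param default_role Role tag assigned to all nodes.
#' @param quiet Suppress drop-count messages.
#' @return An \code{igraph} network.
#' @export
read_edge_list <- function(path, format = c("auto", "tsv", "sif"),
                           default_role = "interactor", quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  lines <- readLines(path, warn = FALSE)
  idx <- strip_comment_blank(lines)
  if (length(idx) == 0L) {
    return(make_network(NULL, default_role = default_role, quiet = quiet))
  }
  if (format == "tsv") {
    parts <- strsplit(lines[idx], "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed edge row at line %d of %s: need at least 2 fields",
                   idx[bad[1L]], path))
    }
    em <- t(vapply(parts, function(p) trimws(p[1:2]), character(2L)))
    # header detection: conventional column names in the first row
    if (tolower(em[1L, 1L]) %in% c("nodea", "from", "source", "node1")) {
      em <- em[-1L, , drop = FALSE]
    }
  } else {
    em <- matrix(character(0), ncol = 2L)
    iso <- character(0)
    for (i in idx) {
      p <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
      if (length(p) == 1L) {  # single-field row: isolated node
        iso <- c(iso, p)
        next
      }
      if (length(p) < 3L) {
        stop(sprintf("malformed SIF row at line %d of %s: need node relation node",
                     i, path))
      }
      em <- rbind(em, cbind(p[1L], p[-(1:2)]))
    }
    return(make_network(em, nodes = iso, default_role = default_role,
                        quiet = quiet))
  }
  make_network(em, default_role = default_role, quiet = quiet)
}

#' Write a network to TSV, SIF or GraphML
#'
#' TSV and SIF output uses the canonical (lexicographically sorted) edge
#' order and can be read back with \code{\link{read_edge_list}}; isolated
#' nodes are emitted as single-field SIF rows and are listed in a trailing
#' comment block in TSV. GraphML (via igraph) preserves the \code{role}
#' vertex attribute and isolated nodes natively.
#'
#' @param net An \code{igraph} network.
#' @param path Output file path.
#' @param format \code{"tsv"}, \code{"sif"} or \code{"graphml"}.
#' @return Invisibly \code{path}.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  validate_network(net)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  el <- edge_table(net)
  iso <- setdiff(igraph::V(net)$name, unique(as.character(el)))
  iso <- sort(iso)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines("nodeA\tnodeB", con)
    if (nrow(el) > 0L) writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
    if (length(iso) > 0L) writeLines(paste0("# isolated\t", iso), con)
  } else {
    if (nrow(el) > 0L) writeLines(paste(el[, 1L], "pp", el[, 2L], sep = "\t"), con)
    if (length(iso) > 0L) writeLines(iso, con)
  }
  invisible(path)
}

#' Read a gene list
#'
#' One identifier per line, or the first column of a TSV. Symbols are
#' normalized (uppercase, trimmed); order is preserved and duplicates are
#' retained -- deduplication is the job of the set operations downstream. A
#' single header line named \code{gene}, \code{symbol}, \code{target} or
#' \code{id} (case-insensitive) is skipped.
#'
#' @param path File path. An empty file yields an empty vector.
#' @return Character vector of normalized gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- strip_comment_blank(lines)
  if (length(idx) == 0L) return(character(0))
  first <- vapply(strsplit(lines[idx], "\t", fixed = TRUE), `[`, "", 1L)
  if (tolower(trimws(first[1L])) %in% c("gene", "symbol", "target", "id")) {
    first <- first[-1L]
  }
  normalize_symbols(first)
}

#' Write a gene list (one symbol per line)
#'
#' @param genes Character vector.
#' @param path Output path.
#' @return Invisibly \code{path}.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Apply a two-column identifier mapping to a symbol vector
#'
#' A plain join against a user-supplied mapping table (e.g. protein accession
#' to gene symbol). Unmapped symbols are kept unchanged.
#'
#' @param genes Character vector of symbols.
#' @param mapping Data frame whose first column is the source identifier and
#'   second the replacement.
#' @return Character vector, normalized.
#' @export
apply_mapping <- function(genes, mapping) {
  stopifnot(ncol(mapping) >= 2L)
  from <- normalize_symbols(mapping[[1L]])
  to <- normalize_symbols(mapping[[2L]])
  g <- normalize_symbols(genes)
  hit <- match(g, from)
  g[!is.na(hit)] <- to[hit[!is.na(hit)]]
  g
}
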