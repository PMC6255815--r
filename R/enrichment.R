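#' Build an annotation collection
#'
#' A collection of term -> gene-set annotations with a background size N.
#' When no background is given, N defaults to the size of the union of all
#' term sets (a DAVID-style annotation universe); it may be overridden, e.g.
#' with the interactome size.
#'
#' @param terms Named list of character vectors (term_id -> genes).
#' @param names Optional named character vector of human-readable term
#'   names.
#' @param background Background size N, or \code{NULL} for the union
#'   default.
#' @return A list of class \code{annotation_collection} with fields
#'   \code{terms}, \code{names}, \code{background}, \code{universe}.
#' @export
annotation_collection <- function(terms, names = NULL, background = NULL) {
  stopifnot(is.list(terms), length(terms) > 0L,
            !is.null(base::names(terms)))
  terms <- lapply(terms, function(g) unique(normalize_symbols(g)))
  if (any(vapply(terms, length, 1L) == 0L)) {
    stop("every term must annotate at least one gene")
  }
  universe <- unique(unlist(terms, use.names = FALSE))
  if (is.null(background)) background <- length(universe)
  if (background < max(vapply(terms, length, 1L))) {
    stop("background size must be at least the largest term size")
  }
  if (is.null(names)) {
    names <- stats::setNames(base::names(terms), base::names(terms))
  }
  structure(list(terms = terms, names = names,
                 background = as.integer(background), universe = universe),
            class = "annotation_collection")
}

#' Read a GMT gene-set file
#'
#' Standard GMT rows: \code{term_id <tab> description <tab> gene1 ...}.
#' Genes are normalized; the background defaults to the union of all term
#' sets unless \code{background} is supplied.
#'
#' @param path File path.
#' @param background Optional background size override.
#' @return An \code{\link{annotation_collection}}.
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- strip_comment_blank(lines)
  if (length(idx) == 0L) stop("GMT file is empty: ", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed GMT row at line %d of %s: need term, description, genes",
                 idx[bad[1L]], path))
  }
  ids <- vapply(parts, `[`, "", 1L)
  descs <- vapply(parts, `[`, "", 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  annotation_collection(stats::setNames(sets, ids),
                        names = stats::setNames(descs, ids),
                        background = background)
}

#' Write an annotation collection as GMT
#'
#' @param ann An \code{\link{annotation_collection}}.
#' @param path Output path.
#' @return Invisibly \code{path}.
#' @export
write_gmt <- function(ann, path) {
  rows <- vapply(names(ann$terms), function(id) {
    paste(c(id, unname(ann$names[id]), ann$terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Over-representation analysis with Bonferroni control
#'
#' For a query gene set of size n against each term of size K in a
#' background of N genes, with overlap k, the raw p-value is the upper
#' hypergeometric tail P(X >= k). In \code{ease} mode one overlap member is
#' discounted (k -> k - 1, floored at 0, where k = 0 gives p = 1): the
#' conservative EASE score used by DAVID. Bonferroni-adjusted p-values
#' multiply the raw p by the number of tested terms -- by default only terms
#' with nonzero overlap count as tested (DAVID-style reporting); set
#' \code{multiplier = "all"} to use every term in the collection.
#'
#' Query members outside the background universe are dropped (with a
#' message) before n is determined.
#'
#' @param query A \code{target_set} or character vector of genes.
#' @param ann An \code{\link{annotation_collection}}.
#' @param mode \code{"hypergeometric"} or \code{"ease"}.
#' @param multiplier Bonferroni multiplier rule: \code{"nonzero"} (default)
#'   or \code{"all"}.
#' @param quiet Suppress the dropped-gene message.
#' @return Data frame, p-ascending, with columns \code{term_id},
#'   \code{name}, \code{k}, \code{K}, \code{n}, \code{N}, \code{p_raw},
#'   \code{p_bonferroni}, \code{overlap}.
#' @examples
#' ann <- annotation_collection(list(t1 = LETTERS[1:5], t2 = LETTERS[3:10]))
#' enrich(LETTERS[1:4], ann, quiet = TRUE)
#' @export
enrich <- function(query, ann, mode = c("hypergeometric", "ease"),
                   multiplier = c("nonzero", "all"), quiet = FALSE) {
  mode <- match.arg(mode)
  multiplier <- match.arg(multiplier)
  stopifnot(inherits(ann, "annotation_collection"))
  q <- as_target_members(query)
  inside <- q %in% ann$universe
  if (!quiet && any(!inside)) {
    message("enrich: dropped ", sum(!inside),
            " query gene(s) outside the background universe")
  }
  q <- q[inside]
  n <- length(q)
  if (n == 0L) {
    warning("enrich: empty query after background filtering")
    return(data.frame(term_id = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0), overlap = character(0)))
  }
  N <- ann$background
  ids <- names(ann$terms)
  K <- vapply(ann$terms, length, 1L)
  ov <- lapply(ann$terms, function(g) q[q %in% g])
  k <- vapply(ov, length, 1L)
  k_eff <- if (mode == "ease") pmax(k - 1L, 0L) else k
  # P(X >= k_eff); phyper gives P(X <= q), so use the upper tail at k_eff - 1
  p_raw <- ifelse(k_eff == 0L, 1,
                  stats::phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE))
  n_tests <- if (multiplier == "nonzero") sum(k >= 1L) else length(ids)
  out <- data.frame(term_id = ids,
                    name = unname(ann$names[ids]),
                    k = as.integer(k), K = as.integer(K),
                    n = n, N = N,
                    p_raw = as.numeric(p_raw),
                    p_bonferroni = pmin(1, as.numeric(p_raw) * n_tests),
                    overlap = vapply(ov, function(g)
                      paste(sort(g), collapse = ","), character(1)),
                    row.names = NULL)
  out[order(out$p_raw, out$term_id), , drop = FALSE]
}

#' Filter enrichment rows for significance
#'
#' Strict comparison against \code{alpha} on either the Bonferroni-adjusted
#' p (the usual rule for GO terms) or the raw p (the usual rule for pathway
#' annotations).
#'
#' @param rows Output of \code{\link{enrich}}.
#' @param criterion \code{"bonferroni_lt"} or \code{"raw_lt"}.
#' @param alpha Significance level in (0, 1] (default 0.05).
#' @return The significant subset of \code{rows}.
#' @export
filter_significant <- function(rows, criterion = c("bonferroni_lt", "raw_lt"),
                               alpha = 0.05) {
  criterion <- match.arg(criterion)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  col <- if (criterion == "bonferroni_lt") rows$p_bonferroni else rows$p_raw
  rows[col < alpha, , drop = FALSE]
}
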