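# Independent brute-force oracles, implemented against a plain 0/1 adjacency
# matrix in base R. They deliberately share no code with the package
# implementations they are used to check.

adjacency_of <- function(net) {
  nms <- igraph::V(net)$name
  n <- length(nms)
  A <- matrix(0L, n, n, dimnames = list(nms, nms))
  el <- igraph::as_edgelist(net, names = TRUE)
  for (k in seq_len(nrow(el))) {
    A[el[k, 1L], el[k, 2L]] <- 1L
    A[el[k, 2L], el[k, 1L]] <- 1L
  }
  A
}

# BFS from one source: shortest-path distances and path counts
bfs_sigma <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  sigma <- rep(0, n)
  d[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(A[u, ] == 1L)) {
        if (is.infinite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
        if (d[v] == d[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, sigma = sigma)
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  sp <- lapply(seq_len(n), function(s) bfs_sigma(A, s))
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      if (is.infinite(sp[[s]]$d[t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (sp[[s]]$d[v] + sp[[t]]$d[v] == sp[[s]]$d[t]) {
          bc[v] <- bc[v] +
            sp[[s]]$sigma[v] * sp[[t]]$sigma[v] / sp[[s]]$sigma[t]
        }
      }
    }
  }
  stats::setNames(bc, rownames(A))
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    d <- bfs_sigma(A, v)$d
    reach <- which(is.finite(d) & seq_len(n) != v)
    cc[v] <- if (length(reach) == 0L) 0 else length(reach) / sum(d[reach])
  }
  stats::setNames(cc, rownames(A))
}

oracle_eigenvector <- function(A) {
  n <- nrow(A)
  ec <- stats::setNames(numeric(n), rownames(A))
  # connected components from reachability
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    comp[is.finite(bfs_sigma(A, v)$d)] <- cid
  }
  sizes <- tabulate(comp)
  big <- which(comp == which.max(sizes))
  if (length(big) == 1L) return(ec)
  ev <- eigen(A[big, big, drop = FALSE], symmetric = TRUE)
  v1 <- abs(ev$vectors[, 1L])
  ec[big] <- v1 / sqrt(sum(v1^2))
  ec
}

oracle_lac <- function(A) {
  n <- nrow(A)
  lac <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1L)
    if (length(nb) == 0L) next
    lac[v] <- sum(A[nb, nb, drop = FALSE]) / length(nb)
  }
  stats::setNames(lac, rownames(A))
}

oracle_nc <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  nc <- numeric(n)
  for (u in seq_len(n - 1L)) {
    for (v in (u + 1L):n) {
      if (A[u, v] == 0L) next
      z <- sum(A[u, ] == 1L & A[v, ] == 1L)
      denom <- min(deg[u], deg[v]) - 1
      ecc <- if (denom > 0) z / denom else 0
      nc[u] <- nc[u] + ecc
      nc[v] <- nc[v] + ecc
    }
  }
  stats::setNames(nc, rownames(A))
}

# highest k-core of an adjacency matrix by iterated removal, for the MCODE
# vertex-weight oracle
oracle_highest_core <- function(A) {
  best_k <- 0L
  best <- integer(0)
  k <- 1L
  repeat {
    keep <- seq_len(nrow(A))
    repeat {
      deg <- rowSums(A[keep, keep, drop = FALSE])
      low <- which(deg < k)
      if (length(low) == 0L) break
      keep <- keep[-low]
      if (length(keep) == 0L) break
    }
    if (length(keep) == 0L) break
    best_k <- k
    best <- keep
    k <- k + 1L
  }
  list(k = best_k, members = best)
}

oracle_mcode_weight <- function(A, v, degree_cutoff = 2) {
  nb <- which(A[v, ] == 1L)
  if (length(nb) < degree_cutoff) return(0)
  idx <- c(v, nb)
  sub <- A[idx, idx, drop = FALSE]
  core <- oracle_highest_core(sub)
  if (core$k == 0L) return(0)
  cs <- sub[core$members, core$members, drop = FALSE]
  n <- nrow(cs)
  m <- sum(cs) / 2
  dens <- if (n < 2) 0 else 2 * m / (n * (n - 1))
  core$k * dens
}

# exhaustive hypergeometric tail on a tiny universe by subset enumeration
oracle_hyper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hit_set <- seq_len(K)
  hits <- apply(subsets, 2L, function(s) sum(s %in% hit_set))
  mean(hits >= k)
}

# Erdos-Renyi random network with named nodes
random_network <- function(n, p) {
  nms <- sprintf("N%02d", seq_len(n))
  prs <- t(utils::combn(nms, 2L))
  keep <- stats::runif(nrow(prs)) < p
  netpharm::make_network(prs[keep, , drop = FALSE], nodes = nms, quiet = TRUE)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
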