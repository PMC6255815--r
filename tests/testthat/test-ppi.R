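test_that("1-hop expansion induces the hand-enumerated subgraphs", {
  path <- make_network(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  out <- expand_seeds(path, "B", quiet = TRUE)  # seeds normalized to upper
  # gene normalization uppercases the seed, which then misses lower-case ids
  expect_setequal(igraph::V(out)$name, "B")
  out <- expand_seeds(path, target_set("b"), quiet = TRUE)
  expect_setequal(igraph::V(out)$name, "B")

  pathU <- make_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  out <- expand_seeds(pathU, "B", quiet = TRUE)
  expect_setequal(igraph::V(out)$name, c("A", "B", "C"))
  expect_identical(edge_table(out)[, 1], c("A", "B"))
  expect_equal(igraph::ecount(out), 2L)

  star <- make_network(rbind(cbind("H", paste0("L", 1:4)), c("L1", "L2")))
  out <- expand_seeds(star, "H", quiet = TRUE)
  expect_equal(igraph::vcount(out), 5L)
  expect_equal(igraph::ecount(out), 5L)  # induced includes L1-L2
  out_no <- expand_seeds(star, "H", include_neighbor_edges = FALSE,
                         quiet = TRUE)
  expect_equal(igraph::ecount(out_no), 4L)  # only seed-incident edges
})

test_that("seeds absent from the interactome become isolated seed nodes", {
  inter <- make_network(rbind(c("A", "B")))
  out <- suppressMessages(expand_seeds(inter, c("A", "ZZZ")))
  expect_setequal(igraph::V(out)$name, c("A", "B", "ZZZ"))
  expect_equal(igraph::degree(out)[["ZZZ"]], 0)
  roles <- setNames(igraph::V(out)$role, igraph::V(out)$name)
  expect_identical(unname(roles["ZZZ"]), "seed")
  expect_warning(expand_seeds(make_network(NULL), c("X"), quiet = FALSE),
                 "no seeds")
})

test_that("hop-0 expansion returns the subgraph induced on the seeds", {
  tri <- make_network(rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                            c("C", "D")))
  out <- expand_seeds(tri, c("A", "B"), max_hops = 0, quiet = TRUE)
  expect_setequal(igraph::V(out)$name, c("A", "B"))
  expect_equal(igraph::ecount(out), 1L)
})

test_that("expansion output is always a subgraph of interactome plus seeds", {
  set.seed(9)
  for (i in 1:10) {
    inter <- random_network(25, 0.12)
    seeds <- sample(igraph::V(inter)$name, 4)
    for (hops in 0:2) {
      out <- expand_seeds(inter, seeds, max_hops = hops, quiet = TRUE)
      eo <- edge_table(out); ei <- edge_table(inter)
      expect_true(all(paste(eo[, 1], eo[, 2]) %in% paste(ei[, 1], ei[, 2])))
      expect_true(all(igraph::V(out)$name %in%
                        c(igraph::V(inter)$name, seeds)))
    }
  }
})

test_that("network intersection matches hand enumeration and set algebra", {
  tri <- make_network(rbind(c("A", "B"), c("B", "C"), c("C", "A")))
  pth <- make_network(rbind(c("A", "B"), c("B", "C")))
  out <- intersect_networks(tri, pth)
  expect_identical(edge_table(out), edge_table(pth))
  expect_true(networks_equal(intersect_networks(tri, tri), tri))
  disj <- make_network(rbind(c("X", "Y")))
  expect_equal(igraph::vcount(intersect_networks(tri, disj)), 0L)
})

test_that("intersection is commutative, associative and idempotent", {
  set.seed(31)
  for (i in 1:8) {
    a <- random_network(18, 0.2)
    b <- random_network(18, 0.2)
    c <- random_network(18, 0.2)
    # set-algebra form: keep isolated nodes so node sets compose exactly
    ix <- function(x, y) intersect_networks(x, y, drop_isolated = FALSE)
    expect_true(networks_equal(ix(a, b), ix(b, a)))
    expect_true(networks_equal(ix(ix(a, b), c), ix(a, ix(b, c))))
    expect_true(networks_equal(ix(a, a), a))
  }
})

test_that("drop_isolated controls whether edge-stripped nodes remain", {
  a <- make_network(rbind(c("A", "B"), c("C", "D")))
  b <- make_network(rbind(c("A", "B"), c("C", "E")))
  kept <- intersect_networks(a, b, drop_isolated = FALSE)
  expect_setequal(igraph::V(kept)$name, c("A", "B", "C"))
  dropped <- intersect_networks(a, b)
  expect_setequal(igraph::V(dropped)$name, c("A", "B"))
})

test_that("union of networks covers both inputs", {
  a <- make_network(rbind(c("A", "B")))
  b <- make_network(rbind(c("B", "C")))
  u <- union_networks(a, b)
  expect_equal(igraph::vcount(u), 3L)
  expect_equal(igraph::ecount(u), 2L)
})
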