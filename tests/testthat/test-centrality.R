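test_that("closed forms hold on the triangle, star and isolated node", {
  k3 <- make_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  tab <- compute_centralities(k3)
  expect_equal(tab$dc, rep(2, 3))
  expect_equal(tab$bc, rep(0, 3))
  expect_equal(tab$cc, rep(1, 3))
  expect_equal(tab$ec, rep(1 / sqrt(3), 3), tolerance = 1e-10)
  expect_equal(tab$lac, rep(1, 3))
  expect_equal(tab$nc, rep(2, 3))

  star <- make_network(cbind("H", paste0("L", 1:4)))
  tab <- compute_centralities(star)
  h <- tab[tab$node == "H", ]
  expect_equal(h$dc, 4)
  expect_equal(h$bc, 6)            # C(4,2) leaf pairs
  expect_equal(h$lac, 0)           # no edges among leaves
  expect_equal(h$nc, 0)            # all ECC denominators are 0
  expect_equal(tab$cc[tab$node == "L1"], 4 / 7)
  expect_equal(tab$bc[tab$node != "H"], rep(0, 4))

  iso <- make_network(rbind(c("A", "B")), nodes = "Z")
  tab <- compute_centralities(iso)
  z <- tab[tab$node == "Z", ]
  expect_equal(unlist(z[c("dc", "bc", "cc", "ec", "lac", "nc")]),
               c(dc = 0, bc = 0, cc = 0, ec = 0, lac = 0, nc = 0))
})

test_that("all six measures agree with brute-force oracles on random graphs", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(5:15, 1)
    net <- random_network(n, runif(1, 0.15, 0.6))
    A <- adjacency_of(net)
    tab <- compute_centralities(net)
    ord <- match(tab$node, rownames(A))
    expect_equal(tab$dc, unname(rowSums(A))[ord], tolerance = 1e-9)
    expect_equal(tab$bc, unname(oracle_betweenness(A))[ord], tolerance = 1e-8)
    expect_equal(tab$cc, unname(oracle_closeness(A))[ord], tolerance = 1e-8)
    expect_equal(tab$ec, unname(oracle_eigenvector(A))[ord], tolerance = 1e-8)
    expect_equal(tab$lac, unname(oracle_lac(A))[ord], tolerance = 1e-9)
    expect_equal(tab$nc, unname(oracle_nc(A))[ord], tolerance = 1e-9)
  }
})

test_that("vertex-transitive graphs score constant on every measure", {
  cyc <- make_network(cbind(paste0("v", 1:8), paste0("v", c(2:8, 1))))
  k5 <- make_network(t(utils::combn(paste0("k", 1:5), 2)))
  for (net in list(cyc, k5)) {
    tab <- compute_centralities(net)
    for (m in c("dc", "bc", "cc", "ec", "lac", "nc")) {
      expect_equal(max(tab[[m]]) - min(tab[[m]]), 0, tolerance = 1e-9)
    }
  }
})

test_that("adding an edge never decreases endpoint degree", {
  set.seed(12)
  net <- random_network(12, 0.25)
  nms <- igraph::V(net)$name
  el <- edge_table(net)
  absent <- NULL
  for (a in nms) for (b in nms) {
    if (a < b && !any(el[, 1] == a & el[, 2] == b)) absent <- rbind(absent, c(a, b))
  }
  pick <- absent[1, ]
  bigger <- make_network(rbind(el, pick), nodes = nms, quiet = TRUE)
  d0 <- degree_centrality(net)
  d1 <- degree_centrality(bigger)
  expect_gte(d1[[pick[1]]], d0[[pick[1]]])
  expect_gte(d1[[pick[2]]], d0[[pick[2]]])
})

test_that("eigenvector scoring is confined to the largest component by default", {
  two <- make_network(rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                            c("X", "Y")))
  ec <- eigenvector_centrality(two)
  expect_equal(sum(ec[c("X", "Y")]), 0)
  expect_equal(sum(ec^2), 1, tolerance = 1e-10)
  per <- eigenvector_centrality(two, scope = "components")
  expect_gt(per[["X"]], 0)
  expect_equal(sum(per[c("X", "Y")]^2), 1, tolerance = 1e-10)
})

test_that("the plus-one ECC variant shifts triangle-free edges off zero", {
  # on the path A-B-C-D the middle edge has min(deg)-1 = 1 but no triangles
  pth <- make_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  plain <- network_centrality(pth)
  plus <- network_centrality(pth, ecc_variant = "plus_one")
  expect_equal(unname(plain[["B"]]), 0)
  expect_equal(unname(plus[["B"]]), 1)  # (0+1)/1 on edge B-C, 0 on A-B
})

test_that("centrality tables serialize and round-trip", {
  net <- random_network(10, 0.3)
  tab <- compute_centralities(net, measures = c("dc", "bc", "cc", "ec",
                                                "lac", "nc", "sc"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_centrality_table(tab, p)
  back <- read_centrality_table(p)
  expect_equal(back$node, tab$node)
  expect_equal(back$nc, tab$nc, tolerance = 1e-12)
  expect_equal(back$sc, tab$sc, tolerance = 1e-12)
  expect_error(compute_centralities(net, measures = "zz"), "unknown")
  empty <- compute_centralities(make_network(NULL))
  expect_equal(nrow(empty), 0L)
})
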