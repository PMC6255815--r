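test_that("component generator bookkeeping predicts the screen exactly", {
  g <- gen_components(n_per_herb = c(h1 = 300, h2 = 300),
                      pass_fraction = 0.235, seed = 7)
  kept <- screen_bioactive(g$table, quiet = TRUE)
  expect_setequal(kept$component_id, g$truth$expected_pass)
  expect_equal(length(g$truth$expected_pass), round(0.235 * 600))

  all_pass <- gen_components(c(h = 50), pass_fraction = 1, seed = 1)
  expect_equal(nrow(screen_bioactive(all_pass$table, quiet = TRUE)), 50L)
  none <- gen_components(c(h = 50), pass_fraction = 0, seed = 1)
  expect_equal(nrow(screen_bioactive(none$table, quiet = TRUE)), 0L)
  expect_error(gen_components(c(h = 10), pass_fraction = 2), "pass_fraction")
})

test_that("manual-keep flags are planted on failing components", {
  g <- gen_components(c(h = 100), pass_fraction = 0.2, n_manual_keep = 5,
                      seed = 3)
  expect_length(g$truth$manual_keep, 5)
  expect_length(intersect(g$truth$manual_keep, g$truth$expected_pass), 0)
  kept <- screen_bioactive(g$table, quiet = TRUE)
  expect_setequal(kept$component_id,
                  c(g$truth$expected_pass, g$truth$manual_keep))
})

test_that("component-target degrees are heavy-tailed with the requested mean", {
  ids <- sprintf("c%03d", 1:150)
  g <- gen_component_target(ids, targets = 200, mean_degree = 12, seed = 9)
  expect_equal(mean(g$truth$degrees), 12, tolerance = 0.1 * 12)
  expect_true(all(g$truth$degrees >= 1))
  # degenerate single-target pool: every pair shares that target
  g1 <- gen_component_target(ids[1:5], targets = 1, mean_degree = 1, seed = 2)
  expect_setequal(unique(g1$pairs$target), "TG0001")
  # regeneration determinism
  expect_identical(gen_component_target(ids, 200, 12, seed = 9)$pairs,
                   g$pairs)
})

test_that("disease generator plants its intersection exactly", {
  universe <- sprintf("g%03d", 1:500)
  base <- target_set(sample(universe, 80))
  g <- gen_disease_targets(universe, n = 120, overlap_with = base,
                           overlap_fraction = 0.25, seed = 5)
  got <- intersect_targets(g$targets, base)
  expect_setequal(got$members, g$truth$intersection)
  expect_length(g$truth$intersection, round(0.25 * 120))
  expect_setequal(union_targets(g$sources)$members, g$targets$members)

  g0 <- gen_disease_targets(universe, 50, base, overlap_fraction = 0, seed = 1)
  expect_length(intersect_targets(g0$targets, base), 0)
  g1 <- gen_disease_targets(universe, 50, base, overlap_fraction = 1, seed = 1)
  expect_length(intersect_targets(g1$targets, base), 50)
  expect_error(gen_disease_targets(universe, 10, base, -0.1), "overlap_fraction")
})

test_that("interactome backbone has the attachment-arithmetic edge count", {
  g <- gen_interactome(n = 500, m = 3, seed = 13)
  expect_equal(g$truth$backbone_edges, 3 + 3 * 497)
  expect_equal(igraph::ecount(g$network), 1494L)
  expect_equal(igraph::vcount(g$network), 500L)
  # byte-identical regeneration
  g2 <- gen_interactome(n = 500, m = 3, seed = 13)
  expect_identical(edge_table(g$network), edge_table(g2$network))
})

test_that("planted cliques and hubs appear as specified", {
  g <- gen_interactome(n = 200, m = 2,
                       planted_modules = list(list(size = 6, p_intra = 1)),
                       hub_degree = 50, seed = 17)
  mod <- g$truth$modules[[1]]
  sub <- igraph::induced_subgraph(g$network, mod)
  expect_equal(igraph::ecount(sub), choose(6, 2))  # K6 present
  hub <- g$truth$hubs
  expect_gte(igraph::degree(g$network)[[hub]], 50)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_interactome(n = 50, m = 2, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("a maximal spike makes the spiked term the minimal-p term", {
  universe <- sprintf("g%03d", 1:400)
  g <- gen_annotations(universe, n_terms = 40, query_size = 25,
                       spike_strength = 1, seed = 21)
  rows <- enrich(g$query, g$annotations, quiet = TRUE)
  expect_identical(rows$term_id[1], g$truth$spiked_term)
  expect_setequal(intersect(g$query$members,
                            g$annotations$terms[[g$truth$spiked_term]]),
                  g$truth$planted_overlap)
})

test_that("generated artifacts satisfy their consumers' input invariants", {
  fixdir <- withr::local_tempdir()
  fix <- write_synthetic_fixture(fixdir, seed = 5)
  expect_true(all(file.exists(file.path(fixdir,
    c("components.tsv", "pairs.tsv", "interactome.tsv",
      "annotations.gmt", "truth.json")))))
  tab <- read_component_table(file.path(fixdir, "components.tsv"))
  expect_equal(nrow(tab), 600L)
  net <- read_edge_list(file.path(fixdir, "interactome.tsv"), quiet = TRUE)
  expect_true(validate_network(net))
  expect_true(networks_equal(net, fix$interactome$network))
  pairs <- read_pair_table(file.path(fixdir, "pairs.tsv"))
  expect_true(validate_network(build_bipartite(pairs)))
  ann <- read_gmt(file.path(fixdir, "annotations.gmt"))
  expect_equal(length(ann$terms), 50L)
})
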