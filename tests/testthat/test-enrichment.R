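test_that("GMT parsing normalizes genes and defaults the background to the union", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("t1\tfirst term\ta\tb\tc",
               "t2\tsecond term\tc\td\te\tf"), p)
  ann <- read_gmt(p)
  expect_equal(length(ann$terms), 2L)
  expect_equal(ann$background, 6L)  # union of 3 + 4 genes with 1 shared
  expect_setequal(ann$terms$t1, c("A", "B", "C"))
  # round trip
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, p2)
  back <- read_gmt(p2)
  expect_equal(back$terms, ann$terms)
  expect_equal(back$names, ann$names)
  expect_equal(back$background, ann$background)
  # malformed row
  p3 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("t1\tok\ta", "t2\tnogenes"), p3)
  expect_error(read_gmt(p3), "line 2")
})

test_that("a generated 50-term collection parses to 50 terms", {
  ga <- gen_annotations(sprintf("g%03d", 1:300), n_terms = 50, seed = 2)
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ga$annotations, p)
  expect_equal(length(read_gmt(p)$terms), 50L)
})

test_that("the all-overlap case matches the closed form 1/C(20,5)", {
  universe <- sprintf("u%02d", 1:20)
  ann <- annotation_collection(list(term = universe[1:5]),
                               background = 20)
  rows <- enrich(universe[1:5], ann, quiet = TRUE)
  expect_equal(rows$k, 5L)
  expect_equal(rows$p_raw, 1 / choose(20, 5), tolerance = 1e-12)
})

test_that("zero overlap gives p = 1 in both modes", {
  ann <- annotation_collection(list(t1 = c("A", "B"), t2 = c("C", "D")))
  for (mode in c("hypergeometric", "ease")) {
    rows <- suppressMessages(enrich(c("C", "D"), ann, mode = mode))
    expect_equal(rows$p_raw[rows$term_id == "t1"], 1)
  }
})

test_that("hypergeometric tails agree with exhaustive enumeration at N = 8", {
  universe <- sprintf("x%d", 1:8)
  for (K in 1:8) {
    for (n in 1:8) {
      # the bg term keeps the annotation universe at all 8 genes
      ann <- annotation_collection(list(term = universe[1:K],
                                        bg = universe))
      # place the query to realize every feasible overlap k
      for (k in max(0, n + K - 8):min(n, K)) {
        qk <- c(universe[seq_len(k)],
                if (n - k > 0) universe[K + seq_len(n - k)] else NULL)
        rows <- enrich(qk, ann, quiet = TRUE)
        row <- rows[rows$term_id == "term", ]
        expect_equal(row$k, as.integer(k))
        expect_equal(row$p_raw, oracle_hyper_tail(8, K, n, k),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the hypergeometric pmf sums to one for every triple exercised", {
  for (N in c(8, 20)) for (K in c(2, 5)) for (n in c(3, 6)) {
    ks <- 0:min(n, K)
    expect_equal(sum(stats::dhyper(ks, K, N - K, n)), 1, tolerance = 1e-12)
  }
})

test_that("p_raw is non-increasing in k and EASE never beats hypergeometric", {
  universe <- sprintf("u%02d", 1:30)
  ann <- annotation_collection(list(term = universe[1:10], bg = universe))
  prev <- 1.000001
  for (k in 0:8) {
    q <- c(universe[seq_len(k)],
           if (8 - k > 0) universe[10 + seq_len(8 - k)] else NULL)
    ph <- enrich(q, ann, quiet = TRUE)
    ph <- ph$p_raw[ph$term_id == "term"]
    pe <- enrich(q, ann, mode = "ease", quiet = TRUE)
    pe <- pe$p_raw[pe$term_id == "term"]
    expect_lte(ph, prev)
    expect_gte(pe, ph)
    prev <- ph
  }
})

test_that("the Bonferroni multiplier counts tested terms as configured", {
  ann <- annotation_collection(list(t1 = c("A", "B", "C"),
                                    t2 = c("D", "E"),
                                    t3 = c("F", "G")))
  rows <- enrich(c("A", "B"), ann, quiet = TRUE)
  r1 <- rows[rows$term_id == "t1", ]
  expect_equal(r1$p_bonferroni, min(1, r1$p_raw * 1))  # only t1 overlaps
  rows_all <- enrich(c("A", "B"), ann, multiplier = "all", quiet = TRUE)
  r1a <- rows_all[rows_all$term_id == "t1", ]
  expect_equal(r1a$p_bonferroni, min(1, r1a$p_raw * 3))
})

test_that("significance filtering is strict on the chosen column", {
  rows <- data.frame(term_id = c("a", "b", "c"),
                     p_raw = c(0.04, 0.05, 0.2),
                     p_bonferroni = c(0.04, 0.2, 1))
  expect_identical(filter_significant(rows, "bonferroni_lt")$term_id, "a")
  expect_identical(filter_significant(rows, "raw_lt")$term_id, "a")
  set.seed(4)
  rnd <- data.frame(term_id = sprintf("t%02d", 1:50),
                    p_raw = runif(50), p_bonferroni = runif(50))
  naive <- rnd$term_id[rnd$p_raw < 0.3]
  expect_identical(filter_significant(rnd, "raw_lt", alpha = 0.3)$term_id,
                   naive)
  expect_error(filter_significant(rnd, alpha = 0), "alpha")
})

test_that("query genes outside the background are dropped before testing", {
  ann <- annotation_collection(list(t1 = c("A", "B")))
  expect_message(rows <- enrich(c("A", "ZZZ"), ann), "dropped 1")
  expect_equal(rows$n[1], 1L)
  expect_warning(out <- enrich("QQQ", ann, quiet = TRUE), "empty query")
  expect_equal(nrow(out), 0L)
})
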