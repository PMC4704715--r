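test_that("fold enrichment reproduces the screen's printed ratios", {
  expect_equal(round(fold_enrichment(104, 230, 293, 4609), 0), 7)
  expect_equal(fold_enrichment(104, 230, 293, 4609), 7.11, tolerance = 1e-3)
  expect_equal(round(fold_enrichment(43, 230, 85, 4609), 1), 10.1)
  expect_equal(round(fold_enrichment(28, 230, 62, 4609), 1), 9.0)
  expect_equal(fold_enrichment(0, 230, 85, 4609), 0)
  # scale consistency: doubling k and n leaves fold unchanged
  expect_equal(fold_enrichment(20, 100, 50, 1000),
               fold_enrichment(40, 200, 50, 1000))
  expect_error(fold_enrichment(1, 10, 0, 100), "K = 0")
  expect_error(fold_enrichment(5, 4, 10, 100), "inconsistent")
})

test_that("hypergeometric tails are exact at the boundaries", {
  # P(X <= 11) for the respiration-deficient overlap in the High tail
  expect_equal(round(hypergeom_tail(11, 230, 293, 4609, "lower"), 3), 0.196)
  # k = 0: upper tail is certain, lower tail is the pmf at 0
  expect_equal(hypergeom_tail(0, 10, 4, 20, "upper"), 1)
  expect_equal(hypergeom_tail(0, 10, 4, 20, "lower"),
               choose(16, 10) / choose(20, 10), tolerance = 1e-12)
  # extreme tails must not underflow to zero prematurely
  expect_gt(hypergeom_tail(104, 230, 293, 4609, "upper"), 0)
  expect_lt(hypergeom_tail(104, 230, 293, 4609, "upper"), 1e-40)
})

test_that("tails match exhaustive enumeration of all draws (N=20, n=10, K=4)", {
  N <- 20; n <- 10; K <- 4
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)  # members 1..K form the labelled set
  for (k in 0:K) {
    expect_equal(hypergeom_tail(k, n, K, N, "upper"), mean(overlap >= k),
                 tolerance = 1e-12)
    expect_equal(hypergeom_tail(k, n, K, N, "lower"), mean(overlap <= k),
                 tolerance = 1e-12)
  }
})

test_that("log-space summation agrees with the reference distribution on N<=25 grids", {
  for (N in c(7, 12, 19, 25)) {
    for (K in unique(c(1, 3, N %/% 2, N - 1))) {
      for (n in unique(c(1, N %/% 3, N %/% 2, N - 1))) {
        for (k in max(0, n - (N - K)):min(n, K)) {
          expect_equal(hypergeom_tail(k, n, K, N, "upper"),
                       stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       tolerance = 1e-12)
          expect_equal(hypergeom_tail(k, n, K, N, "lower"),
                       stats::phyper(k, K, N - K, n),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("upper(k) + lower(k-1) = 1 across parameter sweeps", {
  set.seed(4)
  for (i in 1:200) {
    N <- sample(5:400, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    lo <- max(0, n - (N - K)); hi <- min(n, K)
    k <- sample(max(lo, 1):max(hi, 1), 1)
    expect_equal(hypergeom_tail(k, n, K, N, "upper") +
                   hypergeom_tail(k - 1, n, K, N, "lower"), 1,
                 tolerance = 1e-12)
  }
})

test_that("term enrichment flags planted terms and orders by fold", {
  # enough source plates that per-well centering leaves effects intact
  sim <- simulate_screen(small_config(n_strains = 960L, seed = 21L))
  truth <- sim$truth
  sets <- simulate_annotations(truth, n_planted_terms = 3, n_null_terms = 10,
                               term_size_range = c(8L, 12L),
                               planted_overlap = 1.0, seed = 2L)
  res <- score_screen(sim$plates, sim$map)
  universe <- res$scores$strain[!is.na(res$scores$mean_log2_rlu)]
  coll <- gene_set_collection(sets, universe)
  rows <- enrich_terms(res$hits$low, coll)
  expect_true(all(diff(rows$fold) <= 0))
  planted <- grep("^PLANTED", rows$term, value = TRUE)
  expect_gt(length(planted), 0)
  # fully planted terms beat every null term's p-value
  worst_planted <- max(rows$p[rows$term %in% planted])
  null_rows <- rows$p[grepl("^NULL", rows$term)]
  if (length(null_rows)) expect_lt(worst_planted, min(null_rows))
  expect_true(all(rows$significant[rows$term %in% planted]))
})

test_that("a single-member term cannot reach significance at 0.01", {
  universe <- sprintf("g%04d", 1:4609)
  sets <- list(SINGLE = universe[1])
  coll <- gene_set_collection(sets, universe)
  rows <- enrich_terms(universe[1:230], coll)
  expect_equal(rows$k, 1L)
  expect_equal(rows$fold, 4609 / 230, tolerance = 1e-12)
  expect_equal(rows$p, 230 / 4609, tolerance = 1e-12)
  expect_false(rows$significant)
})

test_that("groups disjoint from all terms yield no rows", {
  universe <- sprintf("g%03d", 1:500)
  coll <- gene_set_collection(list(A = universe[1:10]), universe)
  rows <- enrich_terms(universe[400:450], coll)
  expect_equal(nrow(rows), 0L)
  expect_error(enrich_terms(character(), coll), "empty")
  expect_warning(enrich_terms(c(universe[1:20], "not_measured"), coll),
                 "outside the universe")
})

test_that("redundancy trimming collapses duplicates and keeps distinct terms", {
  row <- function(term, p, fold, hits) {
    data.frame(term = term, description = "", k = length(hits), n = 50,
               K = 10, N = 500, fold = fold, p = p,
               hit_genes = paste(sort(hits), collapse = ","),
               significant = TRUE, stringsAsFactors = FALSE)
  }
  g <- sprintf("g%02d", 1:12)
  rows <- rbind(row("A", 1e-6, 9, g[1:6]),   # identical hit sets: A beats B
                row("B", 1e-4, 8, g[1:6]),
                row("C", 1e-3, 7, g[7:12]))  # disjoint: survives
  out <- trim_redundant(rows, 0.8)
  expect_setequal(out$term, c("A", "C"))
  expect_equal(attr(out, "trim_method"), "jaccard_surrogate")

  # nested at Jaccard 0.5 stays below the 0.8 threshold: both survive
  rows2 <- rbind(row("D", 1e-6, 9, g[1:3]), row("E", 1e-4, 8, g[1:6]))
  expect_setequal(trim_redundant(rows2, 0.8)$term, c("D", "E"))
  # disjoint terms all survive
  rows3 <- rbind(row("F", 1e-5, 5, g[1:3]), row("G", 1e-4, 4, g[4:6]))
  expect_equal(nrow(trim_redundant(rows3, 0.8)), 2L)
})

test_that("the overlap test is direction-aware and trims to the universe", {
  universe <- sprintf("g%04d", 1:4609)
  resp <- universe[1:293]
  low_like <- c(universe[1:104], universe[3000:3125])   # k = 104 of 230
  r1 <- set_overlap_test(low_like, resp, universe)
  expect_equal(r1$k, 104L)
  expect_equal(r1$direction, "enriched")
  expect_equal(r1$fold, 7.11, tolerance = 1e-3)

  high_like <- c(universe[1:11], universe[3000:3218])   # k = 11 of 230
  r2 <- set_overlap_test(high_like, resp, universe)
  expect_equal(r2$direction, "depleted")
  expect_equal(round(r2$p, 3), 0.196)

  # a 341-member list reduces to its 293 measured members
  padded <- c(resp, sprintf("x%03d", 1:48))
  r3 <- set_overlap_test(high_like, padded, universe)
  expect_equal(r3$K, 293L)

  # exactly the chance expectation counts as enriched with p >= 0.5
  uni <- sprintf("u%02d", 1:20)
  r4 <- set_overlap_test(uni[1:10], uni[c(1, 2, 11, 12)], uni)
  expect_equal(r4$k, 2L)
  expect_equal(r4$direction, "enriched")
  expect_gte(r4$p, 0.5)
})
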