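test_that("mapping to the universe drops unmapped symbols and reports them", {
  mapped <- mapToUniverse(c("INVS", "DNAH1", "NOT_A_GENE"),
                          c("INVS", "DNAH1", "TTN"))
  expect_setequal(as.character(mapped), c("INVS", "DNAH1"))
  expect_equal(attr(mapped, "unmapped"), "NOT_A_GENE")
  # a list inside the background maps to itself
  expect_setequal(as.character(mapToUniverse(c("a", "b"), c("A", "B", "C"))),
                  c("A", "B"))
  expect_error(mapToUniverse(c("X", "Y"), c("A", "B")), "no gene")
  expect_error(mapToUniverse("A", character(0)), "empty")
})

test_that("hypergeometric right tail matches exact summation on knowns", {
  # 3856/15504 by direct summation of the three terms
  expect_equal(hypergeomRightTail(2, 5, 4, 20), exactRightTail(2, 5, 4, 20),
               tolerance = 1e-14)
  expect_equal(hypergeomRightTail(2, 5, 4, 20), 3856 / 15504,
               tolerance = 1e-12)
  expect_equal(hypergeomRightTail(0, 5, 4, 20), 1)
  expect_equal(hypergeomRightTail(7, 7, 7, 7), 1)  # the single certain term
  expect_error(hypergeomRightTail(5, 4, 10, 20), "impossible")
  expect_error(hypergeomRightTail(3, 25, 10, 20), "<= N")
})

test_that("right tail agrees with phyper and the exact oracle on a grid", {
  set.seed(41)
  for (rep in 1:300) {
    N <- sample(5:48, 1)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    p <- hypergeomRightTail(k, n, K, N)
    expect_equal(p, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(p, exactRightTail(k, n, K, N), tolerance = 1e-12)
  }
})

test_that("EASE removes one list hit and is conservative everywhere", {
  expect_equal(easeScore(1, 5, 4, 20), 1)     # singleton carries no evidence
  expect_equal(easeScore(0, 5, 4, 20), 1)
  expect_equal(easeScore(2, 5, 4, 20), hypergeomRightTail(1, 4, 4, 20))
  expect_equal(easeScore(2, 5, 4, 20), exactRightTail(1, 4, 4, 20),
               tolerance = 1e-12)
  set.seed(42)
  for (rep in 1:200) {
    N <- sample(5:60, 1)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    k <- sample(1:max(1, min(n, K)), 1)
    expect_gte(easeScore(k, n, K, N) + 1e-12, hypergeomRightTail(k, n, K, N))
  }
})

test_that("Benjamini-Hochberg step-up behaves on hand-derived cases", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.05, 4)), rep(0.05, 4))
  expect_equal(bhAdjust(c(0.01, 0.5), method = "bonferroni"), c(0.02, 1))
  expect_equal(bhAdjust(c(0.01, 0.5), method = "none"), c(0.01, 0.5))
})

test_that("fold enrichment is scale invariant and 1 at proportion identity", {
  # multiplying K and N by a common integer leaves the fold unchanged
  baseTs <- function(K, N) {
    genes <- sprintf("B%04d", seq_len(N))
    TermSets("T", "term", list(genes[seq_len(K)]))
  }
  g <- sprintf("B%04d", 1:20)  # 20-gene list, first 10 in the term
  for (mult in c(1, 3)) {
    # k = 10 and n = 20 fixed; K and N scale by `mult`
    term <- c(sprintf("B%04d", 1:10),
              if (mult > 1) sprintf("B%04d", 100 + seq_len(10 * (mult - 1))))
    ts <- TermSets("T", "term", list(term))
    e <- enrich(g, ts, background = sprintf("B%04d", seq_len(200 * mult)),
                min_count = 1)
    expect_equal(e$count, 10L)
    expect_equal(e$fold_enrichment, (10 / 20) / (10 / 200))
  }
  # k/n == K/N exactly -> fold 1
  ts <- baseTs(100, 200)
  gl <- c(sprintf("B%04d", 1:10), sprintf("B%04d", 101:110))
  e <- enrich(gl, ts, background = sprintf("B%04d", 1:200), min_count = 1)
  expect_equal(e$fold_enrichment, 1)
})

test_that("enrich reports counts, percentages and suppresses singleton terms", {
  universe <- sprintf("U%04d", 1:500)
  ts <- TermSets(c("T1", "T2", "T3"), c("hit term", "singleton", "cold"),
                 list(universe[1:50], universe[c(1, 450)], universe[301:350]))
  gl <- universe[1:25]
  e <- enrich(gl, ts, background = universe)
  expect_equal(e$term_id, "T1")        # T2 has k=1 < min_count, T3 k=0
  expect_equal(e$count, 25L)
  expect_equal(e$n_list, 25L)
  expect_equal(e$pct, 100)
  expect_equal(e$K_background, 50L)
  expect_equal(e$N_background, 500L)
  expect_equal(e$fold_enrichment, (25 / 25) / (50 / 500))
  expect_equal(e$genes, paste(sort(universe[1:25]), collapse = ","))
  # raw Fisher mode gives smaller p than the EASE default
  eF <- enrich(gl, ts, background = universe, ease = FALSE)
  expect_lt(eF$p_raw, e$p_raw)
  expect_equal(eF$p_raw, hypergeomRightTail(25, 25, 50, 500))
  expect_equal(e$p_raw, hypergeomRightTail(24, 24, 50, 500))
})

test_that("results come back sorted by ascending raw p", {
  sim <- simulateCohort(simulationParams(n_families = 3, seed = 5,
                                         variants_median = 30,
                                         variants_range = c(15L, 45L)))
  ret <- filterCohort(sim$variants, sim$cohort)$retained
  gl <- unique(unlist(lapply(ret, genes)))
  e <- enrich(gl, sim$termSets)
  expect_true(!is.unsorted(e$p_raw))
  expect_true(all(e$p_adjusted >= e$p_raw - 1e-15))
  expect_true(all(e$count >= 2))
})
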