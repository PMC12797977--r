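toy_sets <- function(lists) {
  structure(lists,
            descriptions = setNames(rep("", length(lists)), names(lists)),
            class = "gene_sets")
}

test_that("Fisher enrichment handles degenerate overlaps", {
  universe <- sprintf("g%02d", 1:20)
  sets <- toy_sets(list(S1 = universe[1:5], S2 = universe[6:10]))

  # no overlap -> p = P(X >= 0) = 1
  r <- fisher_enrichment(universe[11:15], universe, sets)
  expect_identical(r$k[r$set_id == "S1"], 0L)
  expect_identical(r$p_fisher[r$set_id == "S1"], 1)

  # full overlap of a 5-set by a 5-query: p = 1/C(20,5)
  r <- fisher_enrichment(universe[1:5], universe, sets)
  expect_equal(r$p_fisher[r$set_id == "S1"], 1 / choose(20, 5), tolerance = 1e-12)

  # query = universe -> every set fully hit, p = 1
  r <- fisher_enrichment(universe, universe, sets)
  expect_true(all(r$k == r$K))
  expect_true(all(r$p_fisher == 1))

  expect_error(fisher_enrichment(c("g01", "nope"), universe, sets), "nope")
})

test_that("Fisher p-values match exact hypergeometric tail enumeration", {
  set.seed(14)
  for (i in 1:60) {
    N <- sample(5:50, 1)
    universe <- sprintf("u%03d", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    sets <- toy_sets(list(S = sample(universe, K)))
    query <- sample(universe, n)
    r <- fisher_enrichment(query, universe, sets)
    k <- length(intersect(query, sets$S))
    expect_equal(r$p_fisher, hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
    # agreement with one-sided fisher.test on the 2x2 table
    ft <- fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                      alternative = "greater")
    expect_equal(r$p_fisher, ft$p.value, tolerance = 1e-9)
  }
})

test_that("adding a member gene to the query never increases the set's p", {
  set.seed(15)
  universe <- sprintf("u%03d", 1:40)
  sets <- toy_sets(list(S = universe[1:12]))
  query <- sample(universe[13:40], 6)
  p_prev <- fisher_enrichment(query, universe, sets)$p_fisher
  for (g in universe[1:5]) {
    query <- c(query, g)
    p_new <- fisher_enrichment(query, universe, sets)$p_fisher
    expect_lte(p_new, p_prev + 1e-15)
    p_prev <- p_new
  }
})

test_that("sets are intersected with the universe and empty ones skipped", {
  universe <- sprintf("u%02d", 1:10)
  sets <- toy_sets(list(inU = c(universe[1:3], "ghost1", "ghost2"),
                        outU = c("ghost3", "ghost4")))
  r <- fisher_enrichment(universe[1:2], universe, sets)
  expect_identical(r$set_id, "inU")
  expect_identical(r$K, 3L)   # ghosts excluded from the set size
})

test_that("significance is strict FDR < cut over tested sets", {
  universe <- sprintf("u%03d", 1:100)
  sets <- toy_sets(list(hit = universe[1:10], miss = universe[51:60]))
  r <- fisher_enrichment(universe[1:10], universe, sets)
  expect_identical(r$q_fdr, bh_adjust(r$p_fisher))
  expect_identical(r$significant, r$q_fdr < 0.05)
})

test_that("radar values clip into the configured range", {
  mk <- function(q) data.frame(set_id = names(q), neg_log10_q = -log10(unname(q)))
  tabs <- list(cmpA = mk(c(P1 = 1, P2 = 1e-10, P3 = 0.001)),
               cmpB = mk(c(P1 = 0.05, P2 = 0.5, P3 = 1e-4)))
  spec <- radar_values(tabs, c("P1", "P2", "P3"), cap_min = 0, cap_max = 6)
  expect_equal(spec["cmpA", "P1"], 0)     # q = 1 -> 0
  expect_equal(spec["cmpA", "P2"], 6)     # clipped at cap_max
  expect_equal(spec["cmpA", "P3"], 3)     # -log10(0.001)
  expect_true(all(spec >= 0 & spec <= 6))

  # a pathway missing from one comparison falls back to cap_min
  tabs$cmpB <- tabs$cmpB[tabs$cmpB$set_id != "P2", ]
  expect_message(spec2 <- radar_values(tabs, c("P1", "P2", "P3"), cap_max = 6),
                 "P2")
  expect_equal(spec2["cmpB", "P2"], 0)

  expect_error(radar_values(tabs, "P1", cap_min = 6, cap_max = 6), "cap_min")
  expect_error(radar_values(tabs, "P1"), "cap_max")
})

test_that("radar matrix is invariant to re-ordering up to permutation", {
  mk <- function(q) data.frame(set_id = names(q), neg_log10_q = -log10(unname(q)))
  tabs <- list(A = mk(c(P1 = 0.01, P2 = 0.2)), B = mk(c(P1 = 0.5, P2 = 1e-3)))
  s1 <- radar_values(tabs, c("P1", "P2"), cap_max = 4)
  s2 <- radar_values(rev(tabs), c("P2", "P1"), cap_max = 4)
  expect_equal(unclass(s1)[c("A", "B"), c("P1", "P2")],
               unclass(s2)[c("A", "B"), c("P1", "P2")], ignore_attr = TRUE)
})

test_that("radar tables round-trip through delimited text", {
  mk <- function(q) data.frame(set_id = names(q), neg_log10_q = -log10(unname(q)))
  tabs <- list(A = mk(c(P1 = 0.01, P2 = 0.2)))
  spec <- radar_values(tabs, c("P1", "P2"), cap_max = 4)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_radar_table(spec, p)
  back <- as.matrix(read.delim(p, row.names = 1, check.names = FALSE))
  expect_equal(back, unclass(spec), ignore_attr = TRUE)
})
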