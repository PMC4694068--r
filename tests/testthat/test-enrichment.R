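test_that("fold enrichment reproduces printed contingency geometry", {
  # agreement at 2-decimal printed precision (half-ulp of 0.01)
  expect_equal(fold_enrichment(6, 18, 109, 5590), 17.09, tolerance = 3e-4)
  expect_equal(fold_enrichment(2, 18, 14, 5590), 44.36, tolerance = 2e-4)
  expect_equal(fold_enrichment(18, 18, 5590, 5590), 1.0)  # k=L, K=N
  expect_warning(fe0 <- fold_enrichment(0, 18, 109, 5590), "zero overlap")
  expect_equal(fe0, 0)
  expect_error(fold_enrichment(7, 5, 109, 5590), "outside")
  expect_error(fold_enrichment(2, 18, 6000, 5590), "bounds")
})

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_upper_tail(0, 18, 109, 5590), 1.0)
  # X ~ Hypergeom(N=10, K=5, L=5): full pmf enumerable by hand
  expect_equal(hypergeom_upper_tail(2, 5, 5, 10), 226 / 252,
               tolerance = 1e-14)
  expect_equal(hypergeom_upper_tail(3, 5, 5, 10), 0.5, tolerance = 1e-14)
  # oracle equivalence on random small parameter sets
  set.seed(17)
  for (trial in 1:100) {
    N <- sample(10:200, 1L)
    K <- sample(1:N, 1L)
    L <- sample(1:N, 1L)
    k <- sample(0:min(L, K), 1L)
    expect_equal(hypergeom_upper_tail(k, L, K, N),
                 oracle_hyper_upper(k, L, K, N), tolerance = 1e-10)
  }
  # reference library cross-check
  expect_equal(hypergeom_upper_tail(6, 18, 109, 5590),
               stats::phyper(5, 109, 5590 - 109, 18, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the hypergeometric pmf is proper and the tail monotone in k", {
  for (params in list(c(5, 5, 10), c(18, 109, 5590), c(30, 70, 150))) {
    L <- params[1]; K <- params[2]; N <- params[3]
    lo <- max(0, L + K - N)
    pmf <- vapply(lo:min(L, K), function(i) {
      hypergeom_upper_tail(i, L, K, N) -
        hypergeom_upper_tail(i + 1L, L, K, N)
    }, numeric(1L))
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    tails <- vapply(0:min(L, K), hypergeom_upper_tail, numeric(1L),
                    L = L, K = K, N = N)
    expect_true(all(diff(tails) <= 1e-15))
  }
})

test_that("EASE scores drop one overlap gene and dominate the plain tail", {
  expect_equal(ease_p(1, 18, 109, 5590), 1.0)
  expect_equal(ease_p(6, 18, 109, 5590),
               hypergeom_upper_tail(5, 18, 109, 5590))
  expect_equal(ease_p(6, 18, 109, 5590),
               oracle_hyper_upper(5, 18, 109, 5590), tolerance = 1e-10)
  set.seed(23)
  for (trial in 1:50) {
    N <- sample(20:200, 1L)
    K <- sample(2:N, 1L)
    L <- sample(2:N, 1L)
    k <- sample(1:min(L, K), 1L)
    expect_gte(ease_p(k, L, K, N), hypergeom_upper_tail(k, L, K, N))
  }
})

test_that("enrich reports planted geometry, ranks by p, and adjusts by BH", {
  gs <- generate_genesets(n_terms = 40L, N = 5590L, L = 18L,
                          planted_K = 109L, planted_k = 6L, seed = 5L)
  res <- enrich(gs$query, gs$collection)
  planted <- res[res$term_id == gs$planted_id, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$k, 6L)
  expect_equal(planted$L, 18L)
  expect_equal(planted$K, 109L)
  expect_equal(planted$N, 5590L)
  expect_equal(planted$fold_enrichment, 17.09, tolerance = 3e-4)
  expect_identical(res$term_id[1L], gs$planted_id)  # only planted signal
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(diff(res$p_adj) >= -1e-15))       # BH step-up monotone
  expect_true(all(res$p_ease >= res$p_fisher))
})

test_that("enrich handles disjoint, uninformative, and case-mismatched inputs", {
  sets <- list(T1 = c("A", "B", "C"), T2 = c("D", "E"))
  coll <- gene_set_collection(sets, population_total = 100L)
  expect_equal(nrow(enrich(query_list(c("X", "Y", "Z")), coll)), 0L)
  # matching is case-insensitive
  res <- enrich(query_list(c("a", "b", "q")), coll, min_overlap = 2L)
  expect_equal(res$k[res$term_id == "T1"], 2L)
  # a term equal to the whole population is uninformative
  whole <- gene_set_collection(list(ALL = sprintf("G%03d", 1:100)),
                               population_total = 100L)
  res2 <- enrich(query_list(c("G001", "G002")), whole)
  expect_equal(res2$fold_enrichment, 1)
  expect_equal(res2$p, 1)
})

test_that("a larger overlap at equal set size always ranks first", {
  universe <- sprintf("G%04d", 1:2000)
  query <- universe[1:18]
  mk_set <- function(k) c(query[seq_len(k)], universe[500:(500 + 109 - k - 1)])
  coll <- gene_set_collection(list(BIG = mk_set(6), SMALL = mk_set(2)),
                              population_total = 2000L)
  res <- enrich(query_list(query), coll)
  expect_identical(res$term_id, c("BIG", "SMALL"))
  expect_lt(res$p[1L], res$p[2L])
})
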