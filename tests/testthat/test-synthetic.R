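test_that("generation is bit-identical for identical seeds", {
  spec <- synthetic_screen_spec(seed = 1L)
  s1 <- generate_screen(spec)
  s2 <- generate_screen(spec)
  expect_identical(s1$ct, s2$ct)
  expect_identical(s1$prolif, s2$prolif)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_screen(synthetic_screen_spec(seed = 2L))
  expect_false(identical(s1$ct$ct, s3$ct$ct))
})

test_that("a noise-free screen round-trips exactly through the qpcr stage", {
  spec <- synthetic_screen_spec(n_kinases = 40L, n_hits = 8L,
                                ct_noise_sd = 0, seed = 9L)
  sim <- generate_screen(spec)
  fc <- fc_from_sim(sim)
  expected <- 2^sim$truth$log2fc[rownames(fc), colnames(fc)]
  expect_equal(fc, expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(fc["CTRL", ] == 1))
})

test_that("a single planted effect is recovered exactly without noise", {
  spec <- synthetic_screen_spec(n_kinases = 1L, n_hits = 1L,
                                ct_noise_sd = 0,
                                hit_effect_log2_mean = log2(100),
                                hit_effect_log2_sd = 0, seed = 1L)
  sim <- generate_screen(spec)
  fc <- fc_from_sim(sim)
  expect_equal(unname(fc["KIN001", "IL6"]), 100, tolerance = 1e-12)
})

test_that("default calibration matches the screen's magnitude regime", {
  # Monte-Carlo check of the generating truth over 20 seeds: SASP
  # inductions reach beyond 100-fold, hit medians are strong, and p16
  # saturates in the modest (< 4-fold) regime
  p16_max <- sasp_median <- sasp_max <- numeric(20)
  for (s in 1:20) {
    sim <- generate_screen(synthetic_screen_spec(seed = 400L + s))
    tr <- sim$truth
    hits <- tr$kinases$kinase_id[tr$kinases$is_hit]
    sasp_fc <- 2^tr$log2fc[hits, c("IL1A", "IL1B", "IL6", "IL8")]
    p16_max[s] <- max(2^tr$log2fc[, "p16"])
    sasp_median[s] <- stats::median(sasp_fc)
    sasp_max[s] <- max(sasp_fc)
  }
  expect_true(all(p16_max <= 4))
  expect_gte(mean(sasp_median), 10)
  expect_gt(max(sasp_max), 100)  # >100-fold inductions occur in the screen
})

test_that("estimated log2 fold changes regress on truth with slope ~ 1", {
  slopes <- vapply(1:3, function(s) {
    sim <- generate_screen(synthetic_screen_spec(n_kinases = 100L,
                                                 n_hits = 20L,
                                                 seed = 500L + s))
    fc <- fc_from_sim(sim)
    hits <- sim$truth$kinases$kinase_id[sim$truth$kinases$is_hit]
    est <- as.vector(log2(fc[hits, ]))
    tru <- as.vector(sim$truth$log2fc[hits, colnames(fc)])
    unname(stats::coef(stats::lm(est ~ tru))[2L])
  }, numeric(1L))
  expect_true(all(abs(slopes - 1) <= 0.05))
})

test_that("shared-program genes correlate strongly; p16 weaker but positive", {
  within_rho <- p16_rho <- numeric(20)
  shared <- c("IL1A", "IL1B", "IL6", "IL8", "IKBA", "SOD2", "COX2")
  for (s in 1:20) {
    sim <- generate_screen(synthetic_screen_spec(seed = 600L + s))
    fc <- fc_from_sim(sim)
    anti <- call_proliferation_hits(sim$prolif)
    cr <- spearman_matrix(fc[names(anti)[anti], , drop = FALSE])
    rr <- cr$rho[shared, shared]
    within_rho[s] <- mean(rr[lower.tri(rr)])
    p16_rho[s] <- mean(cr$rho["p16", shared])
  }
  expect_gte(mean(within_rho), 0.8)
  expect_gt(mean(p16_rho), 0)
  expect_lt(mean(p16_rho), mean(within_rho))
})

test_that("generate_genesets plants the requested overlap geometry", {
  gs <- generate_genesets(n_terms = 20L, N = 1000L, L = 18L,
                          planted_K = 50L, planted_k = 4L, seed = 2L)
  planted <- gs$collection$genes[[gs$planted_id]]
  expect_length(planted, 50L)
  expect_equal(length(intersect(planted, gs$query$genes)), 4L)
  expect_equal(gs$collection$population_total, 1000L)
  expect_equal(gs$query$mapped_total, 18L)
  # every other term avoids the query entirely
  others <- gs$collection$genes[setdiff(gs$collection$term_ids,
                                        gs$planted_id)]
  expect_true(all(vapply(others, function(g) {
    length(intersect(g, gs$query$genes)) == 0L
  }, logical(1L))))
  # a zero-overlap planted term never surfaces at min_overlap 2
  gs0 <- generate_genesets(n_terms = 10L, N = 1000L, L = 18L,
                           planted_K = 50L, planted_k = 0L, seed = 3L)
  res <- enrich(gs0$query, gs0$collection)
  expect_equal(nrow(res), 0L)
  expect_error(generate_genesets(N = 100L, L = 10L, planted_K = 20L,
                                 planted_k = 15L), "infeasible")
  expect_error(generate_genesets(N = 100L, L = 10L, planted_K = 95L,
                                 planted_k = 2L), "infeasible")
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_screen_spec(n_hits = 300L), "n_hits")
  expect_error(synthetic_screen_spec(ct_noise_sd = -1), "sd")
  expect_error(synthetic_screen_spec(p16_cap_fc = 0.9), "p16_cap_fc")
})
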