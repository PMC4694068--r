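test_that("scale_induction maps 1 to 0 and the column max to 1", {
  expect_equal(scale_induction(c(1, 3, 5)), c(0, 0.5, 1))
  x <- c(1, 2, 7, 4)
  s <- scale_induction(x)
  expect_equal(s[which.max(x)], 1)
  expect_equal(s[x == 1], 0)
  expect_true(all(diff(s[order(x)]) >= 0))  # order-preserving
  # degenerate no-induction column
  expect_equal(scale_induction(c(0.5, 1)), c(0, 0))
  # repressed genes clip to 0, with a message
  expect_message(s2 <- scale_induction(c(0.25, 1, 3)), "clipped")
  expect_equal(s2, c(0, 0, 1))
  expect_error(scale_induction(c(-1, 2)), "> 0")
})

test_that("log2_matrix is elementwise log2 with a zero control row", {
  fc <- rbind(CTRL = c(1, 1), K = c(100, 0.25))
  colnames(fc) <- c("A", "B")
  m <- log2_matrix(fc)
  expect_equal(unname(m["CTRL", ]), c(0, 0))
  expect_equal(unname(m["K", "A"]), log2(100))
  expect_equal(unname(m["K", "B"]), -2)
  expect_identical(attr(induction_matrix(fc, "log2"), "representation"),
                   "log2")
  s01 <- induction_matrix(fc, "scaled01")
  expect_true(all(s01 >= 0 & s01 <= 1))
})

test_that("spearman_matrix matches hand-checkable cases", {
  m <- cbind(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5),
             yr = c(5, 4, 3, 2, 1))
  cr <- spearman_matrix(m)
  expect_equal(unname(diag(cr$rho)), c(1, 1, 1))
  expect_equal(unname(cr$rho["x", "y"]), 0.8)       # brute-force rank Pearson
  expect_equal(unname(cr$rho["x", "yr"]), -1)       # reversed ranks
  expect_equal(unname(cr$p["x", "yr"]), 0)
  expect_true(isSymmetric(cr$rho) && isSymmetric(unname(cr$p)))
  # p agrees with cor.test's t approximation
  ct <- stats::cor.test(m[, "x"], m[, "y"], method = "spearman",
                        exact = FALSE)
  expect_equal(unname(cr$p["x", "y"]), unname(ct$p.value), tolerance = 1e-12)
})

test_that("spearman rho equals the brute-force midrank Pearson oracle", {
  set.seed(101)
  for (trial in 1:60) {
    n <- sample(4:25, 1L)
    m <- matrix(sample(1:8, 3L * n, replace = TRUE) + rnorm(3L * n, 0, 0.1),
                n, 3L, dimnames = list(NULL, c("a", "b", "c")))
    cr <- spearman_matrix(m)
    for (i in 1:2) for (j in (i + 1L):3L) {
      expect_equal(cr$rho[i, j], oracle_spearman(m[, i], m[, j]),
                   tolerance = 1e-12)
    }
    # also agrees with the reference library implementation
    expect_equal(unname(cr$rho),
                 unname(stats::cor(m, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("spearman rho is invariant under strictly monotone column transforms", {
  set.seed(11)
  m <- matrix(rlnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  cr1 <- spearman_matrix(m)
  m2 <- m
  m2[, "a"] <- exp(m2[, "a"])
  m2[, "b"] <- log2(m2[, "b"])
  expect_equal(cr1$rho, spearman_matrix(m2)$rho)
})

test_that("constant columns give NA correlations with a warning, never 0", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), c = c(4, 3, 2, 1))
  expect_warning(cr <- spearman_matrix(m), "constant")
  expect_true(is.na(cr$rho["a", "b"]))
  expect_equal(unname(cr$rho["a", "c"]), -1)
})

test_that("exact permutation p-values are available for small n", {
  m <- cbind(x = 1:5, y = c(1, 2, 3, 4, 5))
  cr <- spearman_matrix(m, p_method = "exact")
  # only the identity and full reversal reach |rho| = 1 among 5! orderings
  expect_equal(unname(cr$p["x", "y"]), 2 / 120)
  expect_error(spearman_matrix(matrix(rnorm(27), 9, 3,
                                      dimnames = list(NULL, letters[1:3])),
                               p_method = "exact"),
               "n <= 8")
})

test_that("clustering joins the most correlated pair first, heights in [0, 2]", {
  set.seed(5)
  base <- rnorm(30)
  m <- cbind(a = base + rnorm(30, 0, 0.1),   # a and b nearly identical
             b = base + rnorm(30, 0, 0.1),
             c = rnorm(30),
             d = rnorm(30))
  dnd <- cluster_profiles(m)
  first <- sort(dnd$labels[-dnd$merge[1L, ]])
  expect_identical(first, c("a", "b"))
  expect_true(all(dnd$height >= 0 & dnd$height <= 2))
  expect_equal(nrow(dnd$merge), ncol(m) - 1L)
  # the Newick string round-trips through a tree parser with the same tips
  tree <- ape::read.tree(text = dnd$newick)
  expect_setequal(tree$tip.label, colnames(m))

  # two identical columns merge first at height 0
  m2 <- cbind(a = base, b = base, c = rnorm(30))
  dnd2 <- cluster_profiles(m2)
  expect_equal(dnd2$height[1L], 0, tolerance = 1e-12)
  expect_identical(sort(dnd2$labels[-dnd2$merge[1L, ]]), c("a", "b"))

  m3 <- cbind(a = 1:10, b = rep(1, 10), c = 10:1)
  expect_error(suppressWarnings(cluster_profiles(m3)), "constant")
})

test_that("on synthetic screens p16 splits from the shared-program genes", {
  separated <- 0L
  for (s in 1:10) {
    sim <- generate_screen(synthetic_screen_spec(seed = 300L + s))
    fc <- fc_from_sim(sim)
    anti <- call_proliferation_hits(sim$prolif)
    sub <- fc[names(anti)[anti], , drop = FALSE]
    cl <- stats::cutree(cluster_profiles(sub)$hclust, k = 2)
    if (sum(cl == cl[["p16"]]) == 1L) separated <- separated + 1L
  }
  expect_gte(separated, 9L)
})
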