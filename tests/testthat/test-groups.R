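test_that("gated test selection follows the normality/homoscedasticity gates", {
  # identical groups: parametric branch, t ~ 0, p ~ 1
  r <- auto_group_test(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(r$method_used, "t")
  expect_lt(abs(r$statistic), 1e-12)
  expect_gt(r$p, 0.99)

  set.seed(15)
  gauss <- c(rnorm(8), rnorm(8, 0.5))
  rg <- auto_group_test(gauss, rep(c("A", "B"), each = 8))
  expect_equal(rg$method_used, "t")
  expect_gt(rg$normality_p, 0.05)

  set.seed(4)
  heavy <- c(10^rnorm(12, sd = 2), 10^rnorm(12, sd = 2))
  rh <- auto_group_test(heavy, rep(c("A", "B"), each = 12))
  expect_equal(rh$method_used, "wilcoxon")
  expect_lt(rh$normality_p, 0.05)

  set.seed(2)
  three <- c(rnorm(6), rnorm(6), rnorm(6, 1))
  r3 <- auto_group_test(three, rep(c("A", "B", "C"), each = 6))
  expect_true(r3$method_used %in% c("anova", "kruskal_wallis"))

  expect_error(auto_group_test(rep(1, 6), rep(c("A", "B"), each = 3)),
               "constant")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) > -1e-12))   # monotone in order statistics
})

test_that("distance matrices match the closed forms", {
  m <- matrix(c(5L, 3L, 5L, 3L), 2, 2)     # identical samples
  expect_equal(max(abs(distance_matrix(make_cm(m), "bray_curtis"))), 0)
  expect_equal(max(abs(distance_matrix(make_cm(m), "jaccard"))), 0)

  dis <- matrix(c(4L, 0L, 0L, 7L), 2, 2)   # disjoint samples
  expect_equal(distance_matrix(make_cm(dis), "bray_curtis")[1, 2], 1)
  expect_equal(distance_matrix(make_cm(dis), "jaccard")[1, 2], 1)

  xy <- matrix(c(1L, 0L, 1L, 2L), 2, 2)
  expect_equal(distance_matrix(make_cm(xy), "bray_curtis")[1, 2], 0.5)

  z <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  expect_error(distance_matrix(make_cm(z), "bray_curtis"), "zero total")
})

test_that("PERMANOVA enumerates exhaustively and matches vegan's pseudo-F", {
  # two tight, well-separated 3v3 clusters on a line: only the mirror
  # arrangement ties the observed F, so p = 2/20 exactly
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(x))
  g <- rep(c("A", "B"), each = 3)
  res <- permanova(d, g, n_permutations = 999)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_permutations, 20)
  expect_equal(res$p, 0.1)
  expect_gt(res$R2, 0.9)

  # agreement with adonis2 on unstructured data
  set.seed(21)
  m <- matrix(rpois(120, 30), 10, 12)
  cm <- make_cm(m)
  d2 <- distance_matrix(cm, "bray_curtis")
  g2 <- sample_groups(cm)
  mine <- permanova(d2, g2, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d2) ~ g2, permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)

  # invariance to a consistent relabelling of samples
  perm <- sample(ncol(m))
  mine2 <- permanova(d2[perm, perm], g2[perm], n_permutations = 99, seed = 1)
  expect_equal(mine2$pseudo_F, mine$pseudo_F)
  expect_equal(mine2$R2, mine$R2)

  # fully degenerate data
  same <- matrix(0, 6, 6)
  res0 <- permanova(same, rep(c("A", "B"), each = 3))
  expect_equal(res0$pseudo_F, 0)
  expect_equal(res0$p, 1)

  # pair-restricted permutations run and stay valid
  rp <- permanova(d2, g2, pairs = sample_pairs(cm), n_permutations = 200,
                  seed = 2)
  expect_gte(rp$p, 1 / 65)
  expect_lte(rp$p, 1)
})

test_that("Venn partition matches hand counts", {
  m <- matrix(c(9L, 1L, 0L, 5L), 2, 2,
              dimnames = list(c("t1", "t2"), c("sA", "sB")))
  v <- venn_partition(make_cm(m, groups = c("A", "B")))
  expect_equal(v$unique_to_A, "t1")
  expect_equal(v$fraction_A, 0.9)
  expect_length(v$unique_to_B, 0)
  expect_equal(v$shared, "t2")

  eq <- matrix(c(3L, 4L, 3L, 4L), 2, 2)
  ve <- venn_partition(make_cm(eq, groups = c("A", "B")))
  expect_length(ve$unique_to_A, 0)
  expect_length(ve$unique_to_B, 0)
})

test_that("random-forest screen ranks a perfectly separating taxon first", {
  set.seed(33)
  m <- matrix(rpois(20 * 12, 50), 20, 12)
  g <- rep(c("A", "B"), 6)
  m[5, g == "A"] <- m[5, g == "A"] + 400L
  cm <- make_cm(m, groups = g)
  imp <- rf_screen(cm, n_trees = 500, seed = 7)
  expect_equal(imp$rank[5], 1L)
  expect_lt(imp$kw_p[5], 0.05)
  expect_identical(imp, rf_screen(cm, n_trees = 500, seed = 7))
  expect_error(rf_screen(make_cm(m, groups = rep("A", 12))), "single class")
})

test_that("Welch comparison matches the hand computation and is symmetric", {
  ft <- function_table(matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
                              dimnames = list("f1", paste0("s", 1:6))))
  g <- rep(c("A", "B"), each = 3)
  w <- welch_compare(ft, g)
  expect_equal(w$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(w$df, 4, tolerance = 1e-8)

  w2 <- welch_compare(ft, rev(g))
  expect_equal(w2$statistic, -w$statistic)
  expect_equal(w2$p, w$p)

  flat <- function_table(matrix(rep(c(1, 1, 1, 1), 2), 2, 4,
                                dimnames = list(c("f1", "f2"), paste0("s", 1:4))))
  wf <- welch_compare(flat, rep(c("A", "B"), each = 2))
  expect_true(all(is.na(wf$p)))
})
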