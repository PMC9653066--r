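test_that("rarefaction draws without replacement to the exact depth", {
  set.seed(1)
  m <- matrix(rpois(40, 60), 10, 4)
  cm <- make_cm(m)
  # exhaustive draw leaves the sample untouched
  full <- rarefy(cm, min(colSums(m)), seed = 1)
  keep_all <- rarefy(subset_counts(cm, samples = which.min(colSums(m))),
                     depth = min(colSums(m)), seed = 1)
  expect_identical(keep_all$counts[, 1], cm$counts[, which.min(colSums(m))])
  expect_true(all(colSums(full$counts) == min(colSums(m))))

  cfg <- synthetic_config(n_taxa = 200, n_pairs = 3, depth_mean = 15000, seed = 8)
  sim <- generate_paired_counts(cfg)
  rr <- rarefy(sim$counts, 10432, seed = 2)
  expect_true(all(colSums(rr$counts) == 10432))
  expect_identical(rr$counts, rarefy(sim$counts, 10432, seed = 2)$counts)

  expect_warning(
    expect_warning(shallow <- rarefy(cm, 10 * max(colSums(m)), seed = 1),
                   "dropping"),
    "no sample")
  expect_equal(ncol(shallow$counts), 0)
  expect_error(rarefy(cm, 0), "positive integer")
})

test_that("mean rarefied richness is monotone in depth", {
  set.seed(42)
  m <- matrix(rnbinom(60, mu = 40, size = 0.5), 30, 2)
  m[1, ] <- m[1, ] + 1L
  cm <- make_cm(m)
  depths <- c(10, 30, 60)
  mean_s <- vapply(depths, function(d) {
    mean(vapply(1:30, function(s) {
      r <- rarefy(cm, d, seed = s)
      mean(colSums(r$counts > 0))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_s) >= 0))
})

test_that("alpha diversity matches hand formulas on known vectors", {
  cm <- make_cm(matrix(c(5L, 1L, 1L, 2L), 4, 1), groups = "A", pairs = "p1")
  d <- alpha_diversity(cm)
  expect_equal(d$observed_richness, 4)
  expect_equal(d$chao1, 6)                # S + F1^2 / (2 F2) = 4 + 4/2
  expect_equal(d$goods_coverage, 1 - 2 / 9)

  even <- make_cm(matrix(rep(10L, 6), 6, 1), groups = "A", pairs = "p1")
  de <- alpha_diversity(even)
  expect_equal(de$invsimpson, 6)
  expect_equal(de$shannon, log(6))
  expect_equal(de$pielou, 1)

  flat <- make_cm(matrix(c(2L, 2L, 2L), 3, 1), groups = "A", pairs = "p1")
  expect_equal(alpha_diversity(flat)$goods_coverage, 1)

  solo <- make_cm(matrix(5L, 1, 1), groups = "A", pairs = "p1")
  expect_true(is.na(alpha_diversity(solo)$pielou))
})

test_that("Fisher's alpha solves its defining equation and matches vegan", {
  # N = 100, S = 10: root of a log(1 + N/a) = S
  x <- c(91, rep(1, 9))
  cm <- make_cm(matrix(as.integer(x), 10, 1), groups = "A", pairs = "p1")
  a <- alpha_diversity(cm)$fisher_alpha
  expect_equal(a, 2.77, tolerance = 0.01)
  expect_equal(a * log(1 + 100 / a), 10, tolerance = 1e-8)
  expect_equal(a, vegan::fisher.alpha(x), tolerance = 1e-4)
})

test_that("richness estimators dominate observed richness and match vegan", {
  set.seed(5)
  for (r in 1:300) {
    x <- rnbinom(40, mu = 3, size = 0.4)
    if (sum(x) == 0) next
    cm <- make_cm(matrix(as.integer(x), 40, 1), groups = "A", pairs = "p1")
    d <- alpha_diversity(cm)
    expect_gte(d$chao1, d$observed_richness)
    if (!is.na(d$ace)) expect_gte(d$ace + 1e-9, d$observed_richness)
  }
  x <- c(10L, 8L, 6L, 4L, 4L, 3L, 2L, 2L, 1L, 1L, 1L, 20L, 15L)
  cm <- make_cm(matrix(x, length(x), 1), groups = "A", pairs = "p1")
  d <- alpha_diversity(cm)
  est <- vegan::estimateR(x)
  expect_equal(d$ace, unname(est["S.ACE"]), tolerance = 1e-8)
  expect_equal(d$shannon, vegan::diversity(x, "shannon"), tolerance = 1e-12)
  expect_equal(d$invsimpson, vegan::diversity(x, "invsimpson"), tolerance = 1e-12)
})

test_that("Faith's PD spans observed leaves including the root path", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  m <- matrix(c(3L, 1L, 2L, 0L, 0L), 5, 1, dimnames = list(star$tip.label, "s1"))
  cm <- make_cm(m, groups = "A", pairs = "p1")
  expect_equal(alpha_diversity(cm, tree = star)$faith_pd, 3)

  pruned <- ape::drop.tip(star, "A")
  expect_error(alpha_diversity(cm, tree = pruned), "missing taxon 'A'")
})

test_that("Faith's PD matches picante on random binary rooted trees", {
  skip_if_not_installed("picante")
  for (r in 1:5) {
    set.seed(40 + r)
    tr <- ape::rtree(12)
    m <- matrix(rbinom(12 * 3, 1, 0.6) * rpois(36, 5), 12, 3,
                dimnames = list(tr$tip.label, paste0("s", 1:3)))
    m[rowSums(m) == 0, 1] <- 1L
    if (any(colSums(m) == 0)) m[1, colSums(m) == 0] <- 1L
    cm <- make_cm(m, groups = c("A", "A", "B"), pairs = c("p1", "p2", "p1"))
    mine <- alpha_diversity(cm, tree = tr)$faith_pd
    ref <- picante::pd(t(m > 0) * 1, tr, include.root = TRUE)$PD
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("function diversity agrees with alpha diversity as cross-oracle", {
  ft <- function_table(matrix(c(0.7, 0.3, 0, 0.5, 0.5, 0, 0.2, 0.3, 0.5), 3, 3,
                              dimnames = list(paste0("f", 1:3), paste0("s", 1:3))))
  fd <- function_diversity(ft)
  expect_equal(fd$richness[2], 2)
  expect_equal(fd$shannon[2], log(2))
  expect_equal(fd$pielou[2], 1)
  expect_equal(fd$invsimpson[2], 2)

  one <- function_table(matrix(0.8, 1, 2, dimnames = list("f1", c("s1", "s2"))))
  fd1 <- function_diversity(one)
  expect_equal(fd1$richness, c(1, 1))
  expect_equal(fd1$invsimpson, c(1, 1))

  # same vector treated as counts must give the same indices
  v <- c(12L, 5L, 2L, 1L)
  cm <- make_cm(matrix(v, 4, 1), groups = "A", pairs = "p1")
  ad <- alpha_diversity(cm)
  ftv <- function_table(matrix(as.numeric(v), 4, 1,
                               dimnames = list(paste0("f", 1:4), "s1")))
  fdv <- function_diversity(ftv)
  expect_equal(fdv$shannon, ad$shannon)
  expect_equal(fdv$invsimpson, ad$invsimpson)
  expect_equal(fdv$pielou, ad$pielou)

  bad <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_error(function_diversity(function_table(bad)), "s2")
})
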