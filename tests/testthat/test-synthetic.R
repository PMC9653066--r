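test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_taxa = 5), "n_taxa")
  expect_error(synthetic_config(n_pairs = 1), "n_pairs")
  expect_error(synthetic_config(
    diff_taxa = data.frame(taxon = c(1, 1), lfc = 2, group = "control")),
    "distinct")
  expect_error(synthetic_config(
    diff_taxa = data.frame(taxon = 2000, lfc = 2, group = "control")),
    "diff_taxa")
  expect_error(synthetic_config(
    corr_blocks = list(list(members = 1:3, loading = 1.4, sign = 1))),
    "loading")
})

test_that("paired counts have the declared shape and are deterministic", {
  cfg <- synthetic_config(n_taxa = 40, n_pairs = 4, depth_mean = 5000, seed = 9)
  a <- generate_paired_counts(cfg)
  b <- generate_paired_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_equal(dim(a$counts), c(40L, 8L))
  expect_true(all(colSums(a$counts$counts) > 0))
  # Poisson library sizes around the mean
  expect_lt(abs(mean(colSums(a$counts$counts)) - 5000), 5 * sqrt(5000))
  expect_setequal(unique(sample_groups(a$counts)), c("control", "treatment"))
})

test_that("a planted log2FC=5 taxon is enriched in nearly every replicate", {
  hits <- 0
  for (r in 1:100) {
    cfg <- synthetic_config(
      n_taxa = 30, n_pairs = 3, depth_mean = 1e5,
      diff_taxa = data.frame(taxon = 7, lfc = 5, group = "treatment"),
      seed = 500 + r)
    sim <- generate_paired_counts(cfg)
    rel <- relative_abundance(sim$counts)
    g <- sample_groups(sim$counts)
    hits <- hits + (mean(rel[7, g == "treatment"]) > mean(rel[7, g == "control"]))
  }
  expect_gte(hits, 99)
})

test_that("without planted effects, taxon-wise Wilcoxon rejects near alpha", {
  # pair_sd = 0: the shared pair intercept induces cross-group dependence
  # that makes the unpaired rank-sum test conservative by design, so the
  # calibration property concerns the generator's sampling noise alone
  n_rej <- 0; n_tests <- 0
  for (r in 1:200) {
    cfg <- synthetic_config(n_taxa = 20, n_pairs = 10, depth_mean = 2000,
                            abundance_shape = 1, pair_sd = 0, seed = 3000 + r)
    sim <- generate_paired_counts(cfg)
    rel <- relative_abundance(sim$counts)
    g <- sample_groups(sim$counts)
    p <- apply(rel, 1, function(v)
      suppressWarnings(wilcox.test(v[g == "control"], v[g == "treatment"])$p.value))
    p <- p[!is.na(p)]
    n_rej <- n_rej + sum(p <= 0.05)
    n_tests <- n_tests + length(p)
  }
  # the exact rank-sum test is discrete at n = 10 per group, so the
  # attainable level sits a little below the nominal 0.05
  expect_gt(n_rej / n_tests, 0.015)
  expect_lt(n_rej / n_tests, 0.075)
})

test_that("within-pair log-abundance correlation exceeds across-pair", {
  within <- c(); across <- c()
  for (r in 1:10) {
    cfg <- synthetic_config(n_taxa = 400, n_pairs = 4, depth_mean = 20000,
                            abundance_shape = 1, pair_sd = 0.5, seed = 40 + r)
    sim <- generate_paired_counts(cfg)
    lg <- log1p(sim$counts$counts)
    lg <- lg - rowMeans(lg)                 # remove the shared baseline
    pr <- sample_pairs(sim$counts)
    cc <- cor(lg)
    same <- outer(pr, pr, "==") & upper.tri(cc)
    diff <- outer(pr, pr, "!=") & upper.tri(cc)
    within <- c(within, cc[same]); across <- c(across, cc[diff])
  }
  expect_gt(mean(within), mean(across))
})

test_that("block members correlate more with each other than with outsiders", {
  d_in <- c(); d_out <- c()
  for (r in 1:5) {
    cfg <- synthetic_config(n_taxa = 30, n_pairs = 12, depth_mean = 20000,
                            abundance_shape = 1,
                            corr_blocks = list(list(members = 1:4, loading = 1,
                                                    sign = 1)),
                            seed = 70 + r)
    sim <- generate_paired_counts(cfg)
    rel <- relative_abundance(sim$counts)
    cc <- cor(t(rel))
    in_block <- cc[1:4, 1:4][upper.tri(cc[1:4, 1:4])]
    out_block <- cc[1:4, 5:30]
    d_in <- c(d_in, in_block); d_out <- c(d_out, out_block)
  }
  expect_gt(mean(d_in), mean(d_out) + 0.5)
})

test_that("generated trees are rooted, binary, reproducible", {
  tr <- generate_tree(c("A", "B"), seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  expect_true(ape::is.rooted(tr))

  tr2 <- generate_tree(paste0("t", 1:25), seed = 5)
  expect_equal(tr2$Nnode, 24)             # n - 1 internal nodes when binary
  expect_true(ape::is.binary(tr2))
  expect_true(all(tr2$edge.length > 0))
  expect_identical(ape::write.tree(tr2),
                   ape::write.tree(generate_tree(paste0("t", 1:25), seed = 5)))
  expect_error(generate_tree("solo"), "at least 2")
})

test_that("function tables conserve total probability and reproduce", {
  cfg <- synthetic_config(n_taxa = 15, n_pairs = 3, depth_mean = 2000, seed = 2)
  sim <- generate_paired_counts(cfg)
  ft <- generate_function_table(sim$counts, n_functions = 1, map_density = 1,
                                seed = 4)
  expect_true(all(abs(unclass(ft) - 1) < 1e-12))
  ft2 <- generate_function_table(sim$counts, n_functions = 20,
                                 map_density = 0.3, seed = 4)
  expect_identical(unclass(ft2),
                   unclass(generate_function_table(sim$counts, 20, 0.3, seed = 4)))
  inc <- attr(ft2, "incidence")
  expect_equal(unclass(ft2), inc %*% relative_abundance(sim$counts),
               ignore_attr = TRUE)
})

test_that("a function carrying only a planted taxon is Welch-detectable", {
  hits <- 0
  for (r in 1:100) {
    cfg <- synthetic_config(
      n_taxa = 20, n_pairs = 5, depth_mean = 20000,
      diff_taxa = data.frame(taxon = 3, lfc = 5, group = "treatment"),
      seed = 900 + r)
    sim <- generate_paired_counts(cfg)
    rel <- relative_abundance(sim$counts)
    ft <- function_table(matrix(rel[3, ], 1,
                                dimnames = list("f1", colnames(rel))))
    wc <- welch_compare(ft, sample_groups(sim$counts))
    hits <- hits + (wc$p < 0.05)
  }
  expect_gte(hits, 95)
})

test_that("assembly scenarios separate groups only in niche mode", {
  within_lt_between <- 0
  diffs <- numeric(50)
  for (r in 1:50) {
    nic <- generate_assembly_scenario("niche", seed = 100 + r)
    d <- distance_matrix(nic, "bray_curtis")
    g <- sample_groups(nic)
    same <- outer(g, g, "==") & upper.tri(d)
    diff <- outer(g, g, "!=") & upper.tri(d)
    within_lt_between <- within_lt_between + (mean(d[same]) < mean(d[diff]))

    dsp <- generate_assembly_scenario("dispersal", seed = 100 + r)
    d2 <- distance_matrix(dsp, "bray_curtis")
    g2 <- sample_groups(dsp)
    diffs[r] <- mean(d2[outer(g2, g2, "!=") & upper.tri(d2)]) -
      mean(d2[outer(g2, g2, "==") & upper.tri(d2)])
  }
  expect_gte(within_lt_between, 48)
  expect_lt(abs(mean(diffs)), 0.02)
  expect_identical(generate_assembly_scenario("niche", seed = 11)$counts,
                   generate_assembly_scenario("niche", seed = 11)$counts)
  expect_error(generate_assembly_scenario("neutral"), "niche")
})
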