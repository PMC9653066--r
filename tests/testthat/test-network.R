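test_that("the prevalence/abundance filter applies both rules", {
  m <- matrix(0L, 3, 4)
  m[1, 1] <- 5000L                       # abundant but in one sample only
  m[2, 1:2] <- c(3L, 2L)                 # prevalent but 5/10000 < 0.1%
  m[3, ] <- c(2000L, 1995L, 500L, 500L)  # passes both
  cm <- make_cm(m)
  kept <- filter_otus(cm)
  expect_equal(taxon_ids(kept), "OTU_3")

  m2 <- m; m2[2, 1:2] <- c(12L, 8L)      # 20 reads / 10000 = 0.2%
  stopifnot(sum(m2) - sum(m2[2, ]) + 20 > 0)
  cm2 <- make_cm(m2)
  expect_true("OTU_2" %in% taxon_ids(filter_otus(cm2)))

  dense <- make_cm(matrix(rpois(20, 100) + 10L, 4, 5))
  expect_identical(filter_otus(dense)$counts, dense$counts)
  expect_warning(empty <- filter_otus(make_cm(m[1, , drop = FALSE])), "no taxon")
  expect_equal(nrow(empty$counts), 0)
})

test_that("network edges reflect exact positive and negative correlation", {
  base <- rpois(10, 50) + 10L
  m <- rbind(a = base, b = 2L * base, c = rpois(10, 30))
  colnames(m) <- paste0("s", 1:10)
  net <- suppressMessages(build_network(make_cm(m)))
  e <- net$edges
  ab <- e[(e$from == "a" & e$to == "b") | (e$from == "b" & e$to == "a"), ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$r, 1)
  expect_equal(ab$sign, "positive")

  # anti-linear proportions: p_x + p_y constant across samples
  x <- c(5L, 10L, 15L, 20L, 25L, 30L, 35L, 40L, 45L, 49L)
  mm <- rbind(x = x, y = 50L - x, filler = rep(50L, 10))
  colnames(mm) <- paste0("s", 1:10)
  net2 <- suppressMessages(build_network(make_cm(mm)))
  e2 <- net2$edges
  expect_equal(nrow(e2), 1)
  expect_equal(e2$r, -1)
  expect_equal(e2$sign, "negative")
  expect_equal(igraph::vcount(net2$graph), 3)   # constant taxon kept isolated

  expect_error(build_network(make_cm(m[, 1:3])), ">= 4 samples")
})

test_that("network construction is invariant to sample and taxon order", {
  cfg <- synthetic_config(n_taxa = 25, n_pairs = 8, depth_mean = 8000,
                          abundance_shape = 1,
                          corr_blocks = list(list(members = 1:3, loading = 1,
                                                  sign = 1)),
                          seed = 77)
  sim <- generate_paired_counts(cfg)
  net <- suppressMessages(build_network(sim$counts))
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  perm_s <- sample(ncol(sim$counts$counts))
  perm_t <- sample(nrow(sim$counts$counts))
  shuffled <- subset_counts(sim$counts, taxa = perm_t, samples = perm_s)
  net2 <- suppressMessages(build_network(shuffled))
  expect_identical(key(net$edges), key(net2$edges))
})

test_that("natural connectivity matches spectral closed forms", {
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(natural_connectivity(empty), 0)
  k2 <- igraph::make_full_graph(2)
  expect_equal(natural_connectivity(k2), log(cosh(1)), tolerance = 1e-12)
  expect_equal(natural_connectivity(k2), 0.4338, tolerance = 1e-4)
  k3 <- igraph::make_full_graph(3)
  expect_equal(natural_connectivity(k3), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  expect_equal(natural_connectivity(k3), 0.9963, tolerance = 1e-4)
})

test_that("natural connectivity never decreases when an edge is added", {
  for (r in 1:40) {
    g <- random_graph(12, 0.25, seed = 600 + r)
    nc0 <- natural_connectivity(g)
    comp <- igraph::complementer(g)
    if (igraph::ecount(comp) == 0) next
    set.seed(r)
    e <- igraph::ends(comp, sample(igraph::ecount(comp), 1))
    g2 <- igraph::add_edges(g, as.vector(t(e)))
    expect_gte(natural_connectivity(g2), nc0 - 1e-12)
  }
})

test_that("property suite matches hand calculations on canonical graphs", {
  k4 <- igraph::make_full_graph(4)
  p <- network_properties(k4)
  expect_equal(p$connectance, 1)
  expect_equal(p$average_degree, 3)
  expect_equal(p$degree_centralization, 0)
  expect_equal(p$n_clusters, 1)

  star <- igraph::make_star(4, mode = "undirected")   # hub + 3 leaves
  ps <- network_properties(star)
  expect_equal(ps$degree_centralization, 1)
  expect_equal(ps$vulnerability, 1)                   # removing the hub: E -> 0

  tri2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(3))
  pt <- network_properties(tri2)
  expect_equal(pt$n_clusters, 2)
  expect_equal(pt$modularity, 0.5)

  g <- random_graph(30, 0.2, seed = 5)
  pg <- network_properties(g)
  expect_equal(sum(igraph::degree(g)), 2 * pg$n_edges)
  expect_gte(pg$connectance, 0)
  expect_lte(pg$connectance, 1)
})

test_that("bootstrapped node attributes resample the intact graph", {
  g <- random_graph(100, 0.08, seed = 9)
  b1 <- bootstrap_node_attributes(g, n_boot = 1, seed = 3)
  expect_length(b1$degree, 100)
  expect_true(all(b1$degree %in% b1$per_node$degree))

  bb <- bootstrap_node_attributes(g, n_boot = 1e5, seed = 4)
  expect_lt(abs(mean(bb$degree) - mean(igraph::degree(g))),
            0.01 * mean(igraph::degree(g)))

  same <- bootstrap_node_attributes(g, n_boot = 2000, seed = 8)
  other <- bootstrap_node_attributes(g, n_boot = 2000, seed = 9)
  expect_lt(ks_compare(same$degree, other$degree)$D, 0.02)
})

test_that("KS comparison hits its boundary cases", {
  expect_equal(ks_compare(1:50, 1:50)$D, 0)
  expect_equal(ks_compare(1:10, 101:110)$D, 1)
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")
})

test_that("removal of half of K10 leaves K5 exactly", {
  k10 <- igraph::make_full_graph(10)
  st <- stability_after_removal(k10, fraction = 0.5, n_replicates = 50, seed = 2)
  expect_true(all(st$average_degree == 4))
  expect_true(all(abs(st$natural_connectivity -
                        natural_connectivity(igraph::make_full_graph(5))) < 1e-9))

  emptyg <- igraph::make_empty_graph(6, directed = FALSE)
  ste <- stability_after_removal(emptyg, 0.5, n_replicates = 5, seed = 1)
  expect_true(all(ste$average_degree == 0))
  expect_true(all(ste$natural_connectivity == 0))
})

test_that("denser graphs keep more degree after removal (KS harness)", {
  dense <- random_graph(100, 0.3, seed = 41)
  sparse <- random_graph(100, 0.1, seed = 42)
  sd_ <- stability_after_removal(dense, 0.5, n_replicates = 300, seed = 1)
  ss <- stability_after_removal(sparse, 0.5, n_replicates = 300, seed = 2)
  ks <- ks_compare(sd_$average_degree, ss$average_degree)
  expect_lt(ks$p, 1e-4)
})

test_that("robustness curves match the complete-graph closed form", {
  n <- 12
  kn <- igraph::make_full_graph(n)
  sweep <- robustness_sweep(kn, fractions = seq(0, 0.75, 0.25),
                            n_replicates = 10, seed = 3)
  expected <- vapply(sweep$curve$fraction,
                     function(f) (n - floor(f * n)) - 1, numeric(1))
  expect_equal(sweep$curve$average_degree_mean, expected)
  expect_equal(sweep$curve$average_degree_sd[-1], rep(0, 3))
  expect_equal(sweep$curve$average_degree_mean[1], n - 1)

  for (r in 1:5) {
    g <- random_graph(40, 0.15, seed = 800 + r)
    rs <- robustness_sweep(g, fractions = seq(0, 0.8, 0.2),
                           n_replicates = 60, seed = r)
    expect_true(all(diff(rs$curve$average_degree_mean) < 0.3))
    expect_lt(rs$fits$average_degree$slope, 0)
  }
})

test_that("degree classes partition, transition and stay disjoint", {
  g <- random_graph(40, 0.2, seed = 10)
  igraph::V(g)$name <- paste0("t", 1:40)
  dc <- degree_class_partition(g, g)
  expect_equal(dc$venn$high$pct_specific, 0)
  expect_equal(dc$venn$low$pct_specific, 0)
  expect_true(all(dc$shared$transition == "none"))
  expect_length(intersect(dc$per_network$A$high, dc$per_network$A$low), 0)

  # hub (max degree) and tip (min degree) swap roles between the networks
  mk <- function(center, pendant) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(c("a", "b", paste0("v", 1:7)))
    g <- igraph::add_edges(g, rbind(center, paste0("v", 1:7)))
    g <- igraph::add_edges(g, rbind(paste0("v", 1:6), paste0("v", 2:7)))
    igraph::add_edges(g, rbind(pendant, "v1"))
  }
  dc2 <- degree_class_partition(mk("a", "b"), mk("b", "a"),
                                high_q = 0.75, low_q = 0.25)
  sh <- dc2$shared[dc2$shared$taxon %in% c("a", "b"), ]
  expect_setequal(sh$transition[sh$taxon == "a"], "high_to_low")
  expect_setequal(sh$transition[sh$taxon == "b"], "low_to_high")

  ga <- random_graph(10, 0.5, seed = 1); igraph::V(ga)$name <- paste0("a", 1:10)
  gb <- random_graph(10, 0.5, seed = 2); igraph::V(gb)$name <- paste0("b", 1:10)
  dc3 <- degree_class_partition(ga, gb)
  expect_equal(dc3$venn$high$pct_specific, 100)
  expect_equal(nrow(dc3$shared), 0)
  expect_error(degree_class_partition(ga, gb, high_q = 0.5, low_q = 0.5),
               "collapse")
})

test_that("delta degree is the absolute shared-node difference", {
  mk <- function(center, pendant) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(c("a", "b", paste0("v", 1:7)))
    g <- igraph::add_edges(g, rbind(center, paste0("v", 1:7)))
    g <- igraph::add_edges(g, rbind(paste0("v", 1:6), paste0("v", 2:7)))
    igraph::add_edges(g, rbind(pendant, "v1"))
  }
  dc <- degree_class_partition(mk("a", "b"), mk("b", "a"))
  dd <- delta_degree(dc)     # degrees: 7 vs 1 either way
  expect_equal(unname(dd[c("a", "b")]), c(6, 6))
  dc_swap <- degree_class_partition(mk("b", "a"), mk("a", "b"))
  expect_equal(delta_degree(dc_swap)[c("a", "b")], dd[c("a", "b")])
  expect_equal(unname(delta_degree(dc, signed = TRUE)[c("a", "b")]), c(-6, 6))
})
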