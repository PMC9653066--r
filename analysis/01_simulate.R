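#!/usr/bin/env Rscript
# Stage 1 — simulate the study communities.
#
# Two synthetic paired communities are generated: a "field-scale" table
# mirroring the sampling design (3 pairs x 2 groups, ~1000 taxa,
# libraries ~ 10^4) used for diversity and composition analyses, and a
# "network-scale" table (15 pairs) with planted differential taxa and
# correlation blocks, since 3 samples per group cannot support
# correlation-based network inference. Assembly scenarios with known
# ground truth, a random phylogeny and a mock function table complete the
# inputs.

suppressMessages(library(netniche))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20220901

field_cfg <- synthetic_config(
  n_taxa = 1000, n_pairs = 3, depth_mean = 12000, abundance_shape = 2,
  diff_taxa = data.frame(taxon = 1:10, lfc = rep(c(3, -3), 5),
                         group = "treatment"),
  seed = seed)
field <- generate_paired_counts(field_cfg)
write_counts(field$counts, "results/data/field_counts.tsv")
message(sprintf("field-scale community: %d taxa x %d samples, %d planted differential taxa",
                nrow(field$counts$counts), ncol(field$counts$counts),
                length(field$truth$true_diff_taxa)))

# pair_sd = 0.3 keeps the pair-intercept leak of the treatment-only block
# below the r = 0.8 edge threshold in the control network
net_cfg <- synthetic_config(
  n_taxa = 150, n_pairs = 15, depth_mean = 20000, abundance_shape = 1.2,
  pair_sd = 0.3,
  diff_taxa = data.frame(taxon = 1:2, lfc = c(5, 4), group = "treatment"),
  corr_blocks = list(list(members = 3:5, loading = 1, sign = 1),
                     list(members = 6:9, loading = 1, sign = 1,
                          group = "treatment")),
  seed = seed + 1)
net <- generate_paired_counts(net_cfg)
write_counts(net$counts, "results/data/network_counts.tsv")
jsonlite::write_json(
  list(true_diff_taxa = net$truth$true_diff_taxa,
       true_edges = net$truth$true_edges),
  "results/data/network_ground_truth.json", auto_unbox = TRUE, digits = NA)
message(sprintf("network-scale community: %d taxa x %d samples, %d planted edges",
                nrow(net$counts$counts), ncol(net$counts$counts),
                nrow(net$truth$true_edges)))

tree <- generate_tree(taxon_ids(field$counts), seed = seed)
write_newick(tree, "results/data/field_tree.nwk")

ft <- generate_function_table(field$counts, n_functions = 60,
                              map_density = 0.05, seed = seed)
write_function_table(ft, "results/data/field_functions.tsv")

for (mode in c("niche", "dispersal")) {
  sc <- generate_assembly_scenario(mode, seed = seed)
  write_counts(sc, sprintf("results/data/assembly_%s.tsv", mode))
}
message("assembly scenarios, tree and function table written to results/data/")
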