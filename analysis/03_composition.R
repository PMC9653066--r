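#!/usr/bin/env Rscript
# Stage 3 — community composition: PERMANOVA, Venn partition, the
# random-forest differential-taxon screen, and function-table comparisons.
#
# PERMANOVA with 9,999 permutations on Bray-Curtis and Jaccard distances
# tests for an overall compositional shift; the Venn partition counts
# group-unique taxa and their sequence share; the random-forest screen
# (Gini importance + Kruskal-Wallis p) is run on the network-scale table,
# where the planted fold-changes give it something to find; Welch's t is
# applied to every function row.

suppressMessages(library(netniche))
dir.create("results", showWarnings = FALSE)

field <- read_counts("results/data/field_counts.tsv",
                     "results/data/field_counts.tsv.metadata.tsv")

perma <- lapply(c(bray_curtis = "bray_curtis", jaccard = "jaccard"),
                function(met) {
  d <- distance_matrix(field, met)
  r <- permanova(d, sample_groups(field), n_permutations = 9999, seed = 1,
                 distance_name = met)
  message(sprintf("PERMANOVA (%s): R2 = %.3f, pseudo-F = %.2f, p = %.3f (%s, %d arrangements)",
                  met, r$R2, r$pseudo_F, r$p, r$method, r$n_permutations))
  unclass(r)
})
jsonlite::write_json(perma, "results/permanova.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

venn <- venn_partition(field)
message(sprintf("unique taxa: %d in %s (%.2f%% of sequences), %d in %s (%.2f%%), %d shared",
                length(venn$unique_to_A), venn$groups[1], 100 * venn$fraction_A,
                length(venn$unique_to_B), venn$groups[2], 100 * venn$fraction_B,
                length(venn$shared)))
jsonlite::write_json(unclass(venn), "results/venn.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

net_counts <- read_counts("results/data/network_counts.tsv",
                          "results/data/network_counts.tsv.metadata.tsv")
imp <- rf_screen(filter_otus(net_counts), n_trees = 5000, seed = 1)
write.table(imp, "results/rf_importance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
top <- head(imp[order(imp$rank), ], 5)
message("top discriminating taxa (Gini rank, KW p):")
print(top[, c("taxon", "mean_decrease_gini", "rank", "kw_p")], digits = 3)

ft <- read_function_table("results/data/field_functions.tsv")
wc <- welch_compare(ft, sample_groups(field))
write.table(wc, "results/function_welch.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d of %d functions differ at Welch p < 0.05 (%d after BH)",
                sum(wc$p < 0.05, na.rm = TRUE), nrow(wc),
                sum(wc$p_adjusted < 0.05, na.rm = TRUE)))
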