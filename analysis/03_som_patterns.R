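#!/usr/bin/env Rscript
# Temporal pattern discovery on the DE genes: 9-condition mean profiles,
# an 18-node (3 x 6) self-organizing map under Pearson distance, rule-based
# merging of nodes into Progressive/Long-term categories, and Fisher-exact
# over-representation of each category against the gene-set collection.

source(file.path("analysis", "00_config.R"))
inputs <- study_inputs()

de_long <- read.delim(file.path(STUDY_DIR, "de_results.tsv"))
seed_genes <- sort(unique(de_long$gene[de_long$p_perm < 0.01]))
cat("SOM seeded with", length(seed_genes), "DE genes.\n")

profiles <- condition_profiles(inputs$se, seed_genes)
som <- train_som(profiles, grid = c(3, 6), seed = STUDY_SEED, epochs = 20)
cats <- merge_to_categories(som, tol = 0.25)

write.table(data.frame(gene = names(som$assignment),
                       node = as.integer(som$assignment),
                       category = unname(cats$gene_category)),
            file.path(STUDY_DIR, "som_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(node = seq_len(nrow(som$prototypes)),
                  category = cats$node_category,
                  as.data.frame(round(som$prototypes, 4))),
            file.path(STUDY_DIR, "som_prototypes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Quantization error", round(som$qe, 4), "(from",
    round(som$qe_init, 4), "at initialization).\n")
cat("Gene-level category sizes:\n")
print(table(cats$gene_category))

# agreement of SOM gene categories with the planted gene patterns
truth <- setNames(inputs$truth_genes$pattern, inputs$truth_genes$gene)
planted <- names(som$assignment)[truth[names(som$assignment)] != "Null"]
agree <- mean(cats$gene_category[planted] == truth[planted])
cat(sprintf("Planted DE genes carrying their planted category: %.0f%%\n",
            100 * agree))

ora <- NULL
for (cat_name in setdiff(unique(cats$gene_category), "Unclassified")) {
  q <- names(cats$gene_category)[cats$gene_category == cat_name]
  ora <- rbind(ora, cbind(category = cat_name,
                          ora_fisher(q, inputs$sets, rownames(inputs$se))))
}
write.table(ora, file.path(STUDY_DIR, "som_ora.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Significant category/set over-representations (p < 0.05):",
    sum(ora$significant), "\n")
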