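#!/usr/bin/env Rscript
# Simulate the study: 26 subjects per group (N1/N2 the same people before and
# after training, M independent long-term practitioners), timepoints T0/T1/T2,
# 2000 genes with six planted temporal modules (Progressive I/II and
# Long-term, up and down) plus decoy gene sets, an interaction network with
# one planted hub per module, and an FeNO-like covariate coupled to the
# Progressive-I-Up pathway. Writes GCT/CLS-style standard formats under
# results/study/.

source(file.path("analysis", "00_config.R"))

dir.create(STUDY_DIR, recursive = TRUE, showWarnings = FALSE)
cfg <- study_config()
sim <- simulate_expression(cfg)
sets <- simulate_gene_sets(cfg, sim$truth)
net <- simulate_network(sim$truth, n_background_nodes = 60,
                        seed = STUDY_SEED + 1L)
cov <- simulate_covariate(sim$se, sim$truth, cfg)

write_gct(sim$se, file.path(STUDY_DIR, "expression.gct"))
write_design_tsv(as.data.frame(SummarizedExperiment::colData(sim$se)),
                 file.path(STUDY_DIR, "design.tsv"))
write_gmt(sets, file.path(STUDY_DIR, "sets.gmt"))
write_sif(net, file.path(STUDY_DIR, "network.sif"))
write_covariate_tsv(cov, file.path(STUDY_DIR, "covariate.tsv"))
write.table(data.frame(gene = names(sim$truth$gene_pattern),
                       pattern = unname(sim$truth$gene_pattern)),
            file.path(STUDY_DIR, "truth_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(set = names(sim$truth$set_pattern),
                       pattern = unname(sim$truth$set_pattern)),
            file.path(STUDY_DIR, "truth_sets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
# per-timepoint class files for external enrichment tools
for (tp in c("T0", "T1", "T2")) {
  cd <- as.data.frame(SummarizedExperiment::colData(sim$se))
  write_cls(cd$group[cd$timepoint == tp],
            file.path(STUDY_DIR, paste0("groups_", tp, ".cls")))
}

cat("Simulated", nrow(sim$se), "genes x", ncol(sim$se), "samples;",
    length(sets), "gene sets (", length(sim$truth$planted_sets),
    "planted );", igraph::vcount(net), "network nodes.\n")
cat("Outputs in", STUDY_DIR, "\n")
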