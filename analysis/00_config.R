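# Shared configuration for the analysis scripts: one simulated study at the
# design's full scale (26 subjects/group, three timepoints) with planted
# Progressive and Long-term modules, analyzed with the thresholds the
# workflow defaults to (DE p < 0.01; enrichment NPV < 0.05 and FDR < 0.25;
# star tiers 0.09/0.05/0.01; 70% overlap merging; top 20 hubs). Permutation
# counts are scaled to keep each script around a minute.

library(rrtempo)

STUDY_SEED <- 2026L
STUDY_DIR <- file.path("results", "study")
N_PERM_DE <- 500L
N_PERM_GSEA <- 200L

study_config <- function() {
  sim_config(n_subjects_per_group = 26, n_genes = 2000, n_sets = 12,
             set_size_range = c(15, 25), seed = STUDY_SEED)
}

study_inputs <- function() {
  list(se = attach_design(parse_gct(file.path(STUDY_DIR, "expression.gct")),
                          read_design_tsv(file.path(STUDY_DIR, "design.tsv"))),
       sets = parse_gmt(file.path(STUDY_DIR, "sets.gmt")),
       net = parse_sif(file.path(STUDY_DIR, "network.sif")),
       covariate = read_covariate_tsv(file.path(STUDY_DIR, "covariate.tsv")),
       truth_sets = read.delim(file.path(STUDY_DIR, "truth_sets.tsv")),
       truth_genes = read.delim(file.path(STUDY_DIR, "truth_genes.tsv")))
}
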