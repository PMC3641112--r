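#!/usr/bin/env Rscript
# Individual-gene differential expression: random-variance moderated t-tests
# with permutation p-values over all nine across-group and nine within-group
# contrasts, strict p < 0.01 selection, and the Venn overlaps of the three
# comparisons at each timepoint / within each group.

source(file.path("analysis", "00_config.R"))
inputs <- study_inputs()

roster <- contrast_roster()
de <- list()
for (i in seq_along(roster)) {
  nm <- names(roster)[i]
  de[[nm]] <- de_analysis(inputs$se, roster[[nm]], n_perm = N_PERM_DE,
                          seed = STUDY_SEED * 100L + i)
}
de_long <- do.call(rbind, lapply(names(de), function(nm)
  cbind(cell = nm, de[[nm]][, c("gene", "t", "df", "p_param", "p_perm",
                                "direction")])))
write.table(de_long, file.path(STUDY_DIR, "de_results.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sel <- lapply(de, select_de, alpha = 0.01)
counts <- vapply(sel, length, 0L)
cat("Differentially expressed genes (permutation p < 0.01) per contrast:\n")
print(counts)

affected <- inputs$truth_genes$gene[inputs$truth_genes$pattern != "Null"]
cat(sprintf("M-vs-N1@T1 recovers %.0f%% of the %d planted genes.\n",
            100 * mean(affected %in% sel[["N1vsM@T1"]]), length(affected)))

venns <- c(
  lapply(setNames(c("T0", "T1", "T2"), paste0("across@", c("T0", "T1", "T2"))),
         function(tp) venn_counts(setNames(
           sel[paste0(c("N1vsN2", "N1vsM", "N2vsM"), "@", tp)],
           c("N1vsN2", "N1vsM", "N2vsM")))),
  lapply(setNames(c("N1", "N2", "M"), paste0("within@", c("N1", "N2", "M"))),
         function(g) venn_counts(setNames(
           sel[paste0(c("T0vsT1", "T0vsT2", "T1vsT2"), "@", g)],
           c("T0vsT1", "T0vsT2", "T1vsT2")))))
venn_df <- do.call(rbind, lapply(names(venns), function(nm)
  data.frame(panel = nm, region = names(venns[[nm]]),
             count = as.integer(venns[[nm]]))))
write.table(venn_df, file.path(STUDY_DIR, "venn_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Venn overlap of the across-group comparisons at T1:\n")
print(venns[["across@T1"]])
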