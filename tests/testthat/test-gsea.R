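test_that("signal-to-noise ranking matches closed-form toy values", {
  # gene1: means 3 vs 1, sds 1; gene2: identical arms
  x <- rbind(G1 = c(2, 3, 4, 0, 1, 2), G2 = c(0, 1, 2, 0, 1, 2))
  ph <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  rk <- rank_genes(x, ph)
  expect_equal(rk$gene, c("G1", "G2"))
  expect_equal(rk$metric, c(1, 0))
})

test_that("degenerate phenotypes are handled or rejected", {
  x <- matrix(rnorm(40), 4, dimnames = list(paste0("G", 1:4), NULL))
  expect_error(rank_genes(x, rep(1, 10)), "constant covariate")
  # identical classes: all metrics zero, ordering by identifier
  xx <- rbind(GB = rep(1, 6), GA = rep(2, 6))
  rk <- rank_genes(xx, factor(rep(c("A", "B"), each = 3)))
  expect_equal(rk$metric, c(0, 0))
  expect_equal(rk$gene, c("GA", "GB"))
  # covariate equal to a gene's own profile ranks that gene first with r = 1
  cov <- x["G3", ]
  rk2 <- rank_genes(x, cov)
  expect_equal(rk2$gene[1], "G3")
  expect_equal(rk2$metric[1], 1)
})

test_that("enrichment score equals step-by-step running-sum enumeration", {
  # singleton set at rank 1 has the maximal score
  rk <- data.frame(gene = paste0("G", 1:10), metric = 10:1 / 10)
  expect_equal(enrichment_score(rk, "G1")$es, 1)
  set.seed(77)
  worst <- 0
  for (i in 1:200) {
    N <- sample(10:50, 1)
    k <- sample(2:min(10, N - 1), 1)
    metric <- sort(round(rnorm(N), 3), decreasing = TRUE)
    genes <- sprintf("G%03d", 1:N)
    set <- sample(genes, k)
    rk <- data.frame(gene = genes, metric = metric)
    es <- enrichment_score(rk, set)$es
    worst <- max(worst, abs(es - oracle_es(metric, genes %in% set)))
    expect_true(es >= -1 && es <= 1)
  }
  expect_lt(worst, 1e-12)
})

test_that("the full running sum starts and ends at zero", {
  set.seed(3)
  genes <- sprintf("G%02d", 1:30)
  rk <- data.frame(gene = genes, metric = sort(rnorm(30), decreasing = TRUE))
  es <- enrichment_score(rk, sample(genes, 6), return_running = TRUE)
  expect_lt(abs(es$running[30]), 1e-9)
  expect_equal(max(abs(es$running)), abs(es$es))
  expect_error(enrichment_score(rk, genes), "whole universe")
  expect_error(enrichment_score(rk, "nope"), "no overlap")
})

test_that("enrichment score agrees with the fgsea implementation", {
  set.seed(8)
  for (i in 1:20) {
    N <- 40
    stats <- sort(rnorm(N), decreasing = TRUE)
    names(stats) <- sprintf("G%03d", 1:N)
    sel <- sort(sample(N, 7))
    rk <- data.frame(gene = names(stats), metric = unname(stats))
    ours <- enrichment_score(rk, names(stats)[sel])$es
    theirs <- fgsea::calcGseaStat(stats, selectedStats = sel, gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("reversing the ranked list with negated metrics flips the score", {
  set.seed(9)
  genes <- sprintf("G%02d", 1:25)
  metric <- sort(rnorm(25), decreasing = TRUE)
  rk <- data.frame(gene = genes, metric = metric)
  rev_rk <- data.frame(gene = rev(genes), metric = rev(-metric))
  for (i in 1:10) {
    set <- sample(genes, 5)
    expect_equal(enrichment_score(rev_rk, set)$es,
                 -enrichment_score(rk, set)$es, tolerance = 1e-12)
  }
})

test_that("a saturated permutation null gives nominal p of 1", {
  # identical samples: every relabeling reproduces the observed ranking, so
  # each set's permuted scores all equal its observed score
  x <- matrix(rep(seq_len(20), 14), 20, 14,
              dimnames = list(sprintf("G%02d", 1:20), NULL))
  sets <- list(S1 = sprintf("G%02d", 1:5), S2 = sprintf("G%02d", 11:16))
  res <- permutation_significance(
    x, factor(rep(c("A", "B"), each = 7)), sets, n_perm = 50, seed = 1,
    mode = "phenotype")
  expect_equal(res$p_nom, c(1, 1))
})

test_that("planted sets pass the enrichment criteria across seeds", {
  hits <- 0
  for (seed in 1:5) {
    cfg <- sim_config(n_subjects_per_group = 10, n_genes = 400, n_sets = 6,
                      set_size_range = c(12, 18),
                      patterns = c("ProgressiveI_Up", "ProgressiveI_Down"),
                      seed = seed)
    sim <- simulate_expression(cfg)
    sets <- simulate_gene_sets(cfg, sim$truth)
    cd <- as.data.frame(SummarizedExperiment::colData(sim$se))
    sel <- cd$group %in% c("N1", "M") & cd$timepoint == "T1"
    res <- permutation_significance(
      SummarizedExperiment::assay(sim$se)[, sel],
      factor(cd$group[sel], levels = c("M", "N1")), sets,
      n_perm = 100, seed = seed)
    row <- res[res$set == "PROG1_UP", ]
    if (row$p_nom < 0.05 && row$fdr_q < 0.25 && row$es > 0) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("decoy nominal p-values are calibrated under the null", {
  se <- null_se(400, 10, seed = 33)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  sel <- cd$group %in% c("N1", "M") & cd$timepoint == "T0"
  set.seed(44)
  sets <- lapply(setNames(1:40, sprintf("D%02d", 1:40)), function(i)
    sample(rownames(se), 15))
  res <- permutation_significance(
    SummarizedExperiment::assay(se)[, sel],
    factor(cd$group[sel], levels = c("M", "N1")), sets,
    n_perm = 100, seed = 5)
  frac <- mean(res$p_nom < 0.05)
  expect_lt(frac, 0.2)  # binomial noise around 0.05 at 40 sets
})

test_that("covariate enrichment flips sign with the covariate", {
  cfg <- sim_config(n_subjects_per_group = 12, n_genes = 300, n_sets = 5,
                    set_size_range = c(10, 14), covariate_r = 0.9,
                    patterns = c("ProgressiveI_Up", "LongTerm_Down"),
                    seed = 6)
  sim <- simulate_expression(cfg)
  sets <- simulate_gene_sets(cfg, sim$truth)
  cov <- simulate_covariate(sim$se, sim$truth, cfg)
  res <- covariate_correlation_gsea(sim$se, cov, group = "M",
                                    from = "T0", to = "T2",
                                    collection = sets, n_perm = 50, seed = 2)
  cov_neg <- cov; cov_neg$value <- -cov_neg$value
  res_neg <- covariate_correlation_gsea(sim$se, cov_neg, group = "M",
                                        from = "T0", to = "T2",
                                        collection = sets, n_perm = 50,
                                        seed = 2)
  expect_equal(res_neg$es, -res$es, tolerance = 1e-9)
  few <- cov[1:4, ]
  expect_error(covariate_correlation_gsea(sim$se, few, group = "M",
                                          from = "T0", to = "T2",
                                          collection = sets, n_perm = 50),
               "fewer than 3 subjects")
})

test_that("a covariate tracking the planted pathway's changes is detected", {
  cfg <- sim_config(n_subjects_per_group = 20, n_genes = 300, n_sets = 5,
                    set_size_range = c(12, 16),
                    patterns = c("ProgressiveI_Up", "LongTerm_Down"),
                    seed = 14)
  sim <- simulate_expression(cfg)
  sets <- simulate_gene_sets(cfg, sim$truth)
  # covariate whose per-subject T0->T2 change is 0.9-correlated with the
  # planted pathway's per-subject expression change in M
  cd <- as.data.frame(SummarizedExperiment::colData(sim$se))
  x <- SummarizedExperiment::assay(sim$se)
  anchor <- "PROG1_UP"
  msub <- unique(cd$subject[cd$group == "M"])
  sid <- function(tp) cd$sample_id[cd$group == "M" & cd$timepoint == tp][
    match(msub, cd$subject[cd$group == "M" & cd$timepoint == tp])]
  dscore <- colMeans(x[sets[[anchor]], sid("T2")]) -
    colMeans(x[sets[[anchor]], sid("T0")])
  set.seed(99)
  delta <- 0.9 * as.numeric(scale(dscore)) +
    sqrt(1 - 0.81) * rnorm(length(dscore))
  cov <- data.frame(sample_id = cd$sample_id, value = 0)
  cov$value[match(sid("T2"), cov$sample_id)] <- delta
  res <- suppressMessages(covariate_correlation_gsea(
    sim$se, cov, group = "M", from = "T0", to = "T2",
    collection = sets, n_perm = 200, seed = 3))
  row <- res[res$set == anchor, ]
  expect_gt(row$es, 0)
  expect_lt(row$p_nom, 0.05)
})
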