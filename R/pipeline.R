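# End-to-end orchestration: simulate (or load) -> differential expression ->
# SOM patterns -> GSEA grid -> dot matrix & pattern calls -> modules -> hubs
# -> covariate correlation, with deterministic per-stage seeds and a manifest.

#' Analysis configuration
#'
#' Holds every threshold of the workflow with its default (DE alpha 0.01 on
#' 1000 permutations; enrichment FDR 0.25 and nominal p 0.05 on 500
#' permutations; within-group star tiers 0.09/0.05/0.01; 70% overlap for
#' module merging; top 20 focus hubs), the contrast roster covering all nine
#' across-group and nine within-group cells, and either a [sim_config()] or
#' input file paths.
#'
#' @param sim A [sim_config()] for simulated input, or NULL.
#' @param paths Named list of input paths (`gct`, `design`, `gmt`, `sif`,
#'   `covariate`) when not simulating.
#' @param alpha DE permutation-p threshold (strict).
#' @param fdr_threshold,npv_threshold Enrichment dot criteria.
#' @param star_levels Within-group star tiers.
#' @param overlap_threshold Module-merge overlap coefficient.
#' @param k_hubs Number of focus hubs.
#' @param n_perm_de,n_perm_gsea Permutation counts (>= 10).
#' @param expand_neighbors Neighbor expansion for pattern networks.
#' @param som_grid SOM grid shape.
#' @param som_tol Prototype separation tolerance for node categorization.
#' @param covariate_contrast Length-3 (group, from, to) for the covariate
#'   correlation stage.
#' @param seed Base seed; per-stage seeds derive from it by a fixed counter
#'   scheme, so adding a stage never perturbs earlier stages.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(sim = sim_config(), paths = NULL,
                            alpha = 0.01, fdr_threshold = 0.25,
                            npv_threshold = 0.05,
                            star_levels = c(0.09, 0.05, 0.01),
                            overlap_threshold = 0.70, k_hubs = 20,
                            n_perm_de = 1000, n_perm_gsea = 500,
                            expand_neighbors = FALSE,
                            som_grid = c(3, 6), som_tol = 0.25,
                            covariate_contrast = c("M", "T0", "T2"),
                            seed = 1L) {
  thr <- c(alpha, fdr_threshold, npv_threshold, star_levels,
           overlap_threshold)
  if (any(thr <= 0 | thr >= 1 + 1e-12))
    stop("thresholds must lie in (0, 1)")
  if (n_perm_de < 10 || n_perm_gsea < 10)
    stop("permutation counts must be >= 10")
  if (k_hubs < 1) stop("k_hubs must be >= 1")
  if (is.null(sim)) {
    need <- c("gct", "design", "gmt", "sif")
    if (!all(need %in% names(paths)))
      stop("paths must name ", paste(need, collapse = ", "))
    missing <- !vapply(paths[need], file.exists, TRUE)
    if (any(missing))
      stop("input path does not exist: ",
           paste(unlist(paths[need])[missing], collapse = ", "))
  }
  structure(list(sim = sim, paths = paths, alpha = alpha,
                 fdr_threshold = fdr_threshold,
                 npv_threshold = npv_threshold, star_levels = star_levels,
                 overlap_threshold = overlap_threshold, k_hubs = k_hubs,
                 n_perm_de = n_perm_de, n_perm_gsea = n_perm_gsea,
                 expand_neighbors = expand_neighbors,
                 som_grid = as.integer(som_grid), som_tol = som_tol,
                 covariate_contrast = covariate_contrast,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Bundled small-study configuration
#'
#' A fast, fully simulated study used by the examples and the end-to-end
#' determinism checks: 500 genes, 8 subjects per group, four planted patterns
#' (Progressive I and Long-term, up and down) plus six decoy sets, with
#' reduced permutation counts.
#'
#' @param seed Base seed.
#' @return An [analysis_config()].
#' @export
bundled_fixture_config <- function(seed = 1L) {
  analysis_config(
    sim = sim_config(n_subjects_per_group = 8, n_genes = 500, n_sets = 10,
                     set_size_range = c(10, 15),
                     patterns = c("ProgressiveI_Up", "ProgressiveI_Down",
                                  "LongTerm_Up", "LongTerm_Down"),
                     seed = seed),
    n_perm_de = 200, n_perm_gsea = 100, seed = seed)
}

.stage_seed <- function(config, counter) config$seed * 1000L + counter

#' All contrast specifications of the three-group design
#'
#' Nine across-group contrasts (each group pair at each timepoint, oriented
#' more-practiced minus less-practiced) and nine within-group contrasts
#' (each timepoint pair in each group, oriented later minus earlier).
#'
#' @return Named list of [comparison_spec()] objects; across-cell names like
#'   `N1vsM@T1`, within-cell names like `T0vsT1@M`.
#' @export
contrast_roster <- function() {
  roster <- list()
  pairs <- list(N1vsN2 = c("N1", "N2"), N1vsM = c("N1", "M"),
                N2vsM = c("N2", "M"))
  for (nm in names(pairs)) for (tp in TIMEPOINTS)
    roster[[paste0(nm, "@", tp)]] <- comparison_spec("across", pairs[[nm]], tp)
  tpairs <- list(T0vsT1 = c("T0", "T1"), T0vsT2 = c("T0", "T2"),
                 T1vsT2 = c("T1", "T2"))
  for (nm in names(tpairs)) for (g in GROUPS)
    roster[[paste0(nm, "@", g)]] <- comparison_spec("within", tpairs[[nm]], g)
  roster
}

# run GSEA over the across and/or within cells of the design.
# Returns data.frames with columns set/contrast/at/es/nes/p_nom/fdr_q/...
.gsea_cell <- function(se, spec, collection, n_perm, seed, mode = "auto") {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  if (spec$kind == "across") {
    sel <- cd$group %in% spec$pair & cd$timepoint == spec$at
    phenotype <- factor(cd$group[sel], levels = rev(spec$pair))
  } else {
    sel <- cd$timepoint %in% spec$pair & cd$group == spec$at
    phenotype <- factor(cd$timepoint[sel], levels = rev(spec$pair))
  }
  paired_by <- if (spec$paired) cd$subject[sel] else NULL
  res <- permutation_significance(
    SummarizedExperiment::assay(se)[, sel, drop = FALSE], phenotype,
    collection, n_perm = n_perm, seed = seed, mode = mode,
    paired_by = paired_by)
  cmp <- sub("@.*$", "", spec$cell_name)
  res$contrast <- cmp
  res$at <- spec$at
  res
}

#' GSEA over the full contrast grid
#'
#' Runs the enrichment engine over the across-group cells (metric oriented
#' more-practiced minus less-practiced) and optionally the within-group cells
#' (later minus earlier; timepoint labels permuted within subject).
#'
#' @param se SummarizedExperiment with design columns.
#' @param collection Named list of gene sets.
#' @param n_perm Permutations per cell.
#' @param seed Base seed (each cell offsets it deterministically).
#' @param cells `"both"`, `"across"` or `"within"`.
#' @param mode Permutation mode passed through.
#' @return List with data.frames `across` and `within` (NULL when skipped).
#' @export
run_gsea_grid <- function(se, collection, n_perm = 500, seed = 1L,
                          cells = c("both", "across", "within"),
                          mode = "auto") {
  cells <- match.arg(cells)
  roster <- contrast_roster()
  res_a <- NULL; res_w <- NULL
  counter <- 0L
  for (nm in names(roster)) {
    spec <- roster[[nm]]
    counter <- counter + 1L
    if (spec$kind == "across" && cells == "within") next
    if (spec$kind == "within" && cells == "across") next
    spec$cell_name <- nm
    out <- .gsea_cell(se, spec, collection, n_perm,
                      seed = seed + counter, mode = mode)
    if (spec$kind == "across") res_a <- rbind(res_a, out)
    else res_w <- rbind(res_w, out)
  }
  list(across = res_a, within = res_w)
}

.stage <- function(name, expr, out_dir) {
  tryCatch(expr, error = function(e) {
    dir.create(file.path(out_dir, "failed"), showWarnings = FALSE)
    writeLines(conditionMessage(e), file.path(out_dir, "failed", name))
    stop("[stage:", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> differential expression (all 18 contrasts with
#' Venn overlaps) -> SOM pattern discovery with category over-representation
#' -> GSEA grid -> dot matrix, pattern calls and module merging -> pattern
#' networks with focus hubs -> covariate-correlation enrichment, writing
#' plain-TSV stage outputs and a JSON manifest into `out_dir`. Re-running
#' with the same configuration reproduces byte-identical TSVs.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("rrtempo")),
                   seed = config$seed, stages = list(),
                   thresholds = config[c("alpha", "fdr_threshold",
                                         "npv_threshold", "star_levels",
                                         "overlap_threshold", "k_hubs",
                                         "n_perm_de", "n_perm_gsea")])
  p <- function(...) file.path(out_dir, ...)

  # stage 1: inputs ----------------------------------------------------------
  inputs <- .stage("inputs", {
    if (!is.null(config$sim)) {
      sim <- simulate_expression(config$sim)
      sets <- simulate_gene_sets(config$sim, sim$truth)
      net <- simulate_network(sim$truth, seed = .stage_seed(config, 1L))
      covariate <- simulate_covariate(sim$se, sim$truth, config$sim)
      write_gct(sim$se, p("expression.gct"))
      write_design_tsv(as.data.frame(SummarizedExperiment::colData(sim$se)),
                       p("design.tsv"))
      write_gmt(sets, p("sets.gmt"))
      write_sif(net, p("network.sif"))
      write_covariate_tsv(covariate, p("covariate.tsv"))
      .write_tsv(data.frame(gene = names(sim$truth$gene_pattern),
                            pattern = unname(sim$truth$gene_pattern)),
                 p("truth_genes.tsv"))
      .write_tsv(data.frame(set = names(sim$truth$set_pattern),
                            pattern = unname(sim$truth$set_pattern)),
                 p("truth_sets.tsv"))
      list(se = sim$se, truth = sim$truth, sets = sets, net = net,
           covariate = covariate)
    } else {
      se <- attach_design(parse_gct(config$paths$gct),
                          read_design_tsv(config$paths$design))
      covariate <- if (!is.null(config$paths$covariate))
        read_covariate_tsv(config$paths$covariate) else NULL
      list(se = se, truth = NULL, sets = parse_gmt(config$paths$gmt),
           net = parse_sif(config$paths$sif), covariate = covariate)
    }
  }, out_dir)
  manifest$stages$inputs <- list(n_genes = nrow(inputs$se),
                                 n_samples = ncol(inputs$se),
                                 n_sets = length(inputs$sets))

  # stage 2: differential expression -----------------------------------------
  de <- .stage("diffexp", {
    roster <- contrast_roster()
    out <- list()
    counter <- 100L
    for (nm in names(roster)) {
      counter <- counter + 1L
      out[[nm]] <- de_analysis(inputs$se, roster[[nm]],
                               n_perm = config$n_perm_de,
                               seed = .stage_seed(config, counter))
    }
    out
  }, out_dir)
  de_long <- do.call(rbind, lapply(names(de), function(nm)
    cbind(cell = nm, de[[nm]][, c("gene", "t", "df", "p_param", "p_perm",
                                  "direction")])))
  .write_tsv(de_long, p("de_results.tsv"))
  de_genes <- lapply(de, select_de, alpha = config$alpha)
  venns <- list()
  for (tp in TIMEPOINTS)
    venns[[paste0("across@", tp)]] <-
      venn_counts(setNames(de_genes[paste0(c("N1vsN2", "N1vsM", "N2vsM"),
                                           "@", tp)],
                           c("N1vsN2", "N1vsM", "N2vsM")))
  for (g in GROUPS)
    venns[[paste0("within@", g)]] <-
      venn_counts(setNames(de_genes[paste0(c("T0vsT1", "T0vsT2", "T1vsT2"),
                                           "@", g)],
                           c("T0vsT1", "T0vsT2", "T1vsT2")))
  .write_tsv(do.call(rbind, lapply(names(venns), function(nm)
    data.frame(panel = nm, region = names(venns[[nm]]),
               count = as.integer(venns[[nm]]), stringsAsFactors = FALSE))),
    p("venn_counts.tsv"))
  manifest$stages$diffexp <- list(n_selected = vapply(de_genes, length, 0L))

  # stage 3: SOM temporal patterns -------------------------------------------
  som_out <- .stage("som", {
    seed_genes <- .id_sort(unique(unlist(de_genes)))
    if (length(seed_genes) < 2) {
      message("too few DE genes for SOM; stage skipped")
      NULL
    } else {
      grid <- config$som_grid
      while (prod(grid) > length(seed_genes))
        grid <- if (grid[1] > 1) c(grid[1] - 1, grid[2])
                else c(grid[1], grid[2] - 1)
      profiles <- condition_profiles(inputs$se, seed_genes)
      som <- train_som(profiles, grid = grid,
                       seed = .stage_seed(config, 200L))
      cats <- merge_to_categories(som, tol = config$som_tol)
      ora <- NULL
      for (cat in setdiff(unique(cats$gene_category), "Unclassified")) {
        q <- names(cats$gene_category)[cats$gene_category == cat]
        res <- ora_fisher(q, inputs$sets, rownames(inputs$se))
        ora <- rbind(ora, cbind(category = cat, res))
      }
      list(som = som, categories = cats, ora = ora)
    }
  }, out_dir)
  if (!is.null(som_out)) {
    .write_tsv(data.frame(gene = names(som_out$som$assignment),
                          node = as.integer(som_out$som$assignment),
                          category = unname(som_out$categories$gene_category)),
               p("som_assignments.tsv"))
    .write_tsv(cbind(data.frame(node = seq_len(nrow(som_out$som$prototypes)),
                                category = som_out$categories$node_category),
                     as.data.frame(som_out$som$prototypes)),
               p("som_prototypes.tsv"))
    if (!is.null(som_out$ora)) .write_tsv(som_out$ora, p("som_ora.tsv"))
    manifest$stages$som <- list(grid = som_out$som$grid,
                                n_genes = length(som_out$som$assignment))
  }

  # stage 4: GSEA grid --------------------------------------------------------
  gsea <- .stage("gsea", {
    run_gsea_grid(inputs$se, inputs$sets, n_perm = config$n_perm_gsea,
                  seed = .stage_seed(config, 300L))
  }, out_dir)
  .write_tsv(gsea$across, p("gsea_across.tsv"))
  .write_tsv(gsea$within, p("gsea_within.tsv"))
  manifest$stages$gsea <- list(n_cells = 18L)

  # stage 5: dot matrix, pattern calls, modules -------------------------------
  patt <- .stage("patterns", {
    dotmat <- build_dot_matrix(gsea$across, gsea$within,
                               fdr_threshold = config$fdr_threshold,
                               npv_threshold = config$npv_threshold,
                               star_levels = config$star_levels)
    calls <- classify_patterns(dotmat)
    enriched <- calls$set[calls$category != "Unclassified"]
    modules <- if (length(enriched)) {
      members <- lapply(setNames(enriched, enriched), function(s) {
        le <- gsea$across$leading_edge[gsea$across$set == s &
                                         gsea$across$fdr_q <
                                           config$fdr_threshold]
        genes <- unique(unlist(strsplit(le[!is.na(le)], ",")))
        if (length(genes)) genes else inputs$sets[[s]]
      })
      merge_gene_sets(members, config$overlap_threshold)
    } else NULL
    list(dotmat = dotmat, calls = calls, modules = modules)
  }, out_dir)
  .write_tsv(as.data.frame(patt$dotmat), p("dot_matrix.tsv"))
  .write_tsv(patt$calls, p("pattern_calls.tsv"))
  if (!is.null(patt$modules)) .write_tsv(patt$modules, p("modules.tsv"))
  manifest$stages$patterns <-
    list(calls = as.list(table(patt$calls$category)))

  # stage 6: pattern networks and focus hubs ----------------------------------
  hubs <- .stage("hubs", {
    cats <- setdiff(unique(patt$calls$category), "Unclassified")
    nets <- list(); rankings <- NULL
    for (cat in .id_sort(cats)) {
      sets_in <- patt$calls$set[patt$calls$category == cat]
      genes <- unique(unlist(inputs$sets[sets_in]))
      g <- tryCatch(build_pattern_network(genes, inputs$net,
                                          config$expand_neighbors),
                    error = function(e) NULL)
      if (is.null(g)) next
      nets[[cat]] <- g
      rk <- rank_top_hubs(bottleneck_scores(g), k = config$k_hubs,
                          network = g)
      rankings <- rbind(rankings, cbind(network = cat, rk))
    }
    if (length(nets) >= 2) {
      merged <- merge_networks(nets)
      rk <- rank_top_hubs(bottleneck_scores(merged), k = config$k_hubs,
                          network = merged)
      rankings <- rbind(rankings, cbind(network = "merged", rk))
    }
    rankings
  }, out_dir)
  if (!is.null(hubs)) .write_tsv(hubs, p("focus_hubs.tsv"))
  manifest$stages$hubs <-
    list(n_networks = if (is.null(hubs)) 0L
         else length(unique(hubs$network)))

  # stage 7: covariate correlation --------------------------------------------
  cov_res <- .stage("covariate", {
    if (is.null(inputs$covariate)) NULL
    else {
      cc <- config$covariate_contrast
      covariate_correlation_gsea(inputs$se, inputs$covariate,
                                 group = cc[1], from = cc[2], to = cc[3],
                                 collection = inputs$sets,
                                 n_perm = config$n_perm_gsea,
                                 seed = .stage_seed(config, 400L))
    }
  }, out_dir)
  if (!is.null(cov_res)) .write_tsv(cov_res, p("covariate_gsea.tsv"))

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  md5 <- tools::md5sum(Filter(file.exists, c(p("expression.gct"),
                                             p("sets.gmt"),
                                             p("network.sif"))))
  manifest$input_md5 <- as.list(setNames(unname(md5), basename(names(md5))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(inputs = inputs, de = de, som = som_out, gsea = gsea,
                 patterns = patt, hubs = hubs, covariate = cov_res,
                 manifest = manifest))
}
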