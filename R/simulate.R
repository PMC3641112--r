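#' Simulation configuration for the three-group, three-timepoint design
#'
#' Describes a synthetic study emulating a single-session design: paired
#' subjects measured as novices (N1) and again after short-term training (N2),
#' plus an independent long-term group (M), each at timepoints T0, T1, T2.
#' Gene sets with planted temporal patterns are embedded on top of a
#' subject-random-intercept noise model.
#'
#' The per-gene model on the log-expression scale is
#' \deqn{y_{gs} = b_g + u_{subj(s)} + \delta_{p(g)}(grp(s))\,\beta +
#'   m_{p(g)}(grp(s))\,\gamma\,t(s) + \epsilon_{gs}}
#' with \eqn{\epsilon \sim N(0,\sigma^2)}, \eqn{u \sim N(0,\tau^2)} and
#' \eqn{t \in \{0,1,2\}}. Group multipliers \eqn{\delta} by pattern:
#' Progressive I (0, 1/2, 1), Progressive II (0, 1, 1), Long-term (0, 0, 1),
#' each times the pattern's sign. The time-slope multiplier \eqn{m} is nonzero
#' only in group M: +sign for Progressive I, `longterm_slope` * sign for
#' Long-term patterns (default -1: Long-term sets drift back toward baseline
#' within the session). Progressive II sets hold their joint N2/M elevation
#' flat, since an M-only drift would separate M from N2 and contradict that
#' pattern's defining property. Null genes carry no group or time effect.
#'
#' @param n_subjects_per_group Subjects per group (N1/N2 share subjects).
#' @param n_genes Number of genes.
#' @param n_sets Total gene sets (planted patterns plus decoys).
#' @param set_size_range Length-2 integer range of set sizes.
#' @param beta Group effect size, log-expression units.
#' @param gamma Within-M time slope per timepoint step, log-expression units.
#' @param tau Subject random-intercept standard deviation.
#' @param sigma Residual standard deviation (> 0).
#' @param covariate_r Target population correlation between the simulated
#'   physiological covariate and the planted pathway score, in (-1, 1).
#' @param longterm_slope Multiplier applied to `gamma` for the within-M drift
#'   of Long-term sets.
#' @param patterns Planted pattern labels (subset of the six supported).
#' @param seed Integer seed; generators are pure functions of (config, seed).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_group = 26, n_genes = 2000,
                       n_sets = 12, set_size_range = c(15, 30),
                       beta = 1, gamma = 0.15, tau = 0.25, sigma = 0.5,
                       covariate_r = 0.6, longterm_slope = -1,
                       patterns = PATTERNS, seed = 1L) {
  stopifnot(length(n_subjects_per_group) == 1, length(n_genes) == 1,
            length(set_size_range) == 2)
  if (n_subjects_per_group < 2) stop("need at least 2 subjects per group")
  if (sigma <= 0) stop("sigma must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  if (abs(covariate_r) >= 1) stop("|covariate_r| must be < 1")
  if (any(set_size_range < 2) || any(set_size_range > n_genes))
    stop("set sizes must be >= 2 and <= n_genes")
  if (set_size_range[1] > set_size_range[2])
    stop("set_size_range must be nondecreasing")
  patterns <- match.arg(patterns, PATTERNS, several.ok = TRUE)
  if (n_sets < length(patterns))
    stop("n_sets must cover at least the planted patterns")
  # planted sets may not overlap: one gene belongs to at most one pattern
  if (length(patterns) * set_size_range[2] > n_genes)
    stop("n_genes too small for non-overlapping planted sets of this size")
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 beta = beta, gamma = gamma, tau = tau, sigma = sigma,
                 covariate_r = covariate_r, longterm_slope = longterm_slope,
                 patterns = patterns, seed = as.integer(seed)),
            class = "sim_config")
}

.pattern_sign <- function(pattern) ifelse(grepl("_Up$", pattern), 1, -1)

# group multipliers delta(pattern, group) and slope multipliers m(pattern, group)
.pattern_multipliers <- function(pattern, longterm_slope) {
  s <- .pattern_sign(pattern)
  base <- switch(sub("_(Up|Down)$", "", pattern),
                 ProgressiveI  = c(N1 = 0, N2 = 0.5, M = 1),
                 ProgressiveII = c(N1 = 0, N2 = 1, M = 1),
                 LongTerm      = c(N1 = 0, N2 = 0, M = 1),
                 c(N1 = 0, N2 = 0, M = 0))
  # Progressive II sets stay flat: an M-only drift would separate M from N2
  # over the session and contradict the pattern's defining property (M ~ N2)
  slope <- c(N1 = 0, N2 = 0,
             M = if (grepl("^ProgressiveI_", pattern)) 1
                 else if (grepl("^LongTerm", pattern)) longterm_slope
                 else 0)
  list(delta = s * base, slope = s * slope)
}

.set_name_for_pattern <- function(pattern) {
  toupper(gsub("PROGRESSIVEI_", "PROG1_",
          gsub("PROGRESSIVEII_", "PROG2_",
          gsub("_DOWN$", "_DN", toupper(pattern)))))
}

#' Simulate a planted-structure expression experiment
#'
#' Draws a log-scale expression matrix under the model described in
#' [sim_config()], together with the planted ground truth needed by recovery
#' tests. N1 and N2 reuse the same subject identifiers (the same people before
#' and after training) and share one random intercept per subject; M subjects
#' are distinct.
#'
#' @param config A [sim_config()].
#' @return A list with elements `se` (a
#'   [SummarizedExperiment::SummarizedExperiment] whose `colData` carries
#'   `subject`, `group`, `timepoint`) and `truth` (class `planted_truth`:
#'   `gene_pattern`, `set_pattern`, `planted_sets`, `hub_nodes`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects_per_group
  genes <- sprintf("G%05d", seq_len(config$n_genes))

  # planted membership: disjoint draws from the gene universe
  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  length(config$patterns), replace = TRUE)
  pool <- sample(genes)
  planted_sets <- list()
  offset <- 0
  for (i in seq_along(config$patterns)) {
    members <- .id_sort(pool[(offset + 1):(offset + sizes[i])])
    planted_sets[[.set_name_for_pattern(config$patterns[i])]] <- members
    offset <- offset + sizes[i]
  }
  gene_pattern <- setNames(rep("Null", config$n_genes), genes)
  for (i in seq_along(config$patterns))
    gene_pattern[planted_sets[[i]]] <- config$patterns[i]

  shared <- sprintf("S%02d", seq_len(n))
  msub <- sprintf("M%02d", seq_len(n))
  samples <- do.call(rbind, lapply(GROUPS, function(g) {
    subj <- if (g == "M") msub else shared
    expand.grid(subject = subj, group = g, timepoint = TIMEPOINTS,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  }))
  samples$sample_id <- paste(samples$group, samples$subject,
                             samples$timepoint, sep = "_")
  samples <- samples[, c("sample_id", "subject", "group", "timepoint")]
  tnum <- match(samples$timepoint, TIMEPOINTS) - 1

  u <- setNames(rnorm(2 * n, 0, config$tau), c(shared, msub))
  b <- rnorm(config$n_genes, mean = 7, sd = 0.5)

  # effect matrix: per (pattern, group) multipliers looked up per gene/sample
  eff <- matrix(0, config$n_genes, nrow(samples))
  for (p in config$patterns) {
    mm <- .pattern_multipliers(p, config$longterm_slope)
    rows <- which(gene_pattern == p)
    add <- config$beta * mm$delta[samples$group] +
      config$gamma * mm$slope[samples$group] * tnum
    eff[rows, ] <- matrix(add, length(rows), nrow(samples), byrow = TRUE)
  }
  y <- b + eff +
    matrix(u[samples$subject], config$n_genes, nrow(samples), byrow = TRUE) +
    matrix(rnorm(config$n_genes * nrow(samples), 0, config$sigma),
           config$n_genes, nrow(samples))
  dimnames(y) <- list(genes, samples$sample_id)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = y),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  truth <- structure(list(gene_pattern = gene_pattern,
                          set_pattern = setNames(config$patterns,
                                                 names(planted_sets)),
                          planted_sets = planted_sets,
                          hub_nodes = vapply(planted_sets, `[`, "", 1),
                          config = config),
                     class = "planted_truth")
  list(se = se, truth = truth)
}

#' Materialize the gene-set collection for a simulated experiment
#'
#' One set per planted pattern (its member genes) plus decoy sets drawn only
#' from Null genes, sized within the configured range.
#'
#' @param config The [sim_config()] used for [simulate_expression()].
#' @param truth The `planted_truth` it returned.
#' @return Named list of character vectors (a GMT-writable collection).
#' @export
simulate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "planted_truth"))
  set.seed(config$seed + 1L)
  sets <- truth$planted_sets
  n_decoy <- config$n_sets - length(sets)
  null_genes <- names(truth$gene_pattern)[truth$gene_pattern == "Null"]
  for (i in seq_len(n_decoy)) {
    size <- sample(seq(config$set_size_range[1], config$set_size_range[2]), 1)
    sets[[sprintf("DECOY%02d", i)]] <- .id_sort(sample(null_genes, size))
  }
  sets
}

#' Simulate an interaction network with planted hubs
#'
#' Builds one component per planted set: the set's hub gene wired as a star to
#' the remaining member genes (spokes), attached by a single connector edge to
#' a small random background blob. Removing the hub therefore disconnects its
#' spokes — well over a quarter of the component — which is the structure the
#' bottleneck score is designed to detect. With no planted sets a single
#' random connected background graph is returned.
#'
#' @param truth A `planted_truth` (or NULL for background only).
#' @param n_background_nodes Background nodes, split across components.
#' @param seed Integer seed.
#' @return An undirected simple [igraph::igraph] with an edge attribute
#'   `relation`.
#' @export
simulate_network <- function(truth = NULL, n_background_nodes = 60, seed = 1L) {
  set.seed(seed)
  edges <- NULL
  blob_edges <- function(nodes) {
    # random spanning tree plus a few chords: connected, simple
    if (length(nodes) < 2) return(NULL)
    perm <- sample(nodes)
    tree <- cbind(perm[-1],
                  vapply(seq_along(perm)[-1],
                         function(i) perm[sample.int(i - 1, 1)], ""))
    extra <- NULL
    if (length(nodes) > 3) {
      k <- max(1L, round(0.3 * length(nodes)))
      pick <- function() sort(sample(nodes, 2))
      extra <- t(replicate(k, pick()))
    }
    rbind(tree, extra)
  }
  planted <- if (!is.null(truth)) truth$planted_sets else list()
  if (length(planted)) {
    per <- max(3L, n_background_nodes %/% length(planted))
    for (i in seq_along(planted)) {
      members <- planted[[i]]
      hub <- members[1]
      spokes <- members[-1]
      bg <- sprintf("BG%s%02d", LETTERS[i], seq_len(per))
      edges <- rbind(edges,
                     cbind(hub, spokes),
                     blob_edges(bg),
                     cbind(hub, bg[1]))
    }
  } else {
    bg <- sprintf("BG%03d", seq_len(max(2L, n_background_nodes)))
    edges <- blob_edges(bg)
  }
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  g <- igraph::simplify(g)
  igraph::E(g)$relation <- "pp"
  g
}

#' Simulate a physiological covariate tied to a planted pathway
#'
#' One scalar per sample, constructed as `r * z + sqrt(1 - r^2) * noise` where
#' `z` is the standardized per-sample mean expression of the anchor planted
#' set, so the population correlation with the pathway score equals
#' `config$covariate_r` (an FeNO-like measurement series).
#'
#' @param se Expression from [simulate_expression()].
#' @param truth Matching `planted_truth`.
#' @param config The [sim_config()]; `covariate_r` must satisfy |r| < 1.
#' @return data.frame with columns `sample_id`, `value` and attribute
#'   `anchor_set`.
#' @export
simulate_covariate <- function(se, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "planted_truth"))
  if (abs(config$covariate_r) >= 1) stop("|covariate_r| must be < 1")
  set.seed(config$seed + 2L)
  anchor <- names(truth$planted_sets)[1]
  up <- grep("_UP$", names(truth$planted_sets), value = TRUE)
  if (length(up)) anchor <- up[1]
  score <- colMeans(SummarizedExperiment::assay(se)[truth$planted_sets[[anchor]], ,
                                                    drop = FALSE])
  z <- as.numeric(scale(score))
  r <- config$covariate_r
  value <- r * z + sqrt(1 - r^2) * rnorm(length(z))
  structure(data.frame(sample_id = colnames(se), value = value,
                       stringsAsFactors = FALSE),
            anchor_set = anchor)
}
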