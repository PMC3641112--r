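# Gene set enrichment engine: signal-to-noise or correlation ranking, the
# weighted running-sum enrichment score, and permutation significance
# (phenotype or gene-set permutation) with a pooled-NES FDR.

#' Rank genes against a two-class or continuous phenotype
#'
#' Two-class metric: `(mean1 - mean2) / (sd1 + sd2)` with class 1 the first
#' factor level and each class standard deviation floored at
#' `max(0.2 * |class mean|, 0.2 * global floor)` where the global floor is the
#' median positive class sd — the canonical signal-to-noise convention, which
#' keeps the metric finite for near-constant genes. Continuous metric: Pearson
#' correlation of each gene with the covariate (constant genes score 0).
#' Ordering is by metric descending, ties by identifier, so results are
#' reproducible.
#'
#' @param exprs Numeric genes x samples matrix (or SummarizedExperiment).
#' @param phenotype Factor/character with exactly 2 levels, or a numeric
#'   covariate of length `ncol(exprs)` (constant covariate is an error).
#' @return data.frame of class `ranked_list`: `gene`, `metric`, sorted.
#' @export
rank_genes <- function(exprs, phenotype) {
  if (methods::is(exprs, "SummarizedExperiment"))
    exprs <- SummarizedExperiment::assay(exprs)
  if (is.numeric(phenotype)) {
    if (length(phenotype) != ncol(exprs))
      stop("covariate length must match sample count")
    if (stats::sd(phenotype) == 0) stop("constant covariate")
    if (length(phenotype) < 3) stop("continuous ranking needs >= 3 samples")
    z <- phenotype - mean(phenotype)
    xc <- exprs - rowMeans(exprs)
    denom <- sqrt(rowSums(xc^2) * sum(z^2))
    metric <- as.numeric(xc %*% z) / denom
    metric[!is.finite(metric)] <- 0
  } else {
    f <- factor(phenotype)
    if (nlevels(f) != 2) stop("two-class phenotype must have 2 levels")
    i1 <- f == levels(f)[1]
    if (sum(i1) < 2 || sum(!i1) < 2) stop("each class needs >= 2 samples")
    x1 <- exprs[, i1, drop = FALSE]; x2 <- exprs[, !i1, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    s1 <- sqrt(pmax(rowSums((x1 - m1)^2) / (ncol(x1) - 1), 0))
    s2 <- sqrt(pmax(rowSums((x2 - m2)^2) / (ncol(x2) - 1), 0))
    floor_glob <- stats::median(c(s1, s2)[c(s1, s2) > 0])
    if (!length(floor_glob) || !is.finite(floor_glob)) floor_glob <- 1
    s1 <- pmax(s1, 0.2 * abs(m1), 0.2 * floor_glob)
    s2 <- pmax(s2, 0.2 * abs(m2), 0.2 * floor_glob)
    metric <- (m1 - m2) / (s1 + s2)
    metric[!is.finite(metric)] <- 0
  }
  ord <- order(-metric, rownames(exprs), method = "radix")
  structure(data.frame(gene = rownames(exprs)[ord], metric = metric[ord],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ranked_list", "data.frame"))
}

# core running-sum extremum: metric sorted descending, hit_pos = ranks of set
# members (sorted). Hit steps |metric|^p normalized by the set total; miss
# steps -1/(N - k). Returns the signed extremum, its rank, and whether it sits
# at a hit (positive side) or just before one (negative side).
.es_core <- function(metric_sorted, hit_pos, weight_p = 1) {
  N <- length(metric_sorted)
  k <- length(hit_pos)
  w <- abs(metric_sorted[hit_pos])^weight_p
  tot <- sum(w)
  hits <- if (tot > 0) cumsum(w) / tot else seq_len(k) / k
  miss_unit <- 1 / (N - k)
  at_hit <- hits - (hit_pos - seq_len(k)) * miss_unit
  before_hit <- c(0, hits[-k]) - (hit_pos - seq_len(k)) * miss_unit
  i_max <- which.max(at_hit); i_min <- which.min(before_hit)
  es_pos <- at_hit[i_max]
  es_neg <- min(before_hit[i_min], 0)
  if (es_pos >= -es_neg)
    list(es = es_pos, rank = hit_pos[i_max], hit_index = i_max, sign = 1)
  else
    list(es = es_neg, rank = hit_pos[i_min], hit_index = i_min, sign = -1)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; set members increment the running sum by
#' `|metric|^p / sum_set |metric|^p` and non-members decrement it by
#' `1/(N - N_hit)`. The enrichment score is the signed extremum; when the
#' positive and negative extrema tie in absolute value the positive one is
#' reported. The sum starts and ends at zero and the score always lies in
#' \[-1, 1\].
#'
#' @param ranked A [rank_genes()] result (or data.frame `gene`, `metric`
#'   sorted by metric descending).
#' @param set Character vector of member identifiers.
#' @param weight_p Weighting exponent (default 1).
#' @param return_running Also return the full running sum.
#' @return List: `es`, `rank` (position of the extremum), `leading_edge`, and
#'   optionally `running`.
#' @export
enrichment_score <- function(ranked, set, weight_p = 1,
                             return_running = FALSE) {
  hit <- ranked$gene %in% set
  k <- sum(hit)
  if (k < 1) stop("set has no overlap with the ranked universe")
  if (k >= nrow(ranked)) stop("set covers the whole universe")
  core <- .es_core(ranked$metric, which(hit), weight_p)
  leading <- if (core$sign > 0)
    ranked$gene[hit & seq_len(nrow(ranked)) <= core$rank]
  else ranked$gene[hit & seq_len(nrow(ranked)) >= core$rank]
  out <- list(es = core$es, rank = core$rank, leading_edge = leading)
  if (return_running) {
    N <- nrow(ranked)
    w <- abs(ranked$metric)^weight_p
    tot <- sum(w[hit])
    step <- ifelse(hit,
                   if (tot > 0) w / tot else 1 / k,
                   -1 / (N - k))
    if (tot <= 0) step[!hit] <- -1 / (N - k)
    out$running <- cumsum(step)
  }
  out
}

# permutation machinery -------------------------------------------------------

# one phenotype permutation: returns a permuted phenotype vector.
# paired_by: subject ids (two samples each) -> within-subject label swap.
.permute_phenotype <- function(phenotype, paired_by = NULL) {
  if (is.null(paired_by)) return(sample(phenotype))
  out <- phenotype
  for (s in unique(paired_by)) {
    idx <- which(paired_by == s)
    if (length(idx) == 2 && sample(c(TRUE, FALSE), 1))
      out[idx] <- out[rev(idx)]
  }
  out
}

#' Permutation significance for a gene-set collection
#'
#' Computes per-set enrichment scores, a permutation null, normalized scores
#' and a pooled false discovery rate. Phenotype mode relabels samples
#' (two-class: label shuffles, or within-subject swaps when `paired_by` is
#' given; continuous: covariate permutation) and re-ranks for every
#' permutation; gene-set mode keeps the observed ranking and draws random
#' sets of matched size. With fewer than 7 samples per class, gene-set mode is
#' auto-selected with a notice. `NES = ES / mean(same-sign permuted ES)`;
#' nominal p is the add-one same-sign tail proportion; FDR q is the ratio of
#' pooled permuted-NES to observed-NES tail proportions, clipped to \[0, 1\].
#'
#' @param exprs Genes x samples matrix or SummarizedExperiment.
#' @param phenotype Two-class factor/character or numeric covariate.
#' @param collection Named list of gene sets; sets with no overlap with the
#'   universe are dropped with a message, sets covering the whole universe are
#'   an error.
#' @param n_perm Number of permutations (>= 10).
#' @param seed Integer seed.
#' @param mode `"auto"`, `"phenotype"` or `"gene_set"`.
#' @param paired_by Optional subject ids for within-subject relabeling.
#' @param weight_p Weighting exponent for the running sum.
#' @return data.frame of class `enrichment_result`: `set`, `size`, `es`,
#'   `nes`, `p_nom`, `fdr_q`, `direction`, `leading_edge` (comma-separated).
#' @export
permutation_significance <- function(exprs, phenotype, collection,
                                     n_perm = 500, seed = 1L,
                                     mode = c("auto", "phenotype", "gene_set"),
                                     paired_by = NULL, weight_p = 1) {
  mode <- match.arg(mode)
  if (n_perm < 10) stop("n_perm must be >= 10")
  if (methods::is(exprs, "SummarizedExperiment"))
    exprs <- SummarizedExperiment::assay(exprs)
  two_class <- !is.numeric(phenotype)
  if (mode == "auto") {
    enough <- if (two_class) min(table(phenotype)) >= 7
              else length(phenotype) >= 7
    mode <- if (enough) "phenotype" else "gene_set"
    if (mode == "gene_set")
      message("fewer than 7 samples per class: gene_set permutation selected")
  }
  ranked <- rank_genes(exprs, phenotype)
  N <- nrow(ranked)
  keep <- vapply(collection, function(s) sum(ranked$gene %in% s), 0L)
  if (any(keep >= N)) stop("a set covers the whole universe")
  if (any(keep == 0)) {
    message(sum(keep == 0), " set(s) with no universe overlap dropped")
    collection <- collection[keep > 0]
    keep <- keep[keep > 0]
  }
  if (!length(collection)) stop("no testable sets")
  sets <- names(collection)
  obs <- lapply(collection, function(s) enrichment_score(ranked, s, weight_p))
  es_obs <- vapply(obs, `[[`, 0, "es")

  set.seed(seed)
  sizes <- keep
  es_perm <- matrix(NA_real_, length(sets), n_perm,
                    dimnames = list(sets, NULL))
  if (mode == "phenotype") {
    for (b in seq_len(n_perm)) {
      ph <- .permute_phenotype(phenotype, paired_by)
      rb <- rank_genes(exprs, ph)
      for (j in seq_along(sets)) {
        hp <- which(rb$gene %in% collection[[j]])
        es_perm[j, b] <- .es_core(rb$metric, hp, weight_p)$es
      }
    }
  } else {
    metric_sorted <- ranked$metric
    for (b in seq_len(n_perm)) {
      for (j in seq_along(sets)) {
        hp <- sort(sample.int(N, sizes[j]))
        es_perm[j, b] <- .es_core(metric_sorted, hp, weight_p)$es
      }
    }
  }

  nes_obs <- numeric(length(sets))
  p_nom <- numeric(length(sets))
  nes_perm <- matrix(NA_real_, length(sets), n_perm)
  for (j in seq_along(sets)) {
    ep <- es_perm[j, ]
    same <- if (es_obs[j] >= 0) ep[ep >= 0] else ep[ep < 0]
    denom <- mean(abs(same))
    if (!length(same) || !is.finite(denom) || denom == 0) {
      nes_obs[j] <- NA_real_
      p_nom[j] <- 1 / (1 + n_perm)
    } else {
      nes_obs[j] <- es_obs[j] / denom
      p_nom[j] <- (1 + sum(abs(same) >= abs(es_obs[j]))) / (1 + length(same))
    }
    pos <- ep >= 0
    mp <- mean(ep[pos]); mn <- mean(abs(ep[!pos]))
    nes_perm[j, pos] <- if (is.finite(mp) && mp > 0) ep[pos] / mp else NA
    nes_perm[j, !pos] <- if (is.finite(mn) && mn > 0) ep[!pos] / mn else NA
  }
  pool <- nes_perm[is.finite(nes_perm)]
  fdr_q <- vapply(seq_along(sets), function(j) {
    x <- nes_obs[j]
    if (!is.finite(x)) return(NA_real_)
    if (x >= 0) {
      num_all <- sum(pool >= 0)
      num <- if (num_all) sum(pool >= x) / num_all else 0
      den_all <- sum(nes_obs >= 0, na.rm = TRUE)
      den <- sum(nes_obs >= x, na.rm = TRUE) / den_all
    } else {
      num_all <- sum(pool < 0)
      num <- if (num_all) sum(pool <= x) / num_all else 0
      den_all <- sum(nes_obs < 0, na.rm = TRUE)
      den <- sum(nes_obs <= x, na.rm = TRUE) / den_all
    }
    min(1, max(0, num / max(den, .Machine$double.eps)))
  }, 0)

  structure(data.frame(
    set = sets, size = as.integer(sizes), es = es_obs, nes = nes_obs,
    p_nom = p_nom, fdr_q = fdr_q,
    direction = ifelse(es_obs >= 0, "up", "down"),
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL),
    mode = mode, n_perm = n_perm,
    class = c("enrichment_result", "data.frame"))
}

#' Covariate-correlation GSEA on within-group expression changes
#'
#' Ranks per-subject expression changes between two timepoints within one
#' group by their Pearson correlation with the corresponding covariate
#' changes, then assesses set enrichment by permuting the covariate vector.
#' Negative-score sets are negatively correlated pathways.
#'
#' @param se SummarizedExperiment with design columns.
#' @param covariate data.frame `sample_id`, `value` (e.g. FeNO measurements).
#' @param group Group whose subjects are used.
#' @param from,to The two timepoints; changes are `to` minus `from`.
#' @param collection Named list of gene sets.
#' @inheritParams permutation_significance
#' @return An `enrichment_result` data.frame (see
#'   [permutation_significance()]).
#' @export
covariate_correlation_gsea <- function(se, covariate, group,
                                       from = "T0", to = "T2",
                                       collection, n_perm = 500, seed = 1L,
                                       mode = "auto") {
  spec <- comparison_spec("within", c(from, to), group)
  arms <- .spec_arms(se, spec)
  delta <- arms$x2 - arms$x1
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  cov_val <- setNames(covariate$value, covariate$sample_id)
  sid <- function(tp, subj) cd$sample_id[cd$group == group &
                                           cd$timepoint == tp][
    match(subj, cd$subject[cd$group == group & cd$timepoint == tp])]
  # arms are aligned by subject; recover subject ids from the design
  subj <- cd$subject[match(colnames(arms$x1), cd$sample_id)]
  dcov <- cov_val[sid(to, subj)] - cov_val[sid(from, subj)]
  ok <- is.finite(dcov)
  if (sum(ok) < 3) stop("fewer than 3 subjects with complete covariate data")
  if (any(!ok)) message(sum(!ok), " subject(s) without covariate dropped")
  permutation_significance(delta[, ok, drop = FALSE], as.numeric(dcov[ok]),
                           collection, n_perm = n_perm, seed = seed,
                           mode = mode)
}
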