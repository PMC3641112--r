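# Assembly of the per-set significance dot matrix over comparisons x
# timepoints, rule-based classification into Progressive I/II and Long-term
# temporal patterns, and enrichment-map merging of sets into modules.

ACROSS_CONTRASTS <- c("N1vsN2", "N1vsM", "N2vsM")
WITHIN_CONTRASTS <- c("T0vsT1", "T0vsT2", "T1vsT2")

#' Build the significance dot matrix
#'
#' Across-group cells get a solid "dot" when the set passes the enrichment
#' criteria (FDR q below `fdr_threshold` and nominal p below
#' `npv_threshold`); within-group cells get 0-3 "stars", the number of
#' `star_levels` the nominal p-value falls below. Direction is the enrichment
#' score's sign (oriented so "up" means enrichment increases with practice,
#' or with time for within-group cells). Cells without results are recorded
#' as untested.
#'
#' @param across data.frame with columns `set`, `contrast` (one of
#'   `r paste(ACROSS_CONTRASTS, collapse = ", ")`), `at` (timepoint), `es`,
#'   `p_nom`, `fdr_q` — e.g. stacked [permutation_significance()] results.
#' @param within Optional data.frame with `set`, `contrast` (one of
#'   `r paste(WITHIN_CONTRASTS, collapse = ", ")`), `at` (group), `es`,
#'   `p_nom`.
#' @param fdr_threshold Across-group FDR dot boundary.
#' @param npv_threshold Across-group nominal-p dot boundary (set to 1 to use
#'   the FDR criterion alone).
#' @param star_levels Decreasing nominal-p star tiers for within-group cells.
#' @return Long data.frame of class `dot_matrix` (one row per set x cell):
#'   `set`, `axis`, `contrast`, `at`, `es`, `p_nom`, `fdr_q`, `dot`, `stars`,
#'   `direction`, `tested`; thresholds stored in attributes.
#' @export
build_dot_matrix <- function(across, within = NULL, fdr_threshold = 0.25,
                             npv_threshold = 0.05,
                             star_levels = c(0.09, 0.05, 0.01)) {
  check <- function(df, contrasts, ats, label) {
    need <- c("set", "contrast", "at", "es", "p_nom")
    if (!all(need %in% names(df)))
      stop(label, " results need columns ", paste(need, collapse = ", "))
    if (!all(df$contrast %in% contrasts))
      stop(label, " contrast must be one of ", paste(contrasts, collapse = ", "))
    if (!all(df$at %in% ats))
      stop(label, " 'at' must be one of ", paste(ats, collapse = ", "))
    if (anyDuplicated(df[, c("set", "contrast", "at")]))
      stop("conflicting duplicate results for one ", label, " cell")
    df
  }
  across <- check(across, ACROSS_CONTRASTS, TIMEPOINTS, "across")
  sets <- .id_sort(unique(c(across$set, within$set)))
  grid_a <- expand.grid(set = sets, contrast = ACROSS_CONTRASTS,
                        at = TIMEPOINTS, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  grid_a$axis <- "across"
  idx <- match(paste(grid_a$set, grid_a$contrast, grid_a$at),
               paste(across$set, across$contrast, across$at))
  grid_a$es <- across$es[idx]
  grid_a$p_nom <- across$p_nom[idx]
  grid_a$fdr_q <- if ("fdr_q" %in% names(across)) across$fdr_q[idx] else NA
  grid_a$tested <- !is.na(idx)
  grid_a$dot <- grid_a$tested & !is.na(grid_a$fdr_q) &
    grid_a$fdr_q < fdr_threshold & grid_a$p_nom < npv_threshold
  grid_a$stars <- NA_integer_

  grid_w <- NULL
  if (!is.null(within) && nrow(within)) {
    within <- check(within, WITHIN_CONTRASTS, GROUPS, "within")
    grid_w <- expand.grid(set = sets, contrast = WITHIN_CONTRASTS,
                          at = GROUPS, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    grid_w$axis <- "within"
    idx <- match(paste(grid_w$set, grid_w$contrast, grid_w$at),
                 paste(within$set, within$contrast, within$at))
    grid_w$es <- within$es[idx]
    grid_w$p_nom <- within$p_nom[idx]
    grid_w$fdr_q <- NA_real_
    grid_w$tested <- !is.na(idx)
    grid_w$dot <- FALSE
    grid_w$stars <- ifelse(grid_w$tested,
                           vapply(grid_w$p_nom, function(p)
                             if (is.na(p)) NA_integer_
                             else sum(p < star_levels), 0L),
                           NA_integer_)
  }
  out <- rbind(grid_a, grid_w)
  out$direction <- ifelse(out$tested, sign(out$es), NA)
  cols <- c("set", "axis", "contrast", "at", "es", "p_nom", "fdr_q",
            "dot", "stars", "direction", "tested")
  out <- out[, cols]
  structure(out, fdr_threshold = fdr_threshold,
            npv_threshold = npv_threshold, star_levels = star_levels,
            class = c("dot_matrix", "data.frame"))
}

# classify one set's across-group dot row. `row` has columns contrast, at,
# dot, direction. Rule order: Long-term before Progressive I before
# Progressive II; mixed-direction rows are Unclassified.
.classify_row <- function(row) {
  dotted <- row[row$dot %in% TRUE, , drop = FALSE]
  support <- if (nrow(dotted))
    paste(paste0(dotted$contrast, "@", dotted$at), collapse = ";") else ""
  if (!nrow(dotted))
    return(list(category = "Unclassified", direction = NA_character_,
                support = support, reason = "no significant cells"))
  dirs <- unique(dotted$direction)
  if (length(dirs) > 1)
    return(list(category = "Unclassified", direction = NA_character_,
                support = support, reason = "mixed direction"))
  s <- if (dirs > 0) "Up" else "Down"
  ntp <- function(cmp) sum(dotted$contrast == cmp)
  has <- function(cmp, tps) any(dotted$contrast == cmp & dotted$at %in% tps)
  category <- if (ntp("N1vsM") >= 2 && ntp("N2vsM") >= 2 && ntp("N1vsN2") == 0)
    paste0("LongTerm_", s)
  else if (ntp("N1vsN2") >= 1 && ntp("N1vsM") >= 1 && ntp("N2vsM") >= 1)
    paste0("ProgressiveI_", s)
  else if (ntp("N1vsN2") >= 1 && ntp("N1vsM") >= 1 &&
           !has("N2vsM", c("T0", "T1")))
    paste0("ProgressiveII_", s)
  else "Unclassified"
  list(category = category,
       direction = if (category == "Unclassified") NA_character_ else s,
       support = support,
       reason = if (category == "Unclassified") "no rule matched" else "")
}

#' Classify gene sets into temporal pattern categories
#'
#' Applies the pattern rules to each set's across-group dots, in order:
#' Long-term (M differs from both N1 and N2 at two or more timepoints, with
#' no N1-vs-N2 difference anywhere), then Progressive I (all three
#' comparisons significant somewhere — enrichment grows from N1 through N2 to
#' M), then Progressive II (N2 and M both differ from N1 but are
#' indistinguishable from each other at T0 and T1). Rows whose dots disagree
#' in direction are Unclassified, as are rows matching no rule. Within-group
#' stars do not enter the rules (a Long-term set may legitimately drift back
#' toward baseline within the session).
#'
#' @param dotmat A [build_dot_matrix()] result.
#' @return data.frame of class `pattern_calls`: `set`, `category`,
#'   `direction`, `support` (the cells that fired), `reason`.
#' @export
classify_patterns <- function(dotmat) {
  stopifnot(inherits(dotmat, "dot_matrix"))
  ac <- dotmat[dotmat$axis == "across", , drop = FALSE]
  sets <- .id_sort(unique(dotmat$set))
  rows <- lapply(sets, function(s) {
    cl <- .classify_row(ac[ac$set == s, , drop = FALSE])
    data.frame(set = s, category = cl$category, direction = cl$direction,
               support = cl$support, reason = cl$reason,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("pattern_calls", "data.frame"))
}

#' Classify a single set
#' @param dotmat A [build_dot_matrix()] result.
#' @param set Set name.
#' @return One-row data.frame as in [classify_patterns()].
#' @export
classify_pattern <- function(dotmat, set) {
  calls <- classify_patterns(dotmat)
  out <- calls[calls$set == set, , drop = FALSE]
  if (!nrow(out)) stop("unknown set '", set, "'")
  out
}

#' Merge gene sets into modules by overlap coefficient
#'
#' Two sets are neighbors when their overlap coefficient
#' `|A n B| / min(|A|, |B|)` reaches `overlap_threshold`; modules are the
#' connected components of the neighbor graph (transitive closure), labelled
#' by the largest member set (ties by name). The output is a partition of the
#' input sets.
#'
#' @param sets Named list of member-gene vectors (e.g. enriched-gene members
#'   of significant sets).
#' @param overlap_threshold Minimum overlap coefficient (default 0.70).
#' @return data.frame: `set`, `module`, `module_size`; neighbor edges in
#'   attribute `edges`.
#' @export
merge_gene_sets <- function(sets, overlap_threshold = 0.70) {
  if (!length(sets)) stop("need at least one set")
  nms <- names(sets)
  sets <- lapply(sets, unique)
  n <- length(sets)
  edges <- NULL
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ov <- length(intersect(sets[[i]], sets[[j]])) /
        min(length(sets[[i]]), length(sets[[j]]))
      if (ov >= overlap_threshold)
        edges <- rbind(edges, data.frame(a = nms[i], b = nms[j],
                                         coefficient = ov,
                                         stringsAsFactors = FALSE))
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nms)
  if (!is.null(edges))
    g <- igraph::add_edges(g, rbind(match(edges$a, nms), match(edges$b, nms)))
  comp <- igraph::components(g)$membership
  module <- vapply(seq_len(n), function(i) {
    members <- nms[comp == comp[i]]
    sizes <- vapply(sets[members], length, 0L)
    members[.id_order(-sizes, members)][1]
  }, "")
  out <- data.frame(set = nms, module = module,
                    module_size = as.integer(table(module)[module]),
                    stringsAsFactors = FALSE)
  attr(out, "edges") <- edges
  out
}
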