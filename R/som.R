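# Self-organizing-map discovery of temporal expression patterns on the nine
# (group x timepoint) condition means, with Pearson-correlation distance, and
# Fisher-exact over-representation of the resulting categories.

#' Standardized 9-condition mean profiles
#'
#' Per gene: the nine (group, timepoint) condition means, centered at the
#' gene's grand mean and scaled so the largest absolute value is 1 (the -1..+1
#' display scale of temporal pattern plots). Constant genes map to the zero
#' profile, and the profile is invariant to affine transforms of the raw gene.
#'
#' @param se SummarizedExperiment with design columns in `colData`.
#' @param genes Gene identifiers (default: all).
#' @return Numeric matrix genes x 9 with columns `N1.T0` ... `M.T2`.
#' @export
condition_profiles <- function(se, genes = rownames(se)) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  x <- SummarizedExperiment::assay(se)[genes, , drop = FALSE]
  cols <- as.vector(outer(TIMEPOINTS, GROUPS,
                          function(t, g) paste(g, t, sep = ".")))  # group-major
  prof <- matrix(NA_real_, length(genes), 9,
                 dimnames = list(genes, cols))
  for (g in GROUPS) for (tp in TIMEPOINTS) {
    sel <- cd$group == g & cd$timepoint == tp
    if (!any(sel))
      stop("condition cell ", g, "@", tp, " has no samples")
    prof[, paste(g, tp, sep = ".")] <- rowMeans(x[, sel, drop = FALSE])
  }
  prof <- prof - rowMeans(prof)
  amp <- apply(abs(prof), 1, max)
  prof[amp > 0, ] <- prof[amp > 0, , drop = FALSE] / amp[amp > 0]
  prof
}

# 1 - Pearson correlation between profile rows and prototype rows; rows with
# zero variance are at distance 1 from everything (correlation undefined).
.pearson_dist <- function(x, w) {
  zx <- x - rowMeans(x); zw <- w - rowMeans(w)
  nx <- sqrt(rowSums(zx^2)); nw <- sqrt(rowSums(zw^2))
  d <- 1 - (zx %*% t(zw)) / outer(nx, nw)
  d[!is.finite(d)] <- 1
  d
}

#' Train a batch self-organizing map with Pearson distance
#'
#' Prototypes live on a rectangular grid (default 3 x 6 = 18 nodes) and are
#' initialized by sampling input profiles. Each epoch assigns every profile to
#' its nearest prototype under `d = 1 - Pearson` and replaces every prototype
#' by the neighborhood-weighted mean of the profiles, with a Gaussian grid
#' neighborhood whose radius decays monotonically. Deterministic under a
#' fixed seed.
#'
#' @param profiles Matrix from [condition_profiles()] (rows = genes).
#' @param grid Integer length-2 grid shape (rows, cols).
#' @param seed Integer seed (controls prototype initialization).
#' @param epochs Training epochs.
#' @return List of class `som_grid`: `prototypes` (nodes x conditions),
#'   `assignment` (named node index per gene), `grid`, `coords`, `qe`
#'   (mean quantization error), `qe_init`, `node_sizes`.
#' @export
train_som <- function(profiles, grid = c(3, 6), seed = 1L, epochs = 20L) {
  stopifnot(is.matrix(profiles), length(grid) == 2)
  nodes <- prod(grid)
  if (nrow(profiles) < nodes)
    stop("need at least as many profiles (", nrow(profiles),
         ") as nodes (", nodes, ")")
  coords <- cbind(rep(seq_len(grid[1]), times = grid[2]),
                  rep(seq_len(grid[2]), each = grid[1]))
  grid_d2 <- as.matrix(stats::dist(coords))^2
  set.seed(seed)
  proto <- profiles[sample(nrow(profiles), nodes), , drop = FALSE]
  rownames(proto) <- paste0("node", seq_len(nodes))
  r0 <- max(grid) / 2
  qe_init <- NA_real_
  for (e in seq_len(epochs)) {
    d <- .pearson_dist(profiles, proto)
    bmu <- max.col(-d, ties.method = "first")
    if (e == 1) qe_init <- mean(d[cbind(seq_len(nrow(d)), bmu)])
    radius <- max(r0 * (1 - (e - 1) / epochs), 0.5)
    h <- exp(-grid_d2 / (2 * radius^2))     # nodes x nodes
    wts <- h[, bmu, drop = FALSE]           # nodes x genes
    denom <- rowSums(wts)
    upd <- (wts %*% profiles) / denom
    keep <- denom > 1e-12
    proto[keep, ] <- upd[keep, , drop = FALSE]
  }
  d <- .pearson_dist(profiles, proto)
  bmu <- max.col(-d, ties.method = "first")
  if (length(unique(bmu)) == 1 && nodes > 1)
    warning("degenerate input: all profiles mapped to a single node")
  structure(list(prototypes = proto,
                 assignment = setNames(bmu, rownames(profiles)),
                 grid = as.integer(grid), coords = coords,
                 qe = mean(d[cbind(seq_len(nrow(d)), bmu)]),
                 qe_init = qe_init,
                 node_sizes = tabulate(bmu, nodes)),
            class = "som_grid")
}

# pseudo significance dots derived from one prototype: for each timepoint and
# group pair, a "dot" fires when the prototype separation exceeds tol, with
# the separation's sign as direction (oriented toward the more-practiced
# group, matching the enrichment-based dot matrix).
.prototype_dots <- function(prototype, tol) {
  val <- function(g, tp) prototype[paste(g, tp, sep = ".")]
  pairs <- list(N1vsN2 = c("N1", "N2"), N1vsM = c("N1", "M"),
                N2vsM = c("N2", "M"))
  do.call(rbind, lapply(names(pairs), function(cmp) {
    a <- pairs[[cmp]][1]; b <- pairs[[cmp]][2]
    sep <- vapply(TIMEPOINTS, function(tp) val(b, tp) - val(a, tp), 0)
    data.frame(contrast = cmp, at = TIMEPOINTS, dot = abs(sep) > tol,
               direction = sign(sep), stringsAsFactors = FALSE)
  }))
}

#' Merge SOM nodes into temporal pattern categories
#'
#' Each node's prototype is converted into pseudo significance dots (group
#' separations above `tol` on the -1..+1 profile scale) and classified by the
#' same rule set used for enrichment dot-matrix rows ([classify_patterns()]).
#' Genes inherit their node's category; zero profiles are Unclassified. This
#' deterministic rule application replaces manual curation of the maps.
#'
#' @param som A [train_som()] result.
#' @param tol Minimum prototype separation to count as a group difference.
#' @return List: `gene_category` (named character), `node_category`
#'   (per-node character vector).
#' @export
merge_to_categories <- function(som, tol = 0.25) {
  stopifnot(inherits(som, "som_grid"))
  node_cat <- vapply(seq_len(nrow(som$prototypes)), function(j) {
    .classify_row(.prototype_dots(som$prototypes[j, ], tol))$category
  }, "")
  gene_cat <- node_cat[som$assignment]
  names(gene_cat) <- names(som$assignment)
  # zero profiles carry no pattern information
  flat <- rowSums(abs(som$prototypes[som$assignment, , drop = FALSE])) == 0
  gene_cat[flat] <- "Unclassified"
  list(gene_category = gene_cat, node_category = node_cat)
}

#' Fisher-exact over-representation of a gene list
#'
#' One-sided (over-representation) Fisher exact test of each set against the
#' query within the background universe. Sets are intersected with the
#' background before testing; zero-overlap sets report p = 1.
#'
#' @param query Gene list (must be a subset of `background`).
#' @param collection Named list of gene sets.
#' @param background Background universe (non-empty).
#' @param alpha Significance flag threshold (strict `p < alpha`).
#' @return data.frame: `set`, `overlap`, `set_size`, `odds_ratio`, `p`,
#'   `significant`.
#' @export
ora_fisher <- function(query, collection, background, alpha = 0.05) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  query <- unique(query)
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], background)
    a <- length(intersect(query, s))
    b <- length(query) - a
    cc <- length(s) - a
    d <- length(background) - a - b - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                             alternative = "greater")
    data.frame(set = nm, overlap = a, set_size = length(s),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               significant = ft$p.value < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
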