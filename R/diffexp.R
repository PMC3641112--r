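# Individual-gene differential expression: random-variance moderated t-tests
# with permutation p-values, for across-group contrasts at one timepoint and
# within-group contrasts between timepoints.

#' Define a group or timepoint contrast
#'
#' Across-group contrasts compare two groups at one timepoint; within-group
#' contrasts compare two timepoints within one group. The statistic is
#' oriented as `pair[2] minus pair[1]`. Pairing is forced by the design:
#' within-group contrasts and N1-vs-N2 (the same subjects pre/post training)
#' are paired; any contrast against M is unpaired.
#'
#' @param kind `"across"` (groups at a timepoint) or `"within"` (timepoints in
#'   a group).
#' @param pair Length-2: groups for `"across"`, timepoints for `"within"`.
#' @param at The fixed timepoint (`"across"`) or group (`"within"`).
#' @return List of class `comparison_spec` with a `paired` flag and a `label`.
#' @export
comparison_spec <- function(kind = c("across", "within"), pair, at) {
  kind <- match.arg(kind)
  stopifnot(length(pair) == 2, length(at) == 1)
  if (kind == "across") {
    if (!all(pair %in% GROUPS) || !at %in% TIMEPOINTS)
      stop("across contrast needs two groups and a timepoint")
    paired <- setequal(pair, c("N1", "N2"))
  } else {
    if (!all(pair %in% TIMEPOINTS) || !at %in% GROUPS)
      stop("within contrast needs two timepoints and a group")
    paired <- TRUE
  }
  if (pair[1] == pair[2]) stop("contrast arms must differ")
  structure(list(kind = kind, pair = pair, at = at, paired = paired,
                 label = paste0(pair[2], "-vs-", pair[1], "@", at)),
            class = "comparison_spec")
}

# Extract the two arms of a contrast. Paired arms are aligned by subject;
# subjects missing one arm are dropped with a message, and an error lists the
# orphans when fewer than two complete pairs remain.
.spec_arms <- function(se, spec) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  x <- SummarizedExperiment::assay(se)
  pick <- function(value) {
    sel <- if (spec$kind == "across")
      cd$group == value & cd$timepoint == spec$at
    else cd$timepoint == value & cd$group == spec$at
    list(x = x[, sel, drop = FALSE], subject = cd$subject[sel])
  }
  a1 <- pick(spec$pair[1]); a2 <- pick(spec$pair[2])
  if (ncol(a1$x) < 2 || ncol(a2$x) < 2)
    stop("contrast ", spec$label, ": both arms need >= 2 samples")
  if (spec$paired) {
    common <- intersect(a1$subject, a2$subject)
    orphan <- setdiff(union(a1$subject, a2$subject), common)
    if (length(common) < 2)
      stop("contrast ", spec$label, ": unmatched paired design; orphans: ",
           paste(orphan, collapse = ", "))
    if (length(orphan))
      message(length(orphan), " subject(s) missing one arm dropped")
    a1$x <- a1$x[, match(common, a1$subject), drop = FALSE]
    a2$x <- a2$x[, match(common, a2$subject), drop = FALSE]
    a1$subject <- a2$subject <- common
  }
  list(x1 = a1$x, x2 = a2$x, paired = spec$paired)
}

#' Fit random-variance model hyperparameters
#'
#' Per-gene sample variances are modeled as arising from gene-specific true
#' variances with an inverse-gamma prior: the precision `1/sigma_g^2` follows
#' Gamma(shape `a`, rate `b`), so that `s^2 * a / b ~ F(nu, 2a)` marginally.
#' `(a, b)` maximize the marginal likelihood of the observed variances; `b` is
#' on the variance scale, so rescaling the data by `c` multiplies the fitted
#' `b` by `c^2` and leaves `a` unchanged.
#'
#' @param s2 Per-gene sample variances (zeros and non-finite values are
#'   excluded from the fit; at least 50 positive values required).
#' @param nu Residual degrees of freedom of each variance.
#' @param a_max Upper cap for `a`; nearly identical variances push the fitted
#'   prior toward a point mass and `a` toward infinity.
#' @return List of class `rvm_hyperparams`: `a`, `b`, `nu`, `converged`,
#'   `loglik`.
#' @export
fit_rvm_hyperparams <- function(s2, nu, a_max = 1e6) {
  if (nu < 1) stop("nu must be >= 1")
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 50)
    stop("need >= 50 positive variances to fit the prior")
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    if (!is.finite(a) || !is.finite(b)) return(1e300)
    ll <- sum(stats::df(s2 * a / b, df1 = nu, df2 = 2 * a, log = TRUE)) +
      length(s2) * log(a / b)
    if (!is.finite(ll)) return(1e300) else -ll
  }
  m <- mean(s2)
  inits <- list(c(log(2), log(m)), c(log(10), log(9 * m)), c(0, log(m / 2)))
  best <- NULL
  for (init in inits) {
    fit <- tryCatch(stats::optim(init, nll, method = "Nelder-Mead",
                                 control = list(maxit = 2000, reltol = 1e-10)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("random-variance hyperparameter fit failed to converge")
  a <- min(exp(best$par[1]), a_max)
  b <- exp(best$par[2])
  if (a >= a_max) {
    # refit b along the capped-a ridge
    ob <- stats::optimize(function(lb) nll(c(log(a_max), lb)),
                          interval = log(m) + c(-10, 10))
    b <- exp(ob$minimum)
  }
  structure(list(a = a, b = b, nu = nu,
                 converged = best$convergence == 0, loglik = -best$value),
            class = "rvm_hyperparams")
}

# shrunken variance and augmented df under the fitted prior
.rvm_shrink <- function(s2, hp) {
  (hp$nu * s2 + 2 * hp$b) / (hp$nu + 2 * hp$a)
}

# vectorized moderated t for one contrast; X1/X2 genes x samples.
# paired: X1/X2 aligned by subject, test on differences X2 - X1.
.rvm_t <- function(x1, x2, hp, paired) {
  if (paired) {
    d <- x2 - x1
    n <- ncol(d)
    m <- rowMeans(d)
    s2 <- (rowSums(d^2) - n * m^2) / (n - 1)
    s2 <- pmax(s2, 0)
    t <- m / sqrt(.rvm_shrink(s2, hp) / n)
  } else {
    n1 <- ncol(x1); n2 <- ncol(x2)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss1 <- rowSums(x1^2) - n1 * m1^2
    ss2 <- rowSums(x2^2) - n2 * m2^2
    s2 <- pmax((ss1 + ss2) / (n1 + n2 - 2), 0)
    t <- (m2 - m1) / sqrt(.rvm_shrink(s2, hp) * (1 / n1 + 1 / n2))
  }
  t
}

.contrast_nu <- function(arms) {
  if (arms$paired) ncol(arms$x1) - 1 else ncol(arms$x1) + ncol(arms$x2) - 2
}

# raw per-gene variances entering the hyperparameter fit for this contrast
.contrast_s2 <- function(arms) {
  if (arms$paired) {
    d <- arms$x2 - arms$x1
    apply(d, 1, var)
  } else {
    n1 <- ncol(arms$x1); n2 <- ncol(arms$x2)
    (rowSums((arms$x1 - rowMeans(arms$x1))^2) +
       rowSums((arms$x2 - rowMeans(arms$x2))^2)) / (n1 + n2 - 2)
  }
}

#' Random-variance moderated t-test for one contrast
#'
#' Each gene's variance is shrunk toward the fitted prior,
#' `(nu * s^2 + 2b) / (nu + 2a)`, and the t statistic is referred to a t
#' distribution with augmented degrees of freedom `nu + 2a`. Paired contrasts
#' apply the same shrinkage to per-subject difference variances, so
#' zero-variance genes still yield finite statistics.
#'
#' @param se SummarizedExperiment with design columns in `colData`.
#' @param spec A [comparison_spec()].
#' @param hp [fit_rvm_hyperparams()] output for this contrast.
#' @return data.frame: `gene`, `t`, `df`, `p_param`, `direction`, `contrast`.
#' @export
rvm_t_test <- function(se, spec, hp) {
  stopifnot(inherits(spec, "comparison_spec"), inherits(hp, "rvm_hyperparams"))
  arms <- .spec_arms(se, spec)
  t <- .rvm_t(arms$x1, arms$x2, hp, arms$paired)
  dfp <- .contrast_nu(arms) + 2 * hp$a
  data.frame(gene = rownames(se), t = t, df = dfp,
             p_param = 2 * pt(-abs(t), df = dfp),
             direction = sign(t), contrast = spec$label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation p-values for the random-variance t-test
#'
#' Unpaired contrasts shuffle group labels across samples; paired contrasts
#' flip per-subject difference signs. When the number of distinct
#' rearrangements is at most `n_perm`, full enumeration replaces sampling and
#' the p-value is the exact proportion of rearrangements (the identity
#' included) with `|t|` at least the observed; for paired contrasts the
#' enumerated group is the `2^(n-1)` sign assignments modulo the global flip,
#' which leaves `|t|` unchanged. Sampled p-values use the add-one estimator
#' `(1 + exceedances) / (1 + n_perm)` and are never zero.
#'
#' @inheritParams rvm_t_test
#' @param n_perm Number of random permutations (>= 1).
#' @param seed Integer seed.
#' @return The [rvm_t_test()] data.frame plus `p_perm`, `n_perm_used`,
#'   `exhaustive`.
#' @export
permutation_pvalues <- function(se, spec, hp, n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  res <- rvm_t_test(se, spec, hp)
  arms <- .spec_arms(se, spec)
  abs_obs <- abs(res$t) * (1 - 1e-12)
  if (arms$paired) {
    d <- arms$x2 - arms$x1
    n <- ncol(d)
    ss <- rowSums(d^2)  # invariant under sign flips
    t_for_signs <- function(sgn_mat) {
      m <- (d %*% sgn_mat) / n
      s2 <- pmax((ss - n * m^2) / (n - 1), 0)
      m / sqrt(.rvm_shrink(s2, hp) / n)
    }
    # |t| is invariant under a global sign flip, so the effective group is
    # the 2^(n-1) sign assignments with the first subject fixed positive;
    # enumerating it gives the same p as enumerating all 2^n flips
    total <- 2^(n - 1)
    if (n <= 26 && total <= n_perm) {
      bits <- as.matrix(expand.grid(rep(list(c(1, -1)), n - 1)))
      tp <- t_for_signs(rbind(1, t(bits)))
      p <- rowMeans(abs(tp) >= abs_obs)
      exhaustive <- TRUE; used <- total
    } else {
      set.seed(seed)
      sgn <- matrix(sample(c(1, -1), n * n_perm, replace = TRUE), n, n_perm)
      tp <- t_for_signs(sgn)
      p <- (1 + rowSums(abs(tp) >= abs_obs)) / (1 + n_perm)
      exhaustive <- FALSE; used <- n_perm
    }
  } else {
    pool <- cbind(arms$x1, arms$x2)
    n1 <- ncol(arms$x1); n <- ncol(pool)
    t_for_split <- function(idx1) {
      .rvm_t(pool[, idx1, drop = FALSE], pool[, -idx1, drop = FALSE],
             hp, FALSE)
    }
    total <- choose(n, n1)
    if (total <= n_perm) {
      splits <- combn(n, n1)
      tp <- vapply(seq_len(ncol(splits)),
                   function(j) t_for_split(splits[, j]), numeric(nrow(pool)))
      p <- rowMeans(abs(tp) >= abs_obs)
      exhaustive <- TRUE; used <- total
    } else {
      set.seed(seed)
      tp <- vapply(seq_len(n_perm),
                   function(j) t_for_split(sample.int(n, n1)),
                   numeric(nrow(pool)))
      p <- (1 + rowSums(abs(tp) >= abs_obs)) / (1 + n_perm)
      exhaustive <- FALSE; used <- n_perm
    }
  }
  res$p_perm <- p
  res$n_perm_used <- used
  res$exhaustive <- exhaustive
  res
}

#' Differential expression for one contrast (fit + test + permutations)
#'
#' Fits the random-variance prior on this contrast's own residual variances
#' (zero variances excluded from the fit, included in testing) and computes
#' moderated statistics with permutation p-values.
#'
#' @inheritParams permutation_pvalues
#' @param hp Optional pre-fitted hyperparameters; fitted here when NULL.
#' @return [permutation_pvalues()] data.frame with the fitted hyperparameters
#'   in attribute `hyperparams`.
#' @export
de_analysis <- function(se, spec, n_perm = 1000, seed = 1L, hp = NULL) {
  arms <- .spec_arms(se, spec)
  if (is.null(hp))
    hp <- fit_rvm_hyperparams(.contrast_s2(arms), .contrast_nu(arms))
  out <- permutation_pvalues(se, spec, hp, n_perm = n_perm, seed = seed)
  attr(out, "hyperparams") <- hp
  out
}

#' Select differentially expressed genes
#'
#' Strict threshold on the permutation p-value (`p < alpha`), ordered by
#' decreasing `|t|` with ties broken by identifier.
#'
#' @param result A [permutation_pvalues()] / [de_analysis()] data.frame.
#' @param alpha Significance level in (0, 1].
#' @return Character vector of gene identifiers.
#' @export
select_de <- function(result, alpha = 0.01) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  hit <- result[result$p_perm < alpha, , drop = FALSE]
  hit$gene[order(-abs(hit$t), hit$gene, method = "radix")]
}

#' Venn region counts for two or three gene lists
#'
#' @param lists Named list of 2 or 3 character vectors.
#' @return Named integer vector, one entry per exact-membership region
#'   (names joined with `&`); regions sum to the union size.
#' @export
venn_counts <- function(lists) {
  if (!is.list(lists) || is.null(names(lists)) || any(!nzchar(names(lists))))
    stop("lists must be a named list")
  k <- length(lists)
  if (k < 2 || k > 3) stop("venn_counts supports 2 or 3 lists")
  lists <- lapply(lists, unique)
  universe <- unique(unlist(lists))
  if (!length(universe)) {
    nm <- unlist(lapply(seq_len(k), function(size)
      apply(combn(names(lists), size), 2, paste, collapse = "&")))
    return(setNames(integer(length(nm)), nm))
  }
  member <- vapply(lists, function(l) universe %in% l, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  out <- integer(0)
  for (size in seq_len(k)) {
    for (idx in as.list(as.data.frame(combn(k, size)))) {
      inside <- rowSums(member[, idx, drop = FALSE]) == size &
        rowSums(member) == size
      out[paste(names(lists)[idx], collapse = "&")] <- sum(inside)
    }
  }
  out
}
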