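# Toy paired/unpaired experiments built in code; oracles in helper-oracles.R.

toy_se <- function(x1, x2, at = "T1", groups = c("N1", "M")) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  subj <- c(sprintf("S%02d", seq_len(n1)),
            if (groups[2] == "M") sprintf("M%02d", seq_len(n2))
            else sprintf("S%02d", seq_len(n2)))
  make_se(cbind(x1, x2), subj, rep(groups, c(n1, n2)), at)
}

test_that("hyperparameter fit recovers the generating prior and scales", {
  set.seed(10)
  a <- 3; b <- 0.5; nu <- 4; n <- 5000
  sigma2 <- 1 / rgamma(n, shape = a, rate = b)
  s2 <- sigma2 * rchisq(n, nu) / nu
  hp <- fit_rvm_hyperparams(s2, nu)
  expect_true(hp$converged)
  expect_lt(abs(hp$a - a) / a, 0.2)
  expect_lt(abs(hp$b - b) / b, 0.2)
  # scale equivariance: data * c => s2 * c^2 => b * c^2, a unchanged
  hp4 <- fit_rvm_hyperparams(4 * s2, nu)
  expect_equal(hp4$a, hp$a, tolerance = 0.02)
  expect_equal(hp4$b, 4 * hp$b, tolerance = 0.02)
})

test_that("identical variances drive the prior to a point mass", {
  hp <- fit_rvm_hyperparams(rep(2, 200), nu = 4)
  expect_equal(hp$a, 1e6)
  # shrunken variances collapse to a common value near the prior mean
  shr <- (4 * c(0, 1, 5) + 2 * hp$b) / (4 + 2 * hp$a)
  expect_lt(diff(range(shr)) / mean(shr), 1e-3)
})

test_that("moderated t reduces to the ordinary t in the flat-prior limit", {
  set.seed(2)
  x1 <- matrix(rnorm(3 * 60), 60); x2 <- matrix(rnorm(3 * 60), 60) + 0.5
  se <- toy_se(x1, x2)
  hp <- structure(list(a = 1e-12, b = 1e-12, nu = 4, converged = TRUE),
                  class = "rvm_hyperparams")
  res <- rvm_t_test(se, comparison_spec("across", c("N1", "M"), "T1"), hp)
  classic <- vapply(seq_len(60), function(g)
    t.test(x2[g, ], x1[g, ], var.equal = TRUE)$statistic, 0)
  expect_equal(res$t, unname(classic), tolerance = 1e-9)
})

test_that("degenerate inputs give the forced statistics", {
  x <- matrix(rep(c(1, 2, 3), each = 4), 3, 4, byrow = TRUE)
  se <- toy_se(x, x)
  hp <- structure(list(a = 2, b = 0.1, nu = 6, converged = TRUE),
                  class = "rvm_hyperparams")
  res <- rvm_t_test(se, comparison_spec("across", c("N1", "M"), "T1"), hp)
  expect_true(all(res$t == 0))
  expect_true(all(res$p_param == 1))
  expect_true(all(res$direction == 0))

  # paired two-subject toy with zero difference variance: shrinkage rescues t
  x1 <- matrix(c(0, 0), 1); x2 <- matrix(c(1, 1), 1)
  sep <- make_se(cbind(x1, x2), rep(c("S01", "S02"), 2),
                 rep(c("N1", "N2"), each = 2), "T0")
  resp <- rvm_t_test(sep, comparison_spec("across", c("N1", "N2"), "T0"), hp)
  expect_true(is.finite(resp$t) && resp$t > 0)
})

test_that("exhaustive enumeration matches brute-force permutation oracles", {
  set.seed(31)
  hp <- structure(list(a = 1.5, b = 0.3, nu = 4, converged = TRUE),
                  class = "rvm_hyperparams")
  x1 <- matrix(rnorm(3 * 25), 25); x2 <- matrix(rnorm(3 * 25) + 1, 25)
  se <- toy_se(x1, x2)
  spec <- comparison_spec("across", c("N1", "M"), "T1")
  res <- permutation_pvalues(se, spec, hp, n_perm = 50, seed = 1)
  expect_true(all(res$exhaustive))
  expect_equal(res$n_perm_used[1], choose(6, 3))
  expect_equal(res$p_perm, oracle_perm_p_unpaired(x1, x2, hp$a, hp$b))
  # enumeration is independent of requested n_perm once triggered
  res2 <- permutation_pvalues(se, spec, hp, n_perm = 500, seed = 99)
  expect_identical(res$p_perm, res2$p_perm)

  # paired: the sign-flip group modulo the global flip (2^5 representatives)
  # yields exactly the p of enumerating all 2^6 flips
  hp$nu <- 5
  x1 <- matrix(rnorm(6 * 20), 20); x2 <- x1 + rnorm(6 * 20, 0.5)
  sep <- make_se(cbind(x1, x2), rep(sprintf("S%02d", 1:6), 2),
                 rep(c("N1", "N2"), each = 6), "T0")
  specp <- comparison_spec("across", c("N1", "N2"), "T0")
  resp <- permutation_pvalues(sep, specp, hp, n_perm = 100, seed = 1)
  expect_true(all(resp$exhaustive))
  expect_equal(resp$n_perm_used[1], 32)
  expect_equal(resp$p_perm, oracle_perm_p_paired(x1, x2, hp$a, hp$b))
})

test_that("sampled permutation p-values are deterministic and add-one", {
  set.seed(4)
  x1 <- matrix(rnorm(8 * 30), 30); x2 <- matrix(rnorm(8 * 30), 30)
  se <- toy_se(x1, x2)
  spec <- comparison_spec("across", c("N1", "M"), "T1")
  hp <- structure(list(a = 2, b = 0.2, nu = 14, converged = TRUE),
                  class = "rvm_hyperparams")
  r1 <- permutation_pvalues(se, spec, hp, n_perm = 99, seed = 7)
  r2 <- permutation_pvalues(se, spec, hp, n_perm = 99, seed = 7)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_false(any(r1$exhaustive))
  expect_true(all(r1$p_perm >= 1 / 100 & r1$p_perm <= 1))
  expect_error(permutation_pvalues(se, spec, hp, n_perm = 0), "n_perm")
})

test_that("rejection rate is nondecreasing in the effect size", {
  rates <- vapply(c(0, 0.6, 1.5), function(beta) {
    cfg <- sim_config(n_subjects_per_group = 8, n_genes = 300, n_sets = 6,
                      set_size_range = c(40, 50), beta = beta, gamma = 0,
                      tau = 0.2, patterns = c("LongTerm_Up", "LongTerm_Down"),
                      seed = 17)
    sim <- simulate_expression(cfg)
    de <- de_analysis(sim$se, comparison_spec("across", c("N1", "M"), "T0"),
                      n_perm = 100, seed = 3)
    planted <- names(sim$truth$gene_pattern)[sim$truth$gene_pattern != "Null"]
    mean(de$p_perm[de$gene %in% planted] < 0.05)
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.2)
  expect_gt(rates[3], 0.8)
})

test_that("shrunken variances beat raw sample variances in MSE", {
  set.seed(12)
  a <- 3; b <- 0.5; nu <- 4; n <- 5000
  sigma2 <- 1 / rgamma(n, shape = a, rate = b)
  s2 <- sigma2 * rchisq(n, nu) / nu
  hp <- fit_rvm_hyperparams(s2, nu)
  shr <- (nu * s2 + 2 * hp$b) / (nu + 2 * hp$a)
  expect_lt(mean((shr - sigma2)^2), mean((s2 - sigma2)^2))
})

test_that("DE selection uses a strict threshold and a stable order", {
  res <- data.frame(gene = c("GB", "GA", "GC"), t = c(-3, 5, 1),
                    p_perm = c(0.009, 0.010, 0.012))
  expect_equal(select_de(res, alpha = 0.01), "GB")
  expect_equal(select_de(res, alpha = 1), c("GA", "GB", "GC"))
  expect_length(select_de(res[0, ], alpha = 0.01), 0)
  # ties in |t| break by identifier
  res2 <- data.frame(gene = c("GZ", "GA"), t = c(2, -2),
                     p_perm = c(0.001, 0.001))
  expect_equal(select_de(res2, 0.05), c("GA", "GZ"))
})

test_that("paired contrasts require matchable subjects", {
  x <- matrix(rnorm(8 * 5), 5)
  se <- make_se(x, c("S01", "S02", "S03", "S04", "S05", "S06", "S07", "S08"),
                rep(c("N1", "N2"), each = 4), "T0")
  spec <- comparison_spec("across", c("N1", "N2"), "T0")
  expect_error(.spec_arms <- rrtempo:::.spec_arms(se, spec),
               "orphans.*S0", perl = TRUE)
})

test_that("venn regions match brute-force set arithmetic", {
  set.seed(5)
  for (rep in 1:10) {
    ids <- sprintf("g%02d", 1:20)
    lists <- list(A = sample(ids, sample(0:12, 1)),
                  B = sample(ids, sample(1:12, 1)),
                  C = sample(ids, sample(1:12, 1)))
    vc <- venn_counts(lists)
    expect_equal(sum(vc), length(unique(unlist(lists))))
    with(lists, {
      expect_equal(unname(vc["A"]),
                   length(setdiff(setdiff(A, B), C)))
      expect_equal(unname(vc["A&B"]),
                   length(setdiff(intersect(A, B), C)))
      expect_equal(unname(vc["A&B&C"]),
                   length(intersect(intersect(A, B), C)))
    })
  }
  expect_equal(unname(venn_counts(list(x = c("a", "b"),
                                       y = c("a", "b")))["x&y"]), 2)
  expect_equal(unname(venn_counts(list(x = "a", y = "b"))["x&y"]), 0)
  expect_error(venn_counts(list(a = "x", b = "y", c = "z", d = "w")),
               "2 or 3")
})
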