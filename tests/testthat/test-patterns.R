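# Dot-matrix assembly, temporal pattern rules, and enrichment-map merging.

across_row <- function(set, contrast, at, es = 0.5, p = 0.01, q = 0.05) {
  data.frame(set = set, contrast = contrast, at = at, es = es, p_nom = p,
             fdr_q = q, stringsAsFactors = FALSE)
}

test_that("dot and star thresholds honor the printed criteria bit-exactly", {
  across <- rbind(
    across_row("S", "N1vsM", "T0", q = 0.24),
    across_row("S", "N1vsM", "T1", q = 0.26),
    across_row("S", "N1vsM", "T2", q = 0.25))   # boundary: no dot
  within <- data.frame(
    set = "S", contrast = c("T0vsT1", "T0vsT2", "T1vsT2", "T0vsT1"),
    at = c("M", "M", "M", "N1"),
    es = c(0.4, 0.4, -0.2, 0.1),
    p_nom = c(0.04, 0.009, 0.089, 0.09))
  dm <- build_dot_matrix(across, within)
  a <- dm[dm$axis == "across" & dm$tested, ]
  expect_equal(a$dot[a$at == "T0"], TRUE)
  expect_equal(a$dot[a$at == "T1"], FALSE)
  expect_equal(a$dot[a$at == "T2"], FALSE)   # strict: q = 0.25 is not < 0.25
  w <- dm[dm$axis == "within" & dm$tested, ]
  expect_equal(w$stars[w$contrast == "T0vsT1" & w$at == "M"], 2L)
  expect_equal(w$stars[w$contrast == "T0vsT2" & w$at == "M"], 3L)
  expect_equal(w$stars[w$contrast == "T1vsT2" & w$at == "M"], 1L)
  expect_equal(w$direction[w$contrast == "T1vsT2" & w$at == "M"], -1)
  expect_equal(w$stars[w$at == "N1"], 0L)    # strict: p = 0.09 is no star
  # untested cells are recorded as untested, with neither dot nor star
  u <- dm[dm$axis == "across" & !dm$tested, ]
  expect_true(all(!u$dot))
  expect_true(all(is.na(u$es)))
  # the nominal-p criterion also gates the dot
  dm2 <- build_dot_matrix(across_row("S", "N1vsM", "T0", p = 0.2, q = 0.1))
  expect_false(any(dm2$dot))
  expect_error(build_dot_matrix(rbind(across_row("S", "N1vsM", "T0"),
                                      across_row("S", "N1vsM", "T0"))),
               "duplicate")
})

test_that("pattern rules reproduce the category definitions", {
  # progressive I: all three comparisons fire somewhere, shared direction
  pi_rows <- rbind(across_row("P1", "N1vsM", "T0"),
                   across_row("P1", "N1vsM", "T1"),
                   across_row("P1", "N1vsM", "T2"),
                   across_row("P1", "N1vsN2", "T1"),
                   across_row("P1", "N2vsM", "T1"))
  # long-term: M differs from both at >= 2 timepoints, never N1 vs N2
  lt_rows <- rbind(across_row("L1", "N1vsM", "T0"),
                   across_row("L1", "N1vsM", "T1"),
                   across_row("L1", "N1vsM", "T2"),
                   across_row("L1", "N2vsM", "T0"),
                   across_row("L1", "N2vsM", "T2"))
  # progressive II: N2 and M indistinguishable from each other
  p2_rows <- rbind(across_row("P2", "N1vsN2", "T1", es = -0.5),
                   across_row("P2", "N1vsM", "T1", es = -0.4),
                   across_row("P2", "N1vsM", "T2", es = -0.4))
  calls <- classify_patterns(build_dot_matrix(rbind(pi_rows, lt_rows,
                                                    p2_rows)))
  expect_equal(calls$category[calls$set == "P1"], "ProgressiveI_Up")
  expect_equal(calls$category[calls$set == "L1"], "LongTerm_Up")
  expect_equal(calls$category[calls$set == "P2"], "ProgressiveII_Down")
  # a Progressive II candidate with an M-vs-N2 dot at T0 fails rule 3 but,
  # having all three comparisons, is Progressive I
  p3 <- rbind(across_row("P3", "N1vsN2", "T0"),
              across_row("P3", "N1vsM", "T0"),
              across_row("P3", "N2vsM", "T0"))
  expect_equal(classify_patterns(build_dot_matrix(p3))$category,
               "ProgressiveI_Up")
})

test_that("empty and mixed-direction rows are Unclassified", {
  empty <- across_row("E", "N1vsM", "T0", q = 0.9)
  mixed <- rbind(across_row("M1", "N1vsM", "T0", es = 0.5),
                 across_row("M1", "N1vsM", "T1", es = -0.5),
                 across_row("M1", "N2vsM", "T0", es = 0.5))
  calls <- classify_patterns(build_dot_matrix(rbind(empty, mixed)))
  expect_equal(calls$category, c("Unclassified", "Unclassified"))
  expect_equal(calls$reason[calls$set == "M1"], "mixed direction")
})

test_that("every set receives exactly one category, in any order", {
  set.seed(21)
  rows <- NULL
  for (s in sprintf("R%02d", 1:12)) {
    n <- sample(0:6, 1)
    if (n > 0) {
      cells <- expand.grid(contrast = c("N1vsN2", "N1vsM", "N2vsM"),
                           at = c("T0", "T1", "T2"),
                           stringsAsFactors = FALSE)[sample(9, n), ]
      rows <- rbind(rows, data.frame(set = s, cells,
                                     es = sample(c(-0.5, 0.5), n, TRUE),
                                     p_nom = 0.01, fdr_q = 0.05))
    } else {
      rows <- rbind(rows, across_row(s, "N1vsM", "T0", q = 0.9))
    }
  }
  calls <- classify_patterns(build_dot_matrix(rows))
  expect_equal(sort(calls$set), sort(sprintf("R%02d", 1:12)))
  expect_true(all(calls$category %in%
                    c("ProgressiveI_Up", "ProgressiveI_Down",
                      "ProgressiveII_Up", "ProgressiveII_Down",
                      "LongTerm_Up", "LongTerm_Down", "Unclassified")))
  shuffled <- rows[sample(nrow(rows)), ]
  calls2 <- classify_patterns(build_dot_matrix(shuffled))
  expect_equal(calls2[order(calls2$set), ], calls[order(calls$set), ],
               ignore_attr = TRUE)
})

test_that("the 70% overlap-coefficient boundary decides merging", {
  a <- sprintf("g%02d", 1:10)
  merge7 <- merge_gene_sets(list(A = a, B = c(a[1:7], "x", "y", "z")))
  expect_equal(length(unique(merge7$module)), 1)
  merge6 <- merge_gene_sets(list(A = a, B = c(a[1:6], "w", "x", "y", "z")))
  expect_equal(length(unique(merge6$module)), 2)
  # disjoint sets stay singleton modules
  disj <- merge_gene_sets(list(A = a[1:5], B = a[6:10], C = c("q", "r")))
  expect_equal(disj$module, disj$set)
})

test_that("modules are the transitive closure and partition the input", {
  a <- sprintf("g%02d", 1:10)
  b <- c(a[1:7], "x1", "x2", "x3")          # A ~ B (7/10)
  cc <- c(a[1:2], "x1", "x2", "x3", "z1", "z2")  # B ~ C (5/7), A !~ C (2/7)
  expect_gte(length(intersect(b, cc)) / min(length(b), length(cc)), 0.7)
  expect_lt(length(intersect(a, cc)) / min(length(a), length(cc)), 0.7)
  chain <- merge_gene_sets(list(A = a, B = b, C = cc))
  expect_equal(length(unique(chain$module)), 1)
  # random collections: output is always a partition
  set.seed(9)
  for (i in 1:5) {
    sets <- lapply(setNames(1:8, sprintf("S%d", 1:8)), function(j)
      sample(sprintf("g%02d", 1:40), sample(5:15, 1)))
    mg <- merge_gene_sets(sets)
    expect_setequal(mg$set, names(sets))
    expect_equal(anyDuplicated(mg$set), 0)
    expect_true(all(mg$module %in% mg$set))
  }
})
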