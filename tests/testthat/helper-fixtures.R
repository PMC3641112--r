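# Shared fixtures built in code.

# Minimal SummarizedExperiment with the three-group design columns.
make_se <- function(values, subject, group, timepoint,
                    sample_id = paste(group, subject, timepoint, sep = "_")) {
  colnames(values) <- sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%05d", seq_len(nrow(values)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(sample_id = sample_id, subject = subject,
                                   group = group, timepoint = timepoint,
                                   row.names = sample_id))
}

# Balanced design grid for n subjects/group (N1/N2 share subjects).
design_grid <- function(n) {
  shared <- sprintf("S%02d", seq_len(n))
  msub <- sprintf("M%02d", seq_len(n))
  do.call(rbind, lapply(c("N1", "N2", "M"), function(g) {
    subj <- if (g == "M") msub else shared
    expand.grid(subject = subj, group = g, timepoint = c("T0", "T1", "T2"),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  }))
}

# Pure-noise experiment (no planted effects).
null_se <- function(n_genes, n_subjects, sigma = 0.5, tau = 0, seed = 1) {
  set.seed(seed)
  d <- design_grid(n_subjects)
  u <- stats::setNames(rnorm(2 * n_subjects, 0, tau),
                       unique(d$subject))
  y <- matrix(rnorm(n_genes * nrow(d), 0, sigma), n_genes, nrow(d)) +
    matrix(u[d$subject], n_genes, nrow(d), byrow = TRUE)
  rownames(y) <- sprintf("G%05d", seq_len(n_genes))
  make_se(y, d$subject, d$group, d$timepoint)
}

# One bundled-fixture pipeline run, cached for the whole test session.
.fixture_cache <- new.env(parent = emptyenv())
get_fixture_run <- function() {
  if (is.null(.fixture_cache$run)) {
    dir <- file.path(tempdir(), "rrtempo-fixture-run1")
    cfg <- bundled_fixture_config(seed = 11L)
    .fixture_cache$run <- suppressMessages(run_pipeline(cfg, dir))
    .fixture_cache$dir <- dir
    .fixture_cache$config <- cfg
  }
  list(run = .fixture_cache$run, dir = .fixture_cache$dir,
       config = .fixture_cache$config)
}
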