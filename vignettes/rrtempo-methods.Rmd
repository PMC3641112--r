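---
title: "Methods: temporal transcriptome patterns across practice groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal transcriptome patterns across practice groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design and the question

rrtempo analyzes a single-session, three-timepoint transcriptome experiment
across three meditation-practice groups: novices (N1), the same subjects
after eight weeks of training (N2), and an independent cohort of long-term
practitioners (M). Blood is drawn immediately before (T0), immediately after
(T1) and fifteen minutes after (T2) a 20-minute practice session. The
scientific question is which genes and pathways respond to the session, and
whether the response grows with the length of prior practice — a
"Progressive" pattern (N1 < N2 < M, in either direction) — or appears only
in long-term practitioners — a "Long-term" pattern (N1 ≈ N2, M apart).

Because N1 and N2 are the same people, every contrast touching both is
paired; contrasts against M are unpaired. Timepoints are treated as ordinal
(t = 0, 1, 2); the 15-minute spacing between T1 and T2 carries no extra
weight because every downstream operation uses only ordinal contrasts.

## The synthetic-data generator

`simulate_expression()` draws log-scale expression under

$$y_{gs} = b_g + u_{subj(s)} + \delta_{p(g)}(\mathrm{grp}(s))\,\beta +
  m_{p(g)}(\mathrm{grp}(s))\,\gamma\,t(s) + \varepsilon_{gs},$$

with gene baselines $b_g \sim N(7, 0.5^2)$, subject intercepts
$u \sim N(0, \tau^2)$ shared between a subject's N1 and N2 samples, and
residuals $\varepsilon \sim N(0, \sigma^2)$. Planted patterns set the group
multipliers $\delta$: Progressive I (0, 1/2, 1), Progressive II (0, 1, 1),
Long-term (0, 0, 1), each times the pattern's sign. The time slope acts in M
only: Progressive I drifts further in its own direction ($m = +1$), Long-term
sets drift back toward baseline ($m = -1$ by default, matching the
observation that pathways elevated only in long-term practitioners relax
over the session). Progressive II sets stay flat over time: giving them an
M-only drift would separate M from N2 within the session and contradict the
pattern's defining property (M and N2 indistinguishable), making the planted
label itself wrong.

Defaults, chosen once as the study conditions: 26 subjects per group (the
design's cohort size), $\sigma = 0.5$ and $\tau = 0.25$ log-units (noise on
the scale typical of normalized microarray data), $\beta = 1 = 2\sigma$ (a
clearly detectable but not overwhelming set-level effect), $\gamma = 0.15$
(a visible within-session drift of about a third of the group effect over
two steps), 2000 genes and 12 gene sets of 15–25 genes (six planted patterns
plus six decoys drawn from Null genes). The covariate generator emulates an
FeNO-like physiological series: per sample it mixes the standardized mean
expression of one planted pathway with independent noise so the population
correlation equals `covariate_r` (default 0.6).

What the generator does **not** emulate: probe-level artifacts,
normalization residuals, heavy-tailed or gene-correlated noise beyond the
shared subject intercept, missing samples, and pathway overlap (planted sets
are disjoint by construction). Passing recovery tests therefore demonstrate
that the pipeline's logic is correct under its own model assumptions, not
that real arrays meet those assumptions.

## Differential expression: the random-variance t-test

Per-gene variances are unstable in small groups. The moderated test places a
gamma prior on each gene's precision, $1/\sigma_g^2 \sim
\Gamma(a, \mathrm{rate} = b)$ (so $b$ has variance units and
$s^2 a/b \sim F(\nu, 2a)$ marginally), fits $(a, b)$ by maximum likelihood
on the observed variances of the contrast at hand, and shrinks

$$\tilde\sigma^2_g = \frac{\nu s_g^2 + 2b}{\nu + 2a},\qquad
  t_g = \frac{\bar d_g}{\sqrt{\tilde\sigma^2_g \cdot c}},\qquad
  \mathrm{df} = \nu + 2a,$$

with $c$ the usual $1/n_1 + 1/n_2$ (unpaired) or $1/n$ (paired differences).
Zero-variance genes are excluded from the fit but tested — shrinkage keeps
their statistics finite. Nearly identical variances push $a$ to a cap of
$10^6$, where all genes share one variance; in the opposite limit
$a, b \to 0$ the ordinary t-statistic is recovered. Hyperparameters are
fitted per contrast on that contrast's own residual variances, which is what
the random-variance model assumes.

Significance comes from permutations: label shuffles across samples
(unpaired) or per-subject sign flips of the differences (paired), with the
two-sided statistic recomputed under the fitted prior. Because $|t|$ is
invariant under a global sign flip, the paired permutation group effectively
has $2^{n-1}$ elements; whenever that count is within the permutation
budget the group is enumerated and the p-value is exact (identical to
enumerating all $2^n$ flips). Sampled p-values use the add-one estimator
$(1 + \#\{|t^\ast| \ge |t|\})/(1 + B)$ and are never zero. Selection is
strict: a gene is called at $p < 0.01$, with no multiplicity correction and
no fold-change filter at this stage.

## SOM temporal patterns

Differentially expressed genes are summarized by their nine
(group × timepoint) condition means, centered at the gene's grand mean and
scaled so the largest absolute value is one; constant genes map to the zero
profile and the summary is invariant to affine transforms of the raw gene.
A batch self-organizing map on a 3 × 6 rectangular grid (18 nodes, the
conventional map size for this design; configurable) clusters the profiles
under the distance $d = 1 - r_{\mathrm{Pearson}}$. Batch training with a
Gaussian grid neighborhood whose radius decays linearly to 0.5 makes the
result deterministic given the seed, which only controls prototype
initialization by sampling input profiles. A zero profile has undefined
correlation; its distance is defined as 1 to every prototype and such genes
end up Unclassified.

Merging the 18 maps into the four biological categories is automated rather
than curated: each node's prototype is converted into pseudo significance
dots (a group separation above `tol = 0.25` on the −1…1 profile scale counts
as a difference, a quarter of the full display range) and the same rule set
used for enrichment dot-matrix rows classifies the node; genes inherit their
node's category. Over-representation of each category in a gene-set
collection uses a one-sided Fisher exact test against the full gene
universe, flagged at p < 0.05.

## The enrichment engine

Two-class ranking uses the signal-to-noise metric
$(\mu_1 - \mu_2)/(s_1 + s_2)$ with each class standard deviation floored at
$\max(0.2\,|\mu|,\ 0.2\,s_{\mathrm{med}})$, where $s_{\mathrm{med}}$ is the
median positive class standard deviation — the canonical convention, which
keeps the metric finite for near-constant genes. Continuous phenotypes rank
genes by Pearson correlation. Ties break by identifier so rankings are
reproducible. Across-group cells orient the metric as more-practiced minus
less-practiced; within-group cells as later minus earlier, so "up" always
means enrichment growing with practice or time.

The enrichment score walks the ranked list, incrementing by
$|r_j|^p / \sum_{S} |r|^p$ at members and decrementing by $1/(N - N_H)$
elsewhere ($p = 1$); the score is the signed extremum of this running sum,
with ties in magnitude resolved toward the positive extremum. Significance
uses phenotype permutation (label shuffles; within-subject swaps for paired
cells; covariate permutation in continuous mode) when both classes have at
least 7 samples, otherwise size-matched random gene sets, a convention
recorded in the output. $\mathrm{NES} = ES / \overline{|ES^\ast|}$ over
same-sign permutations; the nominal p is the add-one same-sign tail; the FDR
q pools permuted NES over all sets and takes the ratio of permuted to
observed tail proportions, clipped to [0, 1].

## Dot matrix, pattern rules, modules

The dot matrix records, per set, the across-group cells (three comparisons ×
three timepoints) and within-group cells (three timepoint pairs × three
groups). An across cell earns a dot when the set passes the enrichment
criteria — FDR q < 0.25 **and** nominal p < 0.05. The figure convention the
dot matrix mirrors prints only the FDR rule, but the enrichment criterion
itself requires both, and the conjunction is what keeps null sets from
printing dots when they ride just below genuinely enriched sets in the
pooled-FDR ranking; setting `npv_threshold = 1` recovers the FDR-only rule.
Within cells earn 0–3 stars for nominal p below 0.09 / 0.05 / 0.01 — the
0.09 tier is honored verbatim as the lowest tier of the display convention.
All thresholds are strict inequalities.

Classification applies rules in a fixed order to each set's across-group
dots, using only cells with a shared direction (mixed-direction rows are
Unclassified — the patterns are unidirectional by definition; within-group
stars deliberately do not enter the consistency check, since a Long-term set
legitimately drifts back toward baseline within M):

1. **Long-term**: M differs from N1 and from N2 at ≥ 2 timepoints each, and
   N1 never differs from N2. Checked first so that sets without any
   N1-vs-N2 signal are never called Progressive.
2. **Progressive I**: all three comparisons fire somewhere — enrichment
   grows from N1 through N2 to M ("greater enrichment in M" is
   operationalized as a significant M-vs-N2 dot, a quantity the matrix
   already contains).
3. **Progressive II**: N2 and M both differ from N1, with no M-vs-N2 dot at
   T0 or T1 (T2 is deliberately not examined, following the pattern's
   stated definition).
4. Otherwise Unclassified.

Classified sets are merged into modules with the overlap coefficient
$|A \cap B| / \min(|A|, |B|)$ at threshold 0.70 — the coefficient, not
Jaccard, because "70% common genes" reads naturally as a fraction of the
smaller set. Modules are connected components (transitive closure), labelled
by their largest member set.

## Bottleneck focus hubs

For every root $s$ in a pattern network, the breadth-first shortest-path
tree is built with a deterministic parent rule — parent = the neighbor one
level closer with the smallest identifier — making the tree unique; without
it the bottleneck count would depend on arbitrary tree choice. A non-root
node is a bottleneck of that tree when its subtree (itself included) holds
strictly more than a quarter of the tree's nodes; BN(v) counts such trees
over all roots. Edges are unweighted and undirected (interaction sources
carry no weights; directed interactions are flattened). The top k = 20 nodes
by BN, ties by identifier, form the focus-hub signature; asking for more
hubs than nodes returns all of them. Neighbor expansion when building
pattern networks (adding reference-graph neighbors that connect ≥ 2 input
genes) is off by default and exposed as a flag.

## Numerical and engineering choices

* Permutation exceedance comparisons use a relative tolerance of $10^{-12}$
  so the identity permutation always counts itself.
* All identifier ordering uses radix (byte-wise) sorting, independent of
  locale, so ties and parent rules are fully reproducible.
* TSV outputs format numerics with `%.10g`; re-running a pipeline
  configuration reproduces byte-identical files.
* One base seed expands into per-stage seeds by a fixed counter scheme
  (stage seeds = base × 1000 + counter), so adding a stage never perturbs
  earlier stages' randomness.
* Degenerate inputs are handled explicitly: identical SOM profiles collapse
  to one node with a warning; sets covering the whole ranked universe are
  rejected (the miss denominator would vanish); constant covariates are
  errors; empty permutation budgets are errors.

## Problem sizes used by the tests

The test suite exercises the pipeline at sizes chosen to make each check
sharp but quick: calibration on 2000 independent null genes with 8 subjects
per group and 200 permutations; pattern recovery at 20 subjects per group,
1000 genes, 100 enrichment permutations, five seeds; hyperparameter recovery
on 5000 simulated variances; oracle equivalence on hundreds of small random
instances; and an end-to-end determinism check on a bundled 500-gene,
8-subject fixture with four planted patterns. The calibration runs use
independent genes (no shared subject intercept), because the binomial
reference band presumes cross-gene independence of rejections; the intercept
is a nuisance parameter there, not a planted effect.

## Known limitations

* The SOM node categorization substitutes a deterministic rule for expert
  curation of maps; it reproduces planted patterns but will not reproduce
  any particular manual curation of real data.
* Gene-set mode and phenotype mode answer slightly different null
  hypotheses; the automatic switch at 7 samples per class is a pragmatic
  convention, recorded in the result's metadata.
* The pooled FDR can exceed 1 and is clipped; with few sets it is coarse.
* Pattern classification consumes only across-group dots; within-group
  stars are reported for display and interpretation but do not influence
  category calls.
* Identifier matching across files is exact and case-sensitive; upstream
  probe-to-gene mapping is out of scope.
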