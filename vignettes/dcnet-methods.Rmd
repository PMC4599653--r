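---
title: "Disease similarity from differential coexpression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease similarity from differential coexpression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
```

## The idea

Most transcriptomic disease-similarity work compares diseases by which
genes change their *expression level*. `dcnet` compares them by which
genes change their *coexpression*: when a regulatory program is
disturbed, the correlation between a regulator and its targets decays or
reverses even if no gene shifts its mean. Two diseases that decouple the
same parts of the coexpression network are taken to share dysfunctional
regulation, which is closer to shared pathogenesis than shared symptoms
or shared risk genes.

The pipeline has five stages:

1. **Per-gene differential coexpression (dC).** For each disease dataset
   (genes × samples, labelled disease/normal), Pearson correlations are
   computed separately per condition. For gene $i$ with neighbor set of
   size $n$, let $X = (x_{i1},\dots,x_{in})$ and
   $Y = (y_{i1},\dots,y_{in})$ be its correlations to those neighbors in
   the two conditions. Then
   $$ dC_i \;=\; \sqrt{\frac{\sum_{k=1}^{n} (x_{ik}-y_{ik})^2}{n}}, $$
   the root-mean-square change of the gene's coexpression profile —
   equivalently the Euclidean distance between $X$ and $Y$ divided by
   $\sqrt n$. It lies in $[0, 2]$ and is zero iff the profiles agree.
2. **Pathway aggregation.** A pathway's dC is the unweighted mean of its
   measured members' dC values, giving one pathway-level vector per
   disease, aligned across diseases.
3. **Disease similarity.** Each disease pair is scored by the partial
   Spearman correlation of their pathway vectors, conditioning on a
   background vector (see *Covariate choice*).
4. **Significance.** Gene-to-pathway memberships are randomized while
   preserving every gene's membership count, every pathway's size, and
   the number of pathways; pathway vectors and similarities are
   recomputed per permutation. Two-sided empirical p-values on
   $|\rho|$ (with +1 smoothing) are BH-adjusted, and pairs below the
   p-threshold become signed disease–disease links (DDLs).
5. **Network statistics.** Within-network distance (WD) summarizes the
   compactness of disease categories and tissues; hypergeometric and
   Fisher tests ask whether DDLs share known disease genes and drugs;
   average-linkage clustering groups diseases; common differentially
   coexpressed genes (DCGs) and links (DCLs) expose the shared biology
   behind a subnetwork.

A differential-expression baseline replaces $dC_i$ with
$\log_2$ fold change and runs through the *identical* machinery
(`mode = "de"`), so the coexpression-vs-expression comparison is a
configuration switch, not new code.

## Key statistics in detail

### Neighbor sets

The dC definition presumes a neighbor set per gene; we qualify a pair
$(i, j)$ in one condition when $|r_{ij}|$ lies in the top $1-q$ fraction
of that condition's off-diagonal $|r|$ values, and take the union across
conditions so $X$ and $Y$ are read over one identically ordered set.
The default $q = 0.75$ (top quartile) mirrors the link-filtering
convention of the DCp/DCGL software lineage. The informative fraction of
the top quartile scales with the gene universe: at genome scale the top
quartile is dominated by genuinely coupled pairs, while in a compact
universe of a few hundred genes it admits hundreds of uninformative
neighbors per gene and dilutes the statistic. For the 400-gene synthetic
cohorts used throughout the tests we therefore set $q = 0.95$; both
values are ordinary arguments.

### DCG significance

`dcg_significance()` permutes the sample-condition labels, recomputes
both correlation matrices per permutation, and re-evaluates dC over the
*observed* neighbor sets, giving each gene a null distribution that is
conditioned on the observed link structure. The empirical p-value is
$(1 + \#\{dC^{null} \ge dC^{obs}\})/(reps+1)$; genes below
$\alpha = 0.05$ are called DCGs. Holding the neighbor sets fixed keeps
the per-gene nulls aligned with the observed statistic; re-deriving them
per permutation would mix a link-selection null into a link-change null.

### DCL classes

A gene pair is a differentially coexpressed link when at least one
condition shows a qualified correlation
($\max(|r_d|, |r_n|) \ge r_c$) and the change is large
($|r_d - r_n| \ge d_r$). Both correlations qualified with opposite signs
is a *reversal*; only the disease (normal) side qualified is a *gain*
(*loss*). The defaults $r_c = 0.6$, $d_r = 0.8$ were chosen so that the
three canonical worked examples of correlation change — $0.63$ to
$-0.86$ (reversal), $-0.69$ to $0.05$ (loss), and sub-threshold pairs —
classify as described. When $d_r < $ the qualification gap both sides
can qualify with the same sign; such pairs are labelled by whichever
condition is stronger.

### Covariate choice

The partial correlation exists to factor out similarity that every pair
of expression experiments shares (platform, tissue background, global
dC level). Which background vector the original analysis conditioned on
is not recoverable, so it is an explicit option recorded in all outputs:

* `loo-mean` (default): the element-wise mean pathway vector over all
  *other* diseases — a pair-specific background that cannot leak the
  pair's own signal;
* `global-mean`: one shared background;
* `none`: plain Spearman.

### The membership-permutation null

Checkerboard (2×2) swaps on the bipartite gene–pathway incidence
structure preserve both margin sequences exactly: two membership edges
$(g_1, p_1), (g_2, p_2)$ are rewired to $(g_1, p_2), (g_2, p_1)$ when
neither cross-membership exists. The chain is run for 10× the number of
memberships (attempted swaps) per draw; on small structures the sampler
provably reaches every margin-feasible matrix, which the test suite
verifies against exhaustive enumeration on a 4-gene × 3-pathway toy.

This null holds each disease's *gene-level* dC profile fixed and asks
whether the actual pathway grouping concentrates cross-disease agreement
better than arbitrary groupings with the same shape. It is deliberately
conservative: any similarity component expressible at the gene level
survives the permutation and is absorbed into the null.

### Within-network distance

For a disease subset $c$,
$$ WD_c = \frac{\sum_{\{i,j\} \subset c} d(i,j)}{k}, $$
where $d(i,j)$ is the unweighted shortest-path length in the *full*
network over all unordered member pairs and $k$ is the number of links
with both endpoints in $c$. The unordered-pair convention makes
$WD = 1$ for a complete graph exactly; the ordered-pair alternative
gives 2 and was rejected on that ground. Member pairs disconnected in
the full network yield an infinite, flagged WD rather than an arbitrary
penalty. In the tissue permutation test, permuted tissue assignments
with no internal link also score an infinite WD; before the one-sided
Wilcoxon signed-rank test these are mapped to a finite value above the
largest finite WD, which leaves the rank-based p-value unchanged. Both
the Wilcoxon p and the plain empirical fraction are reported, because a
signed-rank test against the observed value and a plain exceedance
fraction answer subtly different questions.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code: it defines the study
conditions under which every downstream claim is checked.

**Expression model.** Each pathway's *home* members load on one shared
latent factor; with loading $a$ and noise $\sigma$ chosen so the
pairwise correlation is `base_correlation` ($a^2/(a^2+\sigma^2)$,
default 0.7). In a disease's dysregulated pathways the shared signal is
partially replaced by private noise of equal variance, so member
correlations fall toward zero while per-gene means and variances are
untouched — differential coexpression with no differential expression,
which the tests confirm via two-sample t-statistics.

**Pathway collection.** A balanced home partition covers the entire
gene universe; each pathway is then topped up with guest genes to a size
drawn from `pathway_size_range`, so a tunable fraction of genes belongs
to several pathways and the membership permutation is non-trivial. The
home pathway carries the gene's factor and is the unit of decoupling.
Full coverage matters: genes outside any coexpression block would form a
large disease-independent dC tier whose scattering under membership
permutation inflates the null and removes all power — an analysis
artifact, not biology.

**Heterogeneity.** Three layers make the planted signal detectable by a
null that preserves gene-level structure, and all three correspond to
familiar features of real cohorts: (1) each dysregulated pathway has its
own perturbation depth, uniform on $[0.3, 1]$ and scaled by
`decoupling_strength`, with core pathways sharing identity *and* depth
within a disease group — diseases perturb pathways to varying, partly
reproducible degrees; (2) within a perturbed pathway each gene responds
with its own depth (uniform $[0.5, 1]$ of the pathway depth) — member
genes are not interchangeable; (3) every gene's factor loading is
jittered per condition (`loading_jitter_sd`) — coupling strength is
gene- and sample-set-specific. Without gene-level idiosyncrasy the
membership permutation preserves essentially all cross-disease
agreement and the observed similarity cannot exceed its own null.

**Associations and groups.** Disease groups share a core of
dysregulated pathways (fraction `within_group_overlap`) and a core of
associated genes/drugs, so similarity inference, sharing enrichment and
compactness statistics all have recoverable ground truth.

**What is *not* emulated.** Probe-level effects, intensity-dependent
noise, saturation, batch structure, heavy-tailed expression, correlated
pathway overlap (real collections are nested), and diseases with
differential expression. Passing tests therefore demonstrate internal
correctness and statistical calibration under a block-factor world, not
performance on arrays; the DE baseline comparison in particular shows
only that logFC carries no signal *when none is planted*, by
construction.

## Numerical and procedural choices

* Empirical p-values use +1 smoothing, so $p \in [1/(reps+1), 1]$ and
  $p = 0$ never occurs; 500 permutations is the conventional depth,
  100 the floor (below it a `force` flag is required).
* FDR is Benjamini–Hochberg (`stats::p.adjust`), cross-checked in the
  tests against an independent step-up implementation; the network's FDR
  summary is the largest q among included edges.
* Zero-variance genes get correlation 0 to all others, a warning, and
  exclusion from DCG calls — shapes stay stable, nothing is silently
  dropped.
* Merging datasets of one disease takes the gene-vocabulary
  intersection, prefixes sample ids by source, and applies no batch
  correction (a warning notes multi-source merges); diseases assayed in
  several tissues are split into "disease - tissue" nodes.
* All pair orderings are lexicographic; clustering sorts diseases by
  label before `hclust`, so ties break deterministically.
* One master seed drives named substreams per stage and per disease, so
  any single disease is reproducible independently of cohort size.

## Problem sizes

The test and acceptance computations use cohorts of 8 diseases in 2
groups over 400 genes and 40 pathways (sizes 8–15), 50 samples per
condition, 16 dysregulated pathways per disease at overlap 0.8, with
100-permutation nulls; calibration pools 8 such cohorts (224 disease
pairs) and recovery checks 20 seeds. These sizes give stable statistics
while keeping the whole suite near a minute of compute.

## Known limitations

* The membership-permutation null is conservative whenever differential
  coexpression is coherent at the gene level across diseases; absolute
  link counts are therefore modest in the synthetic cohorts, and the
  DCE-vs-DE comparison is aggregated over several cohorts.
* Analytical p-values for partial correlations are out of scope; all
  inference is permutation-based.
* `log_fold_change()` assumes linear-scale, strictly positive
  intensities; log-scale input must be exponentiated first.
* WD is undefined (error) for a subset with no internal link, and
  infinite across components; downstream summaries must handle the flag.
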