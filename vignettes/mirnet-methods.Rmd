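---
title: "Methods: integrated miRNA-mRNA analysis with mirnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA-mRNA analysis with mirnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnet)
```

mirnet chains five analyses that together turn matched miRNA and mRNA
count matrices into an inverse-correlation regulatory network:
normalization, exact-test differential expression, cross-cell-type
specificity, hypergeometric enrichment, and seed-match network
construction. This vignette explains the statistical model behind each
stage, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical and design choices
that were genuinely open.

## Count model and differential expression

Counts are modelled feature-wise as negative binomial with mean $\mu$
and dispersion $\varphi$, $\mathrm{Var} = \mu + \varphi\mu^2$; the
$\varphi = 0$ boundary is treated exactly as Poisson. This is the
standard model for RNA-seq with biological replicates, where technical
(Poisson) noise is inflated by between-replicate variability.

**Normalization.** Small-RNA abundances are expressed as TPM,
$\mathrm{counts}/\mathrm{clean\ total} \times 10^6$, where the clean
total is the post-cleaning sequencing depth (at least the mapped sum,
so column sums never exceed $10^6$). For testing, between-library
scaling uses the trimmed mean of M-values: the reference sample is the
one whose 75th-percentile count rate is closest to the cross-sample
mean; each factor is a precision-weighted mean of per-feature log2
rate ratios after trimming the most extreme 30% of M-values and 5% of
A-values on each side, rescaled to unit geometric mean. The test
suite verifies exact agreement with the reference implementation in
edgeR on random matrices. Effective library size = raw library size
$\times$ TMM factor; counts are then placed on the geometric-mean
common scale before group comparison.

**Dispersion.** A single common $\varphi$ is estimated by pooled
method of moments on the common-scale counts: with per-feature
within-group mean $m$ and variance $v$,
$\hat\varphi = \max\!\left(0, \sum (v - m) \big/ \sum m^2\right)$
summed over all replicated groups. At 2000 features this recovers a
true $\varphi = 0.1$ to well within a factor of two and estimates
$\hat\varphi < 0.02$ on Poisson data; tagwise or trended dispersion
(shrinkage across features) is deliberately out of scope, which makes
the estimator simple, transparent, and adequate for common-dispersion
simulations, at the cost of robustness to dispersion heterogeneity in
real data.

**Exact test.** Each feature's group totals $(a, b)$ are tested
conditional on $t = a + b$. A pooled total of $n$ i.i.d.
NB$(\mu, \varphi)$ replicates is NB$(n\mu, \varphi/n)$, so under the
null the split probability is
$$P(A = j \mid t) \propto f_{NB}(j;\ t p,\ n_a/\varphi)\ %
  f_{NB}(t - j;\ t(1-p),\ n_b/\varphi),$$
with $p$ the group share of effective library size (after common
scaling, simply $n_a / (n_a + n_b)$) and $f_{NB}(\cdot;\mu,r)$ the NB
pmf with size $r$. The two-sided p-value sums the probabilities of all
splits no more probable than the observed one (minimum-likelihood
two-siding, ties included, capped at 1); $t = 0$ returns $p = 1$ with
a flag. At $\varphi = 0$ the conditional law is exactly
Binomial$(t, p)$, which the tests exploit as an independent
enumeration oracle. The per-group size parameter $n_g/\varphi$ matters:
treating a 3-replicate pooled total as a single NB draw would
overstate its dispersion threefold and make the test badly
conservative; with it, the null fraction of raw $p < 0.05$ at
$\varphi = 0.1$, $n = 3$ vs 3 sits near 0.05 (the suite asserts
[0.03, 0.07] on 2000 features).

**Classification.** Fold changes are ratios of group means of
normalized counts with a pseudocount of 0.5 added to each mean — small
enough not to bias moderate folds, while keeping folds finite when one
group is all-zero (published miRNA tables contain fold changes in the
hundreds, which implies such zero-handling; the original rule is
unstated, so the pseudocount is this package's choice and is
configurable). Thresholds are inclusive — up means fold $\ge 2$ and
FDR $\le \alpha$, down means fold $\le 0.5$ — matching published
tables in which a printed fold of exactly 0.50 is labelled
down-regulated. The significance filter applies to the BH-adjusted
p-value by default ($\alpha = 0.01$ for miRNA, 0.05 for mRNA
contrasts) and can be switched to raw p, since study descriptions mix
both conventions.

## Specificity analysis

Cross-platform panels are joined by exact feature id (an optional
alias table handles annotation-release renames; features missing from
a platform are dropped, not imputed) and quantile normalized: each
column's values are replaced by the across-column means of the order
statistics, ties receiving the mean of the quantile means their
positions span. On tie-free data this is idempotent and makes sorted
columns identical; with ties (integer counts) idempotence is only
approximate — a property of tie-averaged quantile normalization in
general, not of this implementation (it agrees exactly with limma's
`normalizeQuantiles` where defined).

Clustering is agglomerative average linkage on Euclidean or
correlation distance, with optional per-feature median centering, the
combination conventional for expression heatmaps. Average linkage is
monotone, so dendrograms have no height inversions; trees export as
Newick.

Rank-abundance profiles rank features by their share of a sample's
total abundance. Shares are computed on each sample's own scale, not
after quantile normalization — QN equalizes column distributions and
would make every share profile identical by construction, while leaving
within-column ranks untouched. All ties break lexicographically by
feature id so every output is deterministic. "Similar rank place"
across cell types is |rank difference| ≤ R with R = 10 by default; the
notion is inherently fuzzy in the source material and R is exposed as
configuration rather than claimed as canonical. The condition-specific
set removes features that overlap directionally with any comparison
contrast and, optionally, features rank-similar in at least
`min_similar` other cell types. The published count of 194 specific
miRNAs is not reproducible without the original GEO panels, and the
package does not claim it.

## Enrichment and ontology tree

Over-representation uses the right-tail hypergeometric probability
$P[X \ge k]$ computed in log space (`phyper(..., log.p = TRUE)`), with
the universe defined as all features tested for DE — the standard
choice when the assayed background is known. Terms with fewer than 2
universe genes are skipped (configurable). Up- and down-regulated
query sets are corrected separately by BH, as the two analyses are
reported separately; significance is strict (`fdr < alpha`,
$\alpha = 0.05$). Pathway collections are just another GMT — no
separate code path. The ontology tree is the subgraph induced by
enriched terms plus all ancestors, labelled up / down / ambiguous /
ancestor-only; ancestry-aware p-value corrections (elim/weight) are
out of scope.

## Seed-match network

The seed is mature-miRNA positions 2–8. With $m_7$ the reverse
complement of the seed and $m_6$ that of positions 2–7, a 7mer-m8 site
is an occurrence of $m_7$ in the UTR (sense strand, 5'→3'), an 8mer is
$m_7$ followed by A, and a 7mer-A1 is $m_6$ followed by A. Matches are
found with overlap-aware fixed-string scanning; overlapping
classifications collapse to the strongest type (8mer > 7mer-m8 >
7mer-A1), so the $m_7$ and $m_6$A matches inside an 8mer are not
double-reported. 6mer sites are excluded by default as weak.
Coordinates are 0-based half-open on the supplied UTR; strand handling
is out of scope (UTRs are supplied sense-strand). Context scoring
(conservation, AU content, 3' pairing) is deliberately not
implemented: the network stage needs canonical site presence, not
affinity ranking.

"Inversely correlated" is operationalized as *opposite DE status*, not
a per-sample correlation coefficient: with three replicates per group a
sample-level correlation is far too unstable to filter on, and the
published usage (up-miRNA networks listing down-genes) is exactly the
status rule. The abundance floor drops a miRNA only when its group-mean
normalized abundance is below 100 in *both* groups (strict reading:
means of 100 and 99 pass). Core miRNAs are the top 15 by fold change
per direction (ties by smaller p, then id); the figure legends of the
source study show 14, the text says 15 — the count is a parameter, 15
by default. Every built network is audited: bipartiteness, inverse
directions, abundance, and (when sequences are available) a fresh seed
re-scan per edge.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure* the analysis
assumes, at sizes chosen for fast, well-powered tests:

* `simulate_counts` — NB counts at a constant baseline mean (default
  200, a comfortably quantified feature; dispersion 0.1, typical for
  replicated bulk data; n = 3 per group, the study design) with a
  planted fraction (default 10%) of 4-fold changes, alternating
  up/down. Each planted DE gene is paired round-robin with a planted
  DE miRNA of opposite direction; these pairs are the network truth.
* `simulate_sequences` — 22-nt random RNA miRNAs whose seeds are
  sampled so that no miRNA's match patterns occur inside another's
  8mer site string; planted sites of exactly the requested type are
  embedded in target UTRs, and *all* other UTR sequence is made
  canonical-site-free by mutating incidental matches and re-scanning
  until clean. Site absence is therefore guaranteed, not merely
  improbable, so target-prediction precision/recall on synthetic data
  is exact. (Guaranteed absence is achieved by targeted repair rather
  than whole-sequence resampling, which with hundreds of patterns
  would discard almost every candidate UTR; the resulting guarantee is
  identical.)
* `simulate_celltype_panel` — each cell type has a fixed log-normal
  abundance profile tied to its index (so rankings are stable across
  simulation seeds), and platforms apply the monotone distortion
  $x \mapsto s\,x^{e}$ with $s = (1+\delta)^{p-1}$,
  $e = 1 + 0.5\,\delta\,(p-1)$ — raw values shift across platforms
  while within-sample ranks are untouched, reproducing
  cluster-by-platform behaviour in a rank-testable way.
* `simulate_ontology` — a single-rooted random DAG (1–2 parents per
  term) with every term directly annotated and annotations propagated
  to ancestors; an optional `concentrate` argument places a gene group
  on one term to plant a truly enriched function.

Real data differ in ways the generators do not emulate: feature-wise
mean and dispersion heterogeneity, library-size imbalance,
zero-inflation of lowly expressed miRNAs, multi-site/multi-isoform
UTRs, correlated gene sets, and platform effects richer than a
monotone transform. Passing the synthetic suite therefore demonstrates
correctness of the computations and calibration under the model's own
assumptions, not robustness to real-data pathology. No library-size or
dispersion estimates were available from the source study; the
defaults are chosen for testability, not fidelity to any particular
accession.

## Numerical choices and degenerate inputs

* Exact-test tie comparison uses a relative tolerance of 1e-10 when
  collecting splits "at most as probable" as the observed one, so
  symmetric distributions sum both tails exactly.
* Normalizing the conditional NB law is done by log-sum-exp;
  hypergeometric tails come from the log-space distribution function.
* BH adjustment delegates to `stats::p.adjust` after range
  validation.
* A zero conditional total flags and returns $p = 1$; all-zero columns
  are rejected by rank-profile and chromosome-distribution functions;
  a sample sharing no expressed features with the TMM reference is a
  hard error rather than a silent factor of 1.
* Determinism everywhere: generator outputs are pure functions of
  their seed; analysis stages contain no randomness; ties in ranking
  and core selection break by p-value then id.

## Problem sizes

The shipped analysis scripts and the acceptance checks run the study
at 150–2000 miRNAs, 300–400 genes, 200–300 nt UTRs and 3 replicates
per group; these sizes give the power the recovery checks assert
(directional power ≥ 0.8 at 4-fold, mean 200, $\varphi = 0.1$) while
keeping any single stage under a couple of minutes. Scaling the
configuration up changes nothing structurally — the exact test
enumerates $t+1$ splits per feature, so cost grows linearly in total
counts.
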