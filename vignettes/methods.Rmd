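---
title: "Methods: network-based meta-analysis of multi-study expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based meta-analysis of multi-study expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamodule)
```

This vignette explains the statistical machinery of `metamodule`, the
assumptions behind each stage, the defaults and why they were chosen, and
what the synthetic-data generator does and does not emulate.

## The pipeline at a glance

Given k gene × sample log2 expression matrices with two-group labels
(referred to as "high" and "low" throughout), an undirected interaction
network over the same gene identifiers, and optional gene sets and SNP
tables, the pipeline runs:

1. probe → gene collapse and sample outlier screening (`collapse_probes()`,
   `screen_outliers()`);
2. per-study SAM scores with permutation p-values (`sam_permutation_p()`);
3. gene-level meta-analysis: Fisher combination plus heterogeneity-gated
   effect-size pooling (`meta_deg()`);
4. beta-uniform mixture scoring of the combined p-values and
   maximum-scoring connected subnetwork extraction, repeated over
   resampled data to form a consensus module (`consensus_module()`);
5. enrichment, candidate selection and gene-level GWAS lookup.

All randomness (simulation, permutations, resampling) is drawn from
explicit integer seeds; every function restores the caller's RNG state, so
identical inputs and seeds give bit-identical outputs.

## Preprocessing

Matrices are assumed already normalized on the log2 scale; normalization
itself is out of scope. When several probes map to one gene symbol, the
probe with the largest interquartile range across all samples represents
the gene — a probe that varies is more informative than the average of
probes that may include dead ones. The IQR uses type-7
(linear-interpolation) quantiles, the most common convention; fixing the
estimator matters because equal-IQR ties are resolved toward the
lexicographically smaller probe ID to keep the collapse reproducible.

Outlier screening projects samples on the first two principal components
and removes samples farther than `z_cut` robust-z units (median/MAD per
component) from the center. The default `z_cut = 5` is deliberately
conservative: at microarray sample sizes a removed sample costs real
power, so only gross outliers should go. Classical references for this
step describe "hierarchical clustering and PCA" without a quantitative
rule; a robust-z rule on the PCA plane was chosen here because it is
parameter-explicit, idempotent, and testable, with hierarchical displays
left to generic tooling. A removal that would leave a group with fewer
than two samples is vetoed and the sample only flagged, since every
downstream variance needs two samples per group.

## Per-study differential expression

The SAM relative difference for gene g is

$$d_g = \frac{\bar x_{high,g} - \bar x_{low,g}}{s_g + s_0},$$

with $s_g$ the pooled standard error of the mean difference (the
equal-variance two-sample t denominator; `s0 = 0` makes $d_g$ exactly the
t statistic). The fudge constant $s_0$ damps the scores of low-variance
genes whose t statistics explode. Default `s0 = "auto"` takes the 5th
percentile of the gene-wise standard errors — a simple, widely used
surrogate for the full coefficient-of-variation tuning, which the original
SAM literature leaves as one of several options; any non-negative value
can be supplied instead.

Significance uses label permutations with a **pooled null**: all
`n_perm × n_genes` permuted scores form one empirical null, and

$$p_g = \frac{1 + \#\{|d^*| \ge |d_g|\}}{1 + n_{perm} \cdot n_{genes}}.$$

Pooling is what lets 200–1000 permutations resolve p-values of 10⁻⁵ and
below, which the downstream log-combination needs; the cost is the
assumption that gene null distributions are exchangeable after the $s_0$
stabilization, standard SAM practice. The plus-one smoothing keeps p
strictly positive so `log(p)` is always defined.

## Gene-level meta-analysis

Two complementary combinations run on the cross-study common gene universe
(the intersection of post-collapse gene sets):

**Fisher's method.** $\chi^2 = -2\sum_{i=1}^k \ln p_i$ is referred to the
upper tail of $\chi^2_{2k}$. It is sensitive to a strong signal in any
subset of studies and is the input to module scoring.

**Effect sizes.** Per study, the standardized mean difference is Cohen's d
with Hedges' correction $J = 1 - 3/(4m - 1)$, $m = n_1 + n_2 - 2$, and
variance $J^2\left(\frac{n_1+n_2}{n_1 n_2} + \frac{d^2}{2m}\right)$. The
correction is on by default because group sizes of 9–45, typical of the
designs this package targets, leave a material small-sample bias;
`hedges = FALSE` disables it. Heterogeneity is measured by Cochran's Q and
$I^2 = \max(0, (Q - (k-1))/Q)\cdot 100$. A gene is pooled under
random effects iff the Q test is significant at 0.05 or $I^2 > 50\%$,
otherwise fixed effects — a hard gate chosen for transparency over
always-random pooling. The random-effects between-study variance is the
DerSimonian–Laird moment estimator, the standard closed-form choice; the
tests cross-check it against an independent meta-analysis implementation.
The effect-size p-value defaults to the two-sided normal tail of
$z = \hat\mu/\widehat{se}$; `es_p_method = "permutation"` instead pools
null z statistics over label permutations and all genes, for users who
prefer a permutation reference for both meta-analyses. The asymptotic
default was chosen because at k ≥ 4 studies the normal approximation for
the pooled z is accurate and orders of magnitude cheaper. Both p-value
families receive Benjamini–Hochberg adjustment.

## From p-values to modules

The Fisher combined p-values are modeled as a beta-uniform mixture,
density $f(p) = \lambda + (1-\lambda)\,a\,p^{a-1}$ with
$\lambda, a \in (0,1)$ — uniform noise plus a decreasing beta signal
component. The fit maximizes the log-likelihood with bounded L-BFGS-B from
a 4 × 4 grid of starts (the surface can be flat in $\lambda$ when the
signal is weak; multi-start makes the fit reproducible). With
$\pi = \lambda + (1-\lambda)a$ (the mixture's noise upper bound), the FDR
threshold and node scores are

$$\tau(\mathrm{fdr}) = \left(\frac{\pi - \mathrm{fdr}\,\lambda}{\mathrm{fdr}\,(1-\lambda)}\right)^{1/(a-1)},
\qquad S(p) = (a-1)\,(\ln p - \ln\tau).$$

Scores are computed on the log scale: for near-uniform p-values τ can
underflow double precision, but $(a-1)\ln\tau$ is always finite. The
default `fdr = 0.001` is restrictive on purpose — module search rewards
every positive node, so the score zero-crossing must sit deep in the
signal tail.

**Maximum-scoring subnetwork.** The exact solver first contracts each
connected component of positive-score nodes into a supernode (an optimal
connected solution that touches one positive node of a component always
gains by absorbing the rest), then enumerates connected vertex subsets of
the reduced graph with an include/exclude recursion, pruning any branch
whose current score plus all remaining positive scores cannot beat the
incumbent. It is guaranteed optimal and is used up to `exact_limit = 30`
reduced nodes — beyond that the enumeration can explode combinatorially,
so larger instances go to the heuristic (requesting `method = "exact"`
above the limit is an error rather than a silent fallback). The heuristic
starts from the best positive component and repeatedly merges another
positive component whenever the cheapest connecting path (negative nodes
price their |score|; Dijkstra on arc weights = cost of the entered vertex)
costs less than the component gains, then prunes negative leaves. The
tests verify the exact solver against brute-force enumeration of all
connected subsets and verify that the heuristic never exceeds the exact
optimum.

**Consensus.** Stability is assessed by rerunning the whole chain —
resample, SAM, Fisher, BUM, solve — `n_iter` times and counting how often
each node and edge enters the per-iteration module. Nodes are then
rescored as `frequency − phi` and the solver runs once more on these
consensus scores. `phi = 0.5` means a node must belong to the module in
more than half the iterations to be retained — the natural majority rule;
any monotone transform of frequency would order nodes identically, and phi
is exposed for sensitivity analysis. Two design points deserve emphasis:

* *Resampling mode.* The default is a stratified bootstrap (samples drawn
  with replacement within each group, group sizes preserved). Label
  permutation is also offered but it nullifies the group contrast — a
  permutation-based "consensus" converges to an empty module and is only
  useful for calibration, which is exactly how the null-calibration tests
  use it. Descriptions of resampling the "case/control labels" in the
  module-detection literature are ambiguous between the two readings; the
  signal-preserving bootstrap is the one under which a reproducible module
  is a meaningful target.
* *Failure handling.* An iteration that fails at any stage is logged and
  skipped; frequencies divide by the number of successful iterations, and
  more than 50% failures abort the run.

## Downstream

Enrichment is the exact hypergeometric upper tail $P(X \ge k)$ with
Bonferroni adjustment over the number of sets tested. The background
defaults to the cross-study common universe rather than the whole genome:
genes that were never measured cannot be drawn into a module, and using
the genome would inflate every p-value. Candidate genes must pass
effect-size p < 0.05, Fisher p < 0.05, and module membership — the gate is
applied literally, so a gene printed at p = 0.055 in a reference table
fails it; the bundled five-gene reference table contains exactly one such
borderline case and the test suite documents that it is excluded.
Gene-level GWAS replication takes the most significant SNP per gene and
trait; genes without SNPs report `NA`, never 1, so absence of data is
distinguishable from absence of association.

## The synthetic-data generator

`simulate_dataset()` emulates the target study design: k studies with
unequal group sizes (defaults follow a published six-study design with
groups of 9–45 and 249 subjects in total), baseline log2 expression with
gene-specific mean ~ N(7, 1.5²) and within-group SD ~ Uniform(0.3, 1) (a
realistic microarray dynamic range; the exact values are immaterial to any
contract), a `deg_fraction` of genes with true SMDs drawn from
`smd_range` (default 0.4–0.8, the magnitude scale of published candidate
genes) with random sign, between-study heterogeneity injected on the SMD
scale (variance `heterogeneity_tau2`, default 0.02) so that Q and I²
behavior is directly controllable, an optional two-platform split in
which each half of the studies loses its own disjoint 10% of genes, and a
scale-free network grown by preferential attachment (degree + 1
proportional sampling; n·a − a(a+1)/2 growth edges for n nodes at
attachment a) into which a connected module of `planted_module_size`
DEGs is wired by a random path.

What it does **not** emulate: probe-level noise and normalization
artifacts, correlated gene expression (genes are independent given their
group means), realistic PPI topology beyond the scale-free degree
distribution, and confounders such as batch or age. Passing tests
therefore demonstrate that the statistics and the search behave correctly
under their own model assumptions — not that any particular biological
module will be recovered from real data.

## Problem sizes used by the tests

The suite exercises the pipeline at desk scale, chosen so the full run
stays comfortable on one CPU: up to 2,000 genes, 500-node networks,
planted modules of 10–12 nodes, 20 consensus iterations with 200
permutations per study (the headline checks), and 50-instance
solver-vs-enumeration comparisons on graphs of 6–15 nodes. The reference
analysis design this emulates — six studies, ~13,000 common genes, a
10,174-node PPI, 1,000 permutations and 100 iterations — is reachable
with the same code by raising those parameters.

## Known limitations

* The exact solver's reduction does not include the degree-one negative
  node contractions of full ILP formulations, so its practical exact range
  is smaller than a dedicated solver's; the heuristic carries no
  optimality guarantee.
* The pooled permutation null assumes cross-gene exchangeability of the
  stabilized scores; strongly heteroscedastic genes violate it mildly.
* The BUM model assumes a monotone decreasing signal density; p-value
  histograms with a spike at 1 (for example from discrete tests) fit
  poorly.
* Outlier screening is a stand-in for visual QC, not a claim about how any
  published cohort was cleaned.
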