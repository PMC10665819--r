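---
title: "Methods: metabolomics statistics, correlation patterns, and reporter-ratio network integration"
author: "metabonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolomics statistics, correlation patterns, and reporter-ratio network integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabonet)
```

## The problem this package addresses

Autosomal dominant polycystic kidney disease (ADPKD) reprograms renal
metabolism; AMPK activators such as salsalate are candidate interventions.
A typical study design quantifies tissue metabolites by NMR in three groups
of animals — wildtype, diseased, and diseased-plus-treatment — and profiles
the same kidneys by RNA sequencing. The statistical chain from those two
tables to an interpretable, gene-annotated metabolic network is what this
package implements:

1. unit conversion and probabilistic quotient normalization (PQN) of the
   metabolite concentration table;
2. uncorrected Mann-Whitney screening and PCA summaries per group
   comparison;
3. per-group Pearson correlation matrices, dual-significance filtering, and
   two treatment-relevant correlation pattern classes;
4. selection of differentially expressed (DE) genes from an upstream
   differential-expression table;
5. a modified reporter-metabolite statistic that projects gene-level
   p-values onto substrate-product metabolite ratios of a stoichiometric
   model via a weighted Fisher sum with a simulated null;
6. constrained one- and two-step path finding on the reaction network, and
   assembly, filtering, and export of the final annotated network.

A seeded synthetic-data generator stands in for the animals, so every stage
is testable end to end without any external data.

## Normalization

Concentrations quantified in mmol/L are converted to µg per mg of dry
insoluble pellet as `c × volume × MW / pellet` (`convert_concentration()`).

`pqn_normalize()` implements probabilistic quotient normalization in its
original two-stage form: each sample is first scaled to unit total signal
(integral normalization), the reference profile is the element-wise median
of the scaled samples, and each scaled sample is divided by the median of
its per-metabolite quotients against that reference. The pre-scaling makes
the quotient step's input independent of any per-sample factor, so the
result is *exactly* invariant under per-sample dilution and *exactly*
idempotent — properties the test suite asserts at `1e-10`. A single
quotient pass against the raw median profile cannot have these properties,
because the reference itself moves when samples are rescaled and an overall
dilution factor is fundamentally unidentifiable from the data; the
two-stage form resolves that by fixing the output to the dilution-adjusted
share-of-total-signal scale. All downstream statistics compare groups, so
this global scale convention does not affect any reported quantity. The
reference population is configurable (`"all-samples"`, the default, or
`"group:<name>"` to anchor on one group).

## Univariate screening and PCA

Group comparisons use the Mann-Whitney U test (`mann_whitney()`), two-sided,
and deliberately *uncorrected* for multiple testing: the screen is
exploratory, treatment effects are mild, and a missed true effect is the
costlier error. With `n1 + n2 <= 12` and no ties the p-value is exact
(doubled one-tailed tail probability of the permutation distribution of U,
capped at 1); otherwise a normal approximation with tie and continuity
correction is used. The exact branch is verified against full enumeration
of all labelings in the test suite. Fold changes are
`log2(mean(numerator) / mean(denominator))` of arithmetic group means, with
a zero-denominator guard.

`pca_scores()` autoscales every metabolite column to unit variance before
the singular value decomposition. Tissue metabolite concentrations span
roughly four decades; without autoscaling the first component simply tracks
the most abundant metabolites. Constant columns are dropped with a warning.

## Correlation patterns

`groupwise_pearson()` computes Pearson r per experimental group with
two-sided p-values from the t distribution on `n - 2` degrees of freedom.
Only pairs significant (strict `p < alpha`, default 0.05) in *both* groups
of a comparison are kept (`shared_significant_pairs()`); the concordance
matrix marks kept pairs `+1`/`-1` by sign agreement.

Two pattern classes are defined on top of that rule:

* **opposite under treatment** — dual-significant in (disease, treated)
  with opposite signs, and *not* dual-significant in (wildtype, disease).
  The absence clause is operationalized as failing the dual-significance
  filter there, because that is the only sense in which a pair is "absent"
  from a matrix that displays dual-significant pairs only.
* **corrected toward wildtype** — dual-significant in (wildtype, disease)
  with opposite signs, and dual-significant in (disease, treated) with the
  treated sign equal to the wildtype sign.

The two classes are disjoint by construction. A caveat the package
documents rather than hides: at `alpha = 0.05`, a truly
treatment-specific reversal has exactly a 5% chance per dataset of being
spuriously dual-significant in (wildtype, disease) and therefore excluded
or re-classified — this misclassification channel is a property of the
definitions and does not shrink with sample size. Correlation analysis of
this kind is also sensitive to outlier samples; no outlier rule is applied
because none is part of the procedure being implemented.

## DE gene selection

`select_de_genes()` selects `FDR < 0.05` *or* `|log2FC| > 0.5` (strict
inequalities) and partitions by fold-change sign. The union reading is the
one under which the published sub-counts reconcile: 81 FDR-significant
genes plus 103 fold-change-only genes equals the combined 184 (55 up, 129
down). Selected genes with exactly zero fold change are reported
separately rather than forced into a side.

## Reporter ratios

The unit of transcriptome integration is the *metabolite ratio*: a
substrate-product pair extractable from some reaction of the model.
`build_ratio_gene_map()` attaches to each ratio the union of the gene
associations of every reaction yielding it; gene-less ratios (e.g. pure
transporter pairs) are excluded with a log message.

Weights quantify how much influence a gene is expected to have on a ratio
(`compute_weights()`): start at 1, divide by the number of genes connected
to the ratio, then divide each gene's weights by that gene's maximum weight
over its ratios. Every weight lies in `(0, 1]` and every gene attains
weight exactly 1 somewhere; a ratio that is a gene's only context keeps
weight 1 regardless of gene count.

Gene p-values are first passed through a rank-based inverse uniform
transform, `rank / (N + 1)` with average ranks for ties, which forces an
exactly uniform null marginal and confines values to the open unit
interval. The transform runs over *all* genes in the supplied table (the
whole transcriptome, not only network-mapped genes) — this matters: ranking
within a small mapped subset would flatten genuine signal. The statistic is
the weighted Fisher sum

$$X_i = -\sum_j w_{ij} \ln p_j$$

with the natural logarithm (the Fisher convention). Each ratio is tested
against its own simulated null: `n_sim` draws of the same weighted sum over
i.i.d. Uniform(0,1) variables — justified exactly by the rank transform —
with the add-one estimator `(#{X* >= x_obs} + 1) / (n_sim + 1)`, which is
always positive and respects the `[1/(n_sim+1), 1]` range. The test is
upper-tailed, since the statistic grows with differential-expression
evidence. The production default is `n_sim = 100000`; the test suite uses
2000–5000 per ratio to stay fast, sizes at which the Monte-Carlo error is
still far below the decision threshold. In the equal-weight case with `k`
genes the null is exactly half a chi-square with `2k` degrees of freedom,
which the suite uses as a closed-form cross-check. Metabolites of ratios
with `p < 0.05` feed the network stage. Because gene sets overlap between
ratios, strong signal on one ratio lifts neighboring ratios that share its
enzymes — a deliberate property of reporter scoring, visible in the demo
workflow.

## The reaction network

The model dialect (`load_model()` / `write_model()`) carries metabolites
(compartment-qualified ids, synonyms, formulas, optional ChEBI ids),
reactions (stoichiometry, reversibility, transporter flag, gene ids, and a
*half-reaction partition*), a cofactor-pair registry, and a hub list.
Half-reaction partitions are model data: decoupling electron, amino or
phosphate transfer from the carbon skeleton requires chemical knowledge
that stoichiometry alone cannot recover. A reaction without a partition is
treated as one whole-reaction couple, with a warning.

`extract_pairs()` links a substrate to a product only within one
half-reaction, and only if both carry carbon and neither is a hub, or the
two are a registered cofactor couple (so a NAD-like redox couple stays
linkable; the ATP/ADP phosphate couple is linkable exactly when registered,
which is the default resolution chosen here for consistency with the redox
case). Hubs — ubiquitous currency species, SAM included — are never
linkable, which is what keeps the network from collapsing into a star
around water and ATP. Transporter reactions and producing half-reactions of
*uniquely produced* metabolites yield weight-zero pairs. "Uniquely
produced" is read model-wide: product of exactly one reaction, in the
written direction; this is one plausible reading of an underspecified rule
and is flagged as an interpretation, not asserted as the original authors'
intent.

`find_paths()` enumerates all simple paths of total weight 1 or 2 over the
directed pair graph, honoring irreversibility, with at most two consecutive
zero-weight steps — enough for cytosol–organelle–extracellular transporter
chains while keeping the search finite. The implementation is a recursive
search; the test suite checks it against an independent enumeration
(igraph simple paths expanded over parallel edges and filtered by the
constraints) on dozens of random toy models.

`build_network()` assembles measured metabolites, declared bridge
metabolites (unmeasured central-metabolism intermediates added to prevent
gaps), reporter-selected metabolites, and the genes of every reaction on a
kept path; components are labeled over the whole graph.
`filter_subnetworks()` drops components with fewer than three significant
members (genes and metabolites counted together) and never splits a
component. `export_graph()` writes node-link JSON or GraphML with all
annotations.

## The synthetic generator

`make_toy_model()` emits models with the structural features the pipeline
exercises: equal-carbon partner pairs (so every reaction is carbon-balanced
by construction), a NAD-like cofactor couple, a gene-less transporter, an
irreversible reaction, a carbon-free water-like species, a SAM-like hub,
and gene associations on every enzymatic reaction.

`simulate_metabolite_table()` draws baselines log-uniformly over two
decades (`10^-1.5` to `10^0.5`), matching the span of published tissue
tables, applies multiplicative group shifts, and adds log-normal noise with
a default 20% coefficient of variation — the mid-range of the published
group SD-to-mean ratios. Correlation structure is implanted through shared
latent factors with group-specific loading signs, expressed in units of the
log-noise SD, which guarantees a positive-definite covariance and exact
sign control per group; the default loading magnitude 2 gives within-group
correlations of about 0.8. Group size defaults to 10 per group (published
designs use 8–12). Model topology, concentrations, and gene p-values are
drawn from independently derived sub-streams, so redrawing one never
perturbs another.

`simulate_gene_stats()` gives signal genes `Beta(a, 1)` p-values
(default `a = 0.1`; `a = 1` reduces to the uniform null) and all others
Uniform(0,1), with fold-change magnitudes monotone in the p-value.
`make_de_benchmark()` is different in kind: a fully synthetic table built
to the *published marginal counts* of a DE comparison (81 FDR-significant
genes split 35/46, 103 fold-change-only genes split 20/83, 58 of the 81
shared with the wildtype comparison) so the selection rules can be
exercised at the published sizes; no individual value in it is real.

What the generator does *not* emulate: NMR spectral artifacts, censoring at
the quantification limit, realistic inter-metabolite covariance beyond the
implanted factors, count noise in RNA-seq, or real mouse physiology.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated models, not biological validity on real data.

## Verification sizes and known limitations

The shipped suite runs at sizes chosen to make Monte-Carlo error small
relative to each decision threshold while keeping the whole suite around
half a minute: reporter calibration at 20 seeds × 200 all-null ratios with
`n_sim = 2000` (significant fraction within 3 Monte-Carlo SEs of 0.05);
recovery with 5 planted ratios among 195 nulls at `n_sim = 5000`;
path-finder cross-checks on 50 random models; Mann-Whitney enumeration on
500 random small-sample cases; pattern recovery at 20 seeds with
`n = 500` per group.

Known limitations, by design or by honesty:

* the 5% per-dataset misclassification channel for opposite-pattern pairs
  described above, which caps exact pattern recovery below what a naive
  asymptotic argument suggests;
* correlation p-values assume bivariate normality on the concentration
  scale; the generator's log-normal noise at CV 0.2 is close enough to
  normal for calibration, but heavy-tailed real data would inflate the
  pattern classes' false-positive rates;
* PQN's output scale is a convention (see above), and no outlier handling
  is applied anywhere;
* the model dialect is deliberately small; curation of a real genome-scale
  model (synonym/identifier reconciliation against external databases) is
  out of scope.
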