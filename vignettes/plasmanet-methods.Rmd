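---
title: "Methods: diagnostic modelling and network topology for plasma metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic modelling and network topology for plasma metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmanet)
```

`plasmanet` implements a complete case–control analysis chain for targeted
plasma metabolomics: detection filtering, univariate screening, penalised
diagnostic modelling, ROC evaluation, Pearson-threshold correlation
networks with a full topological parameter battery, and Kaplan–Meier
survival verification. This vignette explains the statistical model behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic-cohort generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The data model

The pipeline's universal input is a wide table: one row per subject, a
`group` column (`control`/`case`), an optional `stage` column
(`early`/`advanced`, cases only), and one non-negative numeric column per
analyte (concentrations in µM; zero is legal and read as
below-quantification, negative values are rejected). Analyte panels are
annotated with one of eight classes: acylcarnitine, amino acid, biogenic
amine, lysoPC, diacyl PC, acyl-alkyl PC, sphingomyelin, hexose.

**Detection filtering** (`filter_detected()`). Targeted assays report many
analytes below the limit of detection. An analyte is retained when its
missing fraction is at most `max_missing_fraction` (default **0.2**, the
usual 20% rule in targeted metabolomics); the surviving analytes' residual
missing cells are imputed at **half the observed minimum**, the standard
stand-in for a value below LOD. An entirely missing analyte is always
dropped — there is no minimum to halve. The output contains no missing
values and the operation is idempotent. The 20% rule is a convention, not
a law; it is exposed as a parameter because assay-specific LOD handling
differs.

## Univariate screening

For each analyte the two groups are compared with a two-stage rule:

1. a two-sided **F-test** of variance equality at `alpha_var` (default
   0.05). The F-test is the classical reading of an "equal variance" gate;
   it is exact under normality and is used here only as a router.
2. if variances are compatible, the **pooled-variance Student's t-test**;
   otherwise the **Mann–Whitney U test** with normal approximation and tie
   correction (no continuity correction, so the two-sided p is exactly
   label-symmetric).

Degenerate analytes (constant in both groups) are flagged and given
p = 1. Bands follow the usual reporting convention: `p<0.001`,
`p<0.01` (0.001 ≤ p < 0.01), `ns`. No multiplicity adjustment is applied
by default because screening tables in this field conventionally report raw
bands; Benjamini–Hochberg is available via `adjust = "BH"`.

Because the Mann–Whitney branch is rank-based it is invariant under any
strictly monotone transform of the analyte — so the routing decision, not
the scale (raw vs log concentrations), is the only place where scale
matters on that branch.

## Diagnostic modelling

**LASSO screening** (`lasso_logistic_cv()`). The metabolome is strongly
collinear, so marker screening uses L1-penalised logistic regression over a
geometric grid of 100 penalties from λ_max (the smallest penalty with an
all-zero solution) down to 10⁻⁴·λ_max. Predictors are z-scored internally
and coefficients reported on the original µM scale. λ_min minimises the
mean cross-validated binomial deviance over **stratified, seeded folds**
(default 10); stratification is not part of every published description of
this procedure but removes the possibility of a single-class fold at these
group sizes. The selected set is the nonzero support at λ_min.

**Backward stepwise logistic regression** (`backward_stepwise()`). Starting
from the LASSO-selected candidates, two rules iterate until neither fires:

- *Collinearity rule*: while any candidate pair has |Pearson r| ≥
  `collinearity_r` (default 0.8, matching the network edge threshold), the
  member of the most-correlated pair with the **higher odds ratio** is
  eliminated. The rule is applied per pair, and the ORs used are
  single-variable logistic ORs: for exactly duplicated predictors — the
  case the rule exists for — a joint fit is aliased and multivariate ORs
  are undefined, while univariate ORs remain well-defined and identical,
  with a lexicographic tie-break keeping the procedure deterministic and
  order-invariant. Read literally the rule drops the larger OR even when
  the pair contains a protective (OR < 1) marker whose reciprocal effect is
  stronger; `or_rule = "magnitude"` switches to comparing
  max(OR, 1/OR).
- *Wald rule*: otherwise the model is refit by maximum likelihood (IRLS
  with intercept, Wald standard errors from the observed information) and
  the variable with the largest Wald p is dropped if that p exceeds
  `alpha_stay` (default 0.05).

If every candidate dies, an intercept-only fit is returned and flagged.
Every elimination (which rule fired, the correlation, the ORs or the p) is
recorded in an auditable trace. Perfect separation is flagged via
`converged = FALSE`, detected on the standardized (per-SD) coefficient
scale so that legitimate large per-µM slopes of low-abundance analytes are
not mistaken for divergence.

A caution that shaped the package's defaults: when a candidate set contains
a marker strong enough to quasi-separate the classes, *all* Wald statistics
degenerate (the Hauck–Donner effect) and backward elimination becomes
arbitrary; and conditional on a near-perfect marker, moderate markers carry
almost no incremental likelihood, so no elimination rule can reliably
retain them. Panels evaluated with this procedure should sit below that
regime; the synthetic generator's defaults (below) do.

**ROC evaluation** (`roc_analysis()`). AUROC is computed by the rank
(Mann–Whitney) identity U/(n₁n₂) with half-credit for ties — the
probability that a random case outranks a random control. The reported
cutoff maximises **Youden's J** = sensitivity + specificity − 1 (ties
resolve to the lower, more sensitive cutoff; no criterion is canonical, and
Youden's J is the common default). PPV and NPV are computed from the cutoff
confusion matrix at sample prevalence. For panels mixing up- and
down-markers, `direction = "auto"` orients each marker so AUROC ≥ 0.5.

## Correlation networks and topology

Within one group (≥3 samples), pairwise Pearson correlations of
concentrations get two-sided p-values from the t transform
t = r·√((n−2)/(1−r²)) with n−2 df; |r| = 1 pairs get p = 0, and
zero-variance analytes are excluded with a warning.

An **edge** joins analytes with r ≥ `r_min` (default **0.8**, inclusive at
the boundary) and p < `alpha` (default 0.05). The threshold is applied to
the *signed* correlation by default — the convention that a co-regulation
network links positively correlated analytes — with `signed = FALSE`
thresholding |r|. Degree-zero analytes are removed before topology is
computed (their count is reported), so node counts reflect connected
analytes; this mirrors how published metabolite networks report N below
the panel size.

The topology battery implements the standard printed formulas:

| parameter | definition |
|---|---|
| clustering C_i | 2L_i/k_i(k_i−1), 0 for degree ≤ 1; ⟨C⟩ averages all nodes |
| density d | L/(N(N−1)/2) |
| average degree ⟨k⟩ | 2L/N |
| heterogeneity | √variance(k)/mean(k), population variance by default |
| centralization | Freeman degree form Σ(k_max−k_i)/((N−1)(N−2)) |
| paths | BFS; ⟨l⟩ and diameter over reachable ordered pairs |
| assortativity | Pearson correlation of degrees over edge endpoints |
| modularity Q | Σ_c(e_c/m − (d_c/2m)²) of a greedy partition |

Numerical choices worth stating:

- *Degree ≤ 1 nodes* contribute C_i = 0 to ⟨C⟩ (some network tools
  exclude them; including them is the plain reading of the averaged
  formula).
- *Heterogeneity* uses the population variance (divide by N); a
  `heterogeneity_variance = "sample"` switch gives the N−1 form, since the
  printed formula names no correction.
- *Degree centralization* is the Freeman normalisation (1 for a star, 0 for
  any regular graph). The raw adjacency-row-sum form that sometimes
  appears in print is just the degree sequence and cannot be a normalised
  index, so the Freeman form is the quantity implemented.
- *Paths are computed within components*: published metabolite networks
  report finite diameters despite having several components, which is only
  possible if unreachable pairs are excluded rather than counted as
  infinite.
- *Modularity* uses deterministic greedy agglomeration (merge the connected
  community pair with the best ΔQ = e_ab/m − d_a·d_b/2m², lexicographic
  tie-breaks, stop when no merge gains). Published values rarely name the
  community algorithm; determinism was prioritised so identical inputs give
  identical reports. Q is undefined (NA) for edgeless graphs, as are path
  statistics; centralization is undefined for N < 3; assortativity is
  undefined when edge-endpoint degrees have zero variance.

Every metric is verified in the test suite against independent brute-force
oracles (exhaustive triangle counting, Floyd–Warshall distances, direct
degree-moment formulas, an independent Pearson-over-stubs assortativity,
and the modularity definition applied to the returned partition) on
Erdős–Rényi graphs across densities 0.1/0.3/0.6 with N ≤ 30, and
cross-checked against igraph.

Stage comparisons (early vs advanced) subsample the larger stage to the
size of the smaller with a seeded uniform draw (`subsample_group()`)
because every parameter in the battery is sample-size sensitive; comparing
topologies computed under different settings is refused outright.

## Survival verification

`km_estimator()` wraps the product-limit estimate (censored times reduce
the risk set without a step; Greenwood standard errors are stored for
optional bands). `median_split()` labels samples strictly above the sample
median `high`, ties going `low` — no published convention fixes the tie
side, and the labelling is invariant under monotone transforms of
expression. `logrank_test()` is the standard two-group log-rank
(χ², 1 df); a cohort with no events at all is reported as statistic 0,
p = 1, flagged degenerate rather than an error.

## The synthetic-cohort generator

`simulate_cohort()` draws per-sample latent vectors from a multivariate
normal on the **log scale** with a group-specific block-correlation matrix,
adds planted effects to case log-means, and exponentiates. Defaults mirror
a realistic study shape: **78 controls, 64 cases** (44 early / 20 advanced
by default; the split is a parameter because staging conventions vary), a
**121-analyte** panel across the eight classes, per-analyte log-SD **0.30**
(~31% CV, typical of targeted plasma assays), and class-level baseline
concentrations spanning sub-µM acylcarnitines to mM-scale hexose.

Planted effects (log units): **arginine +0.55, lysoPC.a.C16.0 −0.36,
PC.aa.C38.3 +0.40**, i.e. marginal AUROCs of roughly 0.90, 0.80 and 0.83.
These magnitudes make the trio *jointly* identifiable: strong enough that
LASSO keeps all three at λ_min and each survives Wald elimination in a
joint model at n = 142, but below the separation regime described above in
which stepwise inference degenerates regardless of implementation.

Correlation blocks: a 27-member glycerophospholipid/sphingomyelin module,
a 6-member lysoPC block and an 8-member acylcarnitine block, at within-block
correlation **0.78 in controls vs 0.88 in cases**. Relative to the r ≥ 0.8
edge threshold, control correlations sit just below the cut and case
correlations above it, so the case network is wired much denser — the
disease-vs-healthy contrast the pipeline is designed to detect — while both
group networks keep enough connected nodes (typically 30–41) that isolate
removal does not degenerate the density comparison. The planted markers are
deliberately *outside* the blocks so marker identifiability and network
density are independent knobs. Correlation is imposed on the log scale
(Gaussian-copula-like); the resulting raw-scale Pearson correlations — the
ones the network stage actually thresholds — are slightly attenuated (at
log-SD 0.3, log-scale 0.78 ≈ raw 0.77), which the defaults account for.

One global seed drives every stage through deterministically derived child
seeds, so adding analytes or stages never reshuffles earlier draws, and
identical configs give byte-identical run reports.

`simulate_survival_cohort()` generates exponential event times with hazard
h₀·exp(β·z) for z-scored expression and independent exponential censoring —
a deliberately minimal stand-in for public expression/survival cohorts.

**What the generator does not emulate**: per-analyte absolute concentration
tables; limit-of-detection (left-censored) missingness beyond
missing-at-random holes; batch/plate effects; correlation between planted
markers and the rest of the metabolome; non-proportional hazards. Passing
tests on these cohorts therefore demonstrate that the *pipeline machinery*
is correct and that its decision rules recover known structure — not that
any particular real-data finding would replicate.

## Problem sizes used in the test battery

The shipped verification suite runs at sizes chosen to make every check
decisive yet quick: ≥100 random graphs (N ≤ 30) for the topology oracles,
1000 random instances for the AUROC identity, 20-seed recovery experiments
for LASSO (n = 300, 50 noise analytes), stepwise (n = 500) and the
end-to-end paper-shaped cohort (78 + 64), 2000 null analytes for type-I
calibration, and 500-per-arm survival simulations for log-rank power.

## Known limitations

- The equal-variance gate is exact only under normality; on raw
  concentrations it partly reflects scale, which is why the Mann–Whitney
  branch exists.
- Wald CIs (not profile likelihood) are reported, matching standard
  glm-style tables; they are anti-conservative near separation, which the
  `converged` flag surfaces.
- The greedy modularity partition is a deterministic heuristic; it can
  undershoot the optimal Q on graphs with weak community structure.
- Stepwise model selection inherits the usual selection-bias caveats; the
  pipeline reports no post-selection-corrected inference.
- No Cox regression, weighted networks, or differential-network statistics
  beyond side-by-side topology comparisons.
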