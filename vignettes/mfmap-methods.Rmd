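---
title: "Hierarchical multifluid correlation maps and phenotype-driven module identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multifluid correlation maps and phenotype-driven module identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mfmap)
```

## Scope

mfmap analyzes untargeted metabolomics measured simultaneously in several
body fluids (plasma `P`, urine `U`, saliva `S` by default).  It builds a
three-level *hierarchical correlation map* — single metabolites,
sub-pathways, super-pathways — from Gaussian graphical models (GGMs), and
searches any level of that map for *modules*: connected groups of nodes
whose aggregated abundance associates with a phenotype.  The motivation is
the contrast between *sparse* phenotypes (few metabolite associations,
best resolved at the metabolite level) and *dense* phenotypes such as sex,
which touch a large share of the metabolome and are only interpretable
after aggregation to pathway level.

Every node is fluid-resolved and named `"FLUID::name"`, so plasma and
urine lysolipids are distinct nodes and cross-fluid edges are visible as
such.

## Preprocessing

The pipeline (`mf_preprocess()`) fixes this order; each stage exists to
license the next one:

1. **Run-day filter.** A feature is dropped when more than half of its
   run days carry fewer than three non-missing values — such day medians
   would be meaningless.  The inequalities are strict ("more than half",
   "fewer than three").
2. **Run-day rescaling.** Each value is divided by its feature's median on
   its run day, removing platform drift.  Post-condition (asserted in the
   tests): every (feature, day) cell has median exactly 1.
3. **Probabilistic quotient normalization** of the configured fluids
   (default urine and saliva; plasma volume is physiologically
   regulated).  The reference pseudo-sample is the per-feature mean over
   samples, restricted to features with *no* missing entries; each
   sample's dilution factor is the median ratio of its values to the
   reference over those complete features.  PQN therefore runs *before*
   imputation, on genuinely observed values only.  Post-condition: the
   median quotient of a normalized sample against the reference used is
   exactly 1.
4. **log2 transform.**
5. **Multivariate outlier exclusion**, per fluid, on the fully observed
   features: columns are centred by median and scaled by MAD, projected
   onto principal components retaining 99% of variance, and a robust
   Mahalanobis-type score is computed by rescaling each component by its
   robust spread.  Samples more than `outlier_sd` (default 4) robust SDs
   above the median score are removed.  This is a documented variant of
   the robust-PCA outlier family rather than a port of any specific
   implementation; it is validated by planted-outlier recovery (a sample
   at 10 SD is flagged, a homogeneous cloud has < 2% flag rate).
6. **Missingness filter.** Features with strictly more than 20% missing
   values (over the retained samples) are removed; correlations estimated
   on heavily imputed features would mostly reflect the imputation model.
7. **Censored-normal imputation.** Missingness in ion-count data is
   mostly left-censoring at the detection limit.  Per (feature, run day)
   with strictly more than 10 observed values, a left-censored normal is
   fitted by maximum likelihood on the log2 *raw* (pre-normalization)
   values: observed values contribute density terms, the `m` missing ones
   contribute `m * log Phi((c - mu)/sigma)`.  The censor point `c` is the
   minimum observed value of that cell — the paper-level description
   ("censored part of a normal") needs a concrete detection limit, and
   the minimum observed value is the tightest bound identifiable from the
   data.  Draws come from the fitted normal truncated to `(-inf, c]` and
   are then mapped onto the normalized scale by subtracting the log2
   run-day median and dilution factor that were applied to that cell.
   Non-convergent fits (or sigma below 1e-8) fall through to stage 8.
8. **Predictive mean matching** for whatever remains: the feature is
   regressed on its `k = 10` most correlated complete features, and each
   missing entry receives a value drawn uniformly from the `donors = 5`
   observed entries with the closest predicted means — so imputed values
   are always actually observed values.  Features with fewer than 10
   observations fall back to a marginal draw.  `k` and `donors` follow
   common predictive-mean-matching practice and are configurable.

Randomness in stages 7–8 uses one master seed with per-(feature, run day)
substreams derived by stable string hashing, so reordering features does
not change any draw.

## Network inference

GGMs use partial correlations: the association between two variables
after removing the linear effect of all others.  With hundreds of
metabolites the sample correlation matrix is ill-conditioned, so it is
shrunk toward the identity with the analytic Ledoit–Wolf/Schäfer–Strimmer
intensity (`lambda`, clipped to [0, 1]) before inversion;
`pcor(i,j) = -Omega_ij / sqrt(Omega_ii Omega_jj)`.

Age, gender and BMI enter as standard covariates *inside* the model: they
are appended as extra columns, conditioned on, and their rows/columns
removed from the result — they never appear as network nodes and never
count toward multiple testing.  The Pearson side is computed on
covariate-residualized data so that both tests condition on the same set.

An edge requires **both** the Pearson and the partial correlation to be
significant at `alpha = 0.05` after Bonferroni correction for
`p(p-1)/2` variable pairs.  The dual rule keeps partial-correlation
artifacts (e.g. conditioning-induced correlations) out of the map while
the Bonferroni pair-count correction keeps it sparse and high-confidence.

**Partial-correlation p-values.**  Two recipes are implemented and
selectable; `method = "auto"` switches between them by regime:

* *Exact t-test* with `n - 2 - (p + c - 2)` degrees of freedom.  This is
  the classical test and is used whenever `n - p - c >= 30`.
* *Fitted null density* `f0(r) ~ (1 - r^2)^((kappa-3)/2)`, with the
  effective degree of freedom `kappa` estimated by maximum likelihood
  from the observed off-diagonal partial correlations, used in the
  high-dimensional regime (`p + c` close to or above `n`) where the exact
  degrees of freedom do not exist and shrinkage invalidates nominal
  ones.  Its known limitation, which drove the regime rule: the single
  density is fitted to *all* off-diagonals, so when true edges make up a
  non-negligible share of pairs (easy at small `p`) the fit absorbs them
  and the p-values become conservative.  In simulations with `p = 50`,
  `n = 200` and shrinkage disabled the fitted null reproduces the nominal
  type-I rate (fraction of p < 0.05 equal to 0.050); if the fitted
  `kappa` collapses to its lower bound a Fisher-z approximation is used
  and a warning raised.

Unknown-structure metabolites (no pathway annotation) are genuine
variables of the system and are included at the metabolite level by
default (`include_unknowns`); pathway levels necessarily exclude them.

## Pathway aggregation

Each (fluid, sub-pathway) group of known metabolites is represented by
its **eigenmetabolite**: members are z-scored and the first principal
component score vector is taken, following the eigengene idea.  The
explained variance — leading eigenvalue over the trace (= member count)
of the member correlation matrix — is reported for every pathway; under a
single-factor model with loading `a` it approaches `(1 + (m-1)a^2)/m`,
which the tests verify.  The PC sign is arbitrary, so it is fixed by
requiring non-negative correlation with the mean z-score of the members;
this makes the representative deterministic.  Single-member pathways are
kept (their eigenmetabolite is the z-scored member itself).

The sub-pathway GGM is inferred from the eigenmetabolite matrix exactly
as at the metabolite level.  The **super-pathway network** is produced by
*collapsing*: two (fluid, super-pathway) nodes are linked when at least
one sub-pathway edge connects their members; edges record the member-edge
count but no correlation statistics, and intra-super-pathway edges are
dropped as self-loops.  Super-pathway eigenmetabolites are deliberately
not used: groups as broad as "Lipid" are too heterogeneous for a single
component to represent them (their explained variance is low), so
collapsing is the honest coarse view.

## Module identification

A candidate module `M` is represented by the *average z-score* `R_M` of
its member metabolites — at pathway levels, of the set union of all
metabolites annotated to its pathway nodes.  The mean z-score (not an
eigenmetabolite) is used because modules deliberately mix heterogeneous
pathways.  The score is obtained from

    R_M ~ b0 + b1 * P + b2 * gender + b3 * age + b4 * BMI + e

as `-log10` of the two-sided p-value of `b1` (capped at 300 to absorb
underflow; the cap only affects reporting since any monotone transform of
p yields the same search trajectory).  A single node is scored by the
same regression on its own z-score, which is exactly the univariate
association test.  When the phenotype *is* one of the standard covariates
(e.g. gender) it is removed from the covariate list.  Binary phenotypes
are 0/1-coded regressors; the linear model on the left-hand-side
representative needs no logistic variant.

**Greedy search.**  From every seed node: evaluate `M ∪ {v}` for each
network neighbor `v` of `M`; take the best-scoring candidate `v*`
(lexicographically smallest node id among exact ties, for determinism);
add it only if the extended score strictly exceeds both the current score
and the maximum single-node score over `M ∪ {v*}`; stop otherwise.  The
single-component dominance clause prevents a module from riding on one
strong member.

**Consolidation.**  Optimal modules from different seeds overlap heavily;
modules sharing at least one node are merged (connected components of the
overlap graph) into *maximal modules*, which are rescored.  A merged
module that no longer passes the rules below is dropped, not decomposed
back into its constituent optima — the union was judged one module, so it
is accepted or rejected as one.

**Significance.**  A maximal module is reported iff its p-value is below
`alpha / n_nodes` (Bonferroni at node level, a conservative choice given
the search's selection pressure) *and* its score strictly exceeds every
member's univariate score.  A consequence worth noting: single-node
modules can never satisfy the strict dominance rule, so every reported
module has at least two nodes.

Known limitation: because `R_M` is a plain average, members with opposing
effect directions cancel; the method finds coherently directed modules
only.

## Synthetic data generator

Real multifluid cohort data of this kind is access-restricted, so the
package ships a generator (`synth_config()`, `generate_synthetic()`)
whose ground truth drives all validation.  The latent model lives on the
log2 scale: members of a (fluid, sub-pathway) block follow
`z = a*f + beta*P + sqrt(1 - a^2 - beta^2)*e` with a shared factor
`f ~ N(0,1)`, standardized phenotype `P`, planted per-feature effect
`beta` (SD units), and unit total variance; cross-fluid pathway pairs can
share a factor component.  Raw intensities are
`2^(z + mu_j) * runday_offset * dilution`, with per-feature baselines
`mu_j ~ N(10, 2)` (log2 ion counts), multiplicative run-day batch
offsets, and per-sample lognormal dilution for urine/saliva
(log2-SD 1.25 and 1.0 — a several-fold 95% range, typical for urine).
A configurable fraction of features (default 50%) is left-censored at its
own intensity quantile; censoring a *fraction* matters because PQN
requires some fully observed features, as real panels have.  A
configurable fraction of features keeps no pathway labels, mimicking
unidentified compounds.  `make_paper_shaped_config()` produces a
three-fluid panel with feature counts proportional to a full
plasma/urine/saliva study (335/473/189, scaled by 1/5 by default) and 906
samples.

What the generator does *not* emulate: heavy-tailed and skewed marginal
distributions, heteroscedastic technical noise, structured (non-censoring)
missingness, correlated covariate effects on the metabolome, and real
pathway topology (blocks plus a few cross-fluid factors instead of a
scale-free-ish correlation web).  Passing tests therefore demonstrate
correctness of the algorithms under a controlled model, not performance
guarantees on any particular cohort.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

* estimator oracles — closed-form 3-variable partial correlations
  (tolerance 1e-12) and dense-inversion agreement at `p = 5`,
  `n = 1000`, shrinkage disabled (1e-8);
* chain-structure recovery (`X -> Y -> Z`, coefficients 0.6, `n = 500`,
  100 seeds): exactly the two true edges, no transitive edge;
* a Bonferroni null (`p = 10`, `n = 500`, 100 seeds): zero edges;
* greedy-vs-exhaustive comparison on 50 random graphs of up to 8 nodes
  with frozen random scores, enumerating every connected subset: the
  greedy result never exceeds the optimum and all output invariants
  (connectedness, seed dominance, disjoint maximal modules) hold;
* planted-module power: 28 metabolites in 7 four-member sub-pathways,
  loading 0.45, one whole pathway planted with per-member effect 0.075 SD
  at `n = 1500`.  These numbers are a deliberate power design: the
  expected single-node statistic (`beta * sqrt(n) ≈ 2.9`) sits below the
  node-level Bonferroni cut (≈ 3.15) while the four-member average gains
  a factor `1/sd(R_M) ≈ 1.57`, and the within-block partial correlation
  (`a^2/(1 + 2a^2) ≈ 0.15`) clears the edge threshold (≈ 0.10) so the
  planted module is actually connected in the inferred map;
* the same conditions with a permuted phenotype: no modules;
* PQN dilution recovery at `n = 200` with a 400-feature urine block and
  ~5% missingness (Pearson r ≥ 0.99 against planted factors);
* censored-normal MLE on `N(0,1)` censored at its 20% quantile,
  `n = 5000` (within ±0.05 of truth), with all imputed values below
  their censor points;
* eigenmetabolite explained variance against the single-factor closed
  form at `n = 10000`;
* the full pipeline invariants on an end-to-end synthetic study
  (`n = 906`, ~200 features).

These sizes were chosen so every experiment is statistically
well-powered while the whole suite remains comfortable on a laptop-class
single core.

## Numerical and design details

* Shrinkage intensity clipped to [0, 1]; `lambda = 1` (pure identity)
  zeroes all partial correlations and warns.
* Censored-normal fits optimize over `(mu, log sigma)` by Nelder–Mead
  from moment starts with an inflated initial sigma; failures fall back
  to predictive mean matching.
* Truncated-normal draws use inverse-CDF sampling; when the censored tail
  mass underflows, the draw degenerates to the censor point.
* Greedy tie-breaks are lexicographic in node id; serialization orders
  nodes and edges lexicographically; GraphML floats are written with 17
  significant digits so round trips are lossless.
* All strictness choices ("more than", "higher than") are strict
  inequalities.
* File formats: TSV for matrices/annotations/phenotypes, GraphML and
  edge-list TSV for networks, JSON for module reports and ground truth,
  YAML for CLI configuration.  Module results have no canonical format in
  the field; JSON was chosen for structured provenance (members, seeds,
  thresholds).
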