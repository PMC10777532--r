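---
title: "Methods: colocalization-first clustering of GWAS risk variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocalization-first clustering of GWAS risk variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

A disease like type 2 diabetes aggregates many distinct biological
processes. Its GWAS risk variants are highly pleiotropic: a variant that
raises disease risk through adiposity also moves adiposity traits, one
acting through lipid metabolism moves lipid traits, and so on. `coloclust`
partitions a disease's risk variants into such pathway clusters by first
requiring *colocalization* — formal evidence that the disease and a
related trait share a causal variant in a region, rather than merely
overlapping association signals inflated by linkage disequilibrium (LD) —
and only then clustering variants by their trait-association profiles.
Partitioned polygenic risk scores (PRSs) built per cluster, and
Mendelian-randomization (MR) directionality tests between the clustered
traits and the disease, probe what the clusters mean physiologically.

The pipeline stages map one-to-one onto the package modules:

1. **Harmonization** (`read_sumstats`, `define_regions`,
   `harmonize_region`, `resolve_palindromic`): per-trait summary
   statistics are restricted to 1 Mbp regions around lead variants,
   allele-reconciled, and oriented to the index trait's effect-increasing
   allele.
2. **Colocalization** (`wakefield_labf`, `coloc_abf`,
   `multitrait_coloc`, `run_region_workflow`, with fine-mapping via
   `susie_rss` and `coloc_susie`).
3. **Network clustering** (`build_zmatrix`, `snp_correlation`,
   `min_degree_threshold`, `spinglass_cluster`, `modularity_q`,
   `summarize_clusters`).
4. **Partitioned PRS** (`build_prs`, `test_association`,
   `decile_contrast`).
5. **MR directionality** (`ivw`, `egger`, `steiger`,
   `effect_correlation`).
6. **Synthetic data** (`simulate_ld`, `simulate_region_sumstats`,
   `make_scenario`, `simulate_zmatrix`, `simulate_cohort`): every stage
   is testable end to end without external downloads.

`run_pipeline()` drives stages 1–3 over an on-disk scenario;
`experiment_*()` functions package the calibration and recovery
experiments the test suite and `scripts/acceptance.R` run.

# Colocalization model

## Approximate Bayes factors

For one variant with effect estimate $\hat\beta$, standard error $se$ and
$z = \hat\beta / se$, the Wakefield approximate Bayes factor for
association under a $N(0, W)$ effect prior is, with $V = se^2$,

$$\log \mathrm{ABF} = \tfrac12\left[\log\frac{V}{V+W} +
z^2\,\frac{W}{V+W}\right].$$

$W$ defaults to $0.04$ on the standardized-beta scale (effects of a few
percent of a phenotypic SD are detectable); it is exposed in
`coloc_priors()` and can be raised for binary traits whose log-odds
effects are larger.

## Pairwise enumeration (H0–H4)

`coloc_abf()` enumerates all single-causal-variant configurations for two
traits over $m$ shared variants. With per-variant Bayes factors $A_{1j},
A_{2j}$ and priors $p_1, p_2$ (association with one trait only, default
$10^{-4}$) and $p_{12}$ (shared association, default $10^{-5}$), the
unnormalized masses of the five hypotheses are

$$1,\quad p_1\textstyle\sum_j A_{1j},\quad p_2\sum_j A_{2j},\quad
p_1 p_2\big(\sum_j A_{1j}\sum_k A_{2k}-\sum_j A_{1j}A_{2j}\big),\quad
p_{12}\sum_j A_{1j}A_{2j},$$

normalized to posterior probabilities PP.H0–PP.H4. All sums run in log
space (log-sum-exp); the tests confirm exact agreement with naive
summation where the naive form does not overflow. A variant pair is
declared colocalized when PP.H4 $> 0.6$.

## Multi-trait posterior

For a region tested across all traits simultaneously,
`multitrait_coloc()` factorizes the evidence into a regional posterior
$P_R$ (every trait has a causal variant in the region) and an alignment
posterior $P_A$ (given that, it is the same variant):

$$P_R = \prod_t \frac{\pi_1 S_t}{1 + \pi_1 S_t},\qquad
P_A = \frac{c\,C}{c\,C + d\prod_t S_t},$$

with $S_t = \sum_j A_{tj}$ the per-trait evidence, $C = \sum_j \prod_t
A_{tj}$ the shared-variant evidence, $\pi_1 = p_1 + p_{12}$, and
per-configuration priors $c = p_{12}$, $d = p_1^{T}$ for $T$ traits. This
is a deliberate, documented simplification of the branch-and-bound
multi-trait method it emulates: instead of exploring all trait subsets,
a greedy divisive step drops the (non-index) trait whose removal most
increases $P_R P_A$ and retries, until the set is accepted or only one
pair remains. The index trait is never dropped — an accepted set without
the disease anchor would not be a disease colocalization event. A set is
accepted when $P_R P_A > 0.60$ *and* every retained trait's association
p-value at the candidate shared variant is below $10^{-5}$ (the stricter
reading of the p-value gate; configurable). Concordance of the two-trait
special case with `coloc_abf` accept/reject decisions is part of the
acceptance suite.

## Staged region workflow

`run_region_workflow()` mirrors a staged analysis built for scale:

* **Stage A** — regions with a single conditionally independent signal
  are tested with the multi-trait posterior across all traits at once.
* **Stage B** — multi-signal regions, or regions with $P_R > 0.8$ that
  nevertheless failed the $P_R P_A$ rule, are fine-mapped per trait with
  `susie_rss()` and tested credible-set-pair by credible-set-pair
  against the index trait (`coloc_susie()`), so each independent signal
  gets its own colocalization decision.
* **Stage C** — when index-trait fine-mapping returns no credible sets,
  the single-causal-variant enumeration is the fallback.

Panels are palindromic-resolved before the workflow, so every emitted
lead variant is already strand-unambiguous and oriented; the event lead
is the index trait's top variant within the colocalized credible set
(stage B/C) or the shared-evidence argmax (stage A).

## Fine-mapping

`susie_rss()` fits a sum-of-single-effects model directly on the z scale
with unit standard errors — sufficient for colocalization decisions,
which never need effect sizes in trait units. For each of $L$ effects
(default 10) the LD-propagated contribution of the other effects is
removed from $z$, per-variant log Bayes factors are computed with prior
variance `prior_w` (default 25 on the $z^2$ scale, i.e. effects
detectable around $|z| \approx 5$), and the inclusion vector is their
normalized exponential. Iteration stops when no inclusion probability
moves by more than `tol` ($10^{-4}$). A 95%-coverage credible set is
reported per effect, discarded if its purity (minimum absolute pairwise
LD among members) falls below 0.5 or the effect's Bayes factor does not
exceed 1 — these conventions follow the fine-mapping literature and are
config-exposed, since the emulated study does not report its settings.
The residual adjustment uses the LD matrix exactly; handling mismatch
between summary statistics and an external LD panel is out of scope.

# Network clustering

## The sparse z matrix

Rows are colocalization-event lead variants, columns are non-index
traits. An entry carries the trait's z-score at the lead (oriented to
the index risk allele) only when that variant colocalized with the trait
*and* the association passes a sample-size-dependent gate:
$p < 5\times10^{-8}$ for GWAS above 60,000 samples, $p < 10^{-5}$ below.
Everything else is exactly 0 — the zeros are data ("no credible shared
signal"), so variant–variant Pearson correlations are computed over all
entries, zeros included.

## Edge threshold and communities

Following the emulated design, the edge cutoff is the *largest* value
$c$ such that the graph with edges $|r| \ge c$ leaves every vertex at
least one edge (`min_degree_threshold`; implemented as the minimum over
vertices of each vertex's best absolute correlation, provably equal to
the exhaustive scan and tested against it). Communities are found by
simulated annealing of the Reichardt–Bornholdt spinglass Hamiltonian
(igraph's implementation) on the surviving positively-weighted edges —
negative surviving weights are clipped to zero, as the spinglass null
model requires non-negative weights. The community count is emergent.
`n_restarts` seeded runs are scored by weighted modularity

$$Q = \sum_c \left[\frac{w_c}{W} - \left(\frac{d_c}{2W}\right)^2\right]$$

and the best partition wins. Disconnected components are annealed
independently; because a component-local null model provably over-splits
isolated components (a tiny positive within-component $Q$ beats the zero
of the unsplit component even when globally worse), a greedy merge pass
afterwards accepts exactly those merges that increase whole-graph
modularity. Clusters smaller than `min_cluster_size` (default 4) remain
in the membership but are excluded from the retained set used for
signatures and scores, mirroring how small uninterpretable clusters are
set aside in practice.

# Partitioned scores and MR

`build_prs()` forms the dosage-weighted sum over a cluster's variants
(weights are index-trait effect sizes on the effect-increasing
orientation) and standardizes within the scored sample; standardization
makes the association estimates scale-invariant in the weights.
Continuous outcomes are tested by OLS with covariates (age, sex, BMI,
cohort by default; BMI dropped when it is the outcome), binary outcomes
by logistic regression reported as odds ratios; both use Wald 95%
intervals and a Bonferroni flag at `alpha / m_tests` (0.05/6 = 0.008 in
the adult analyses this emulates, 0.05/3 = 0.017 pediatric).
`decile_contrast()` compares the top and bottom score tails with the
same covariates.

For MR, `ivw()` regresses outcome on exposure effects through the origin
with $1/se_y^2$ weights (fixed-effects by default; a multiplicative
random-effects switch exists), `egger()` adds a free intercept as a
pleiotropy test after orienting instruments to the exposure-increasing
allele, and `steiger()` infers direction by comparing the variance the
instruments explain in each trait, with per-variant $r^2 =
z^2/(z^2+n-2)$ — the exact $r^2$ identity for simple linear regression,
used here so the two-sample setting is self-contained — summed across
instruments, Fisher-transformed and compared by a normal test. When
per-variant sample sizes differ, the scalar $n$ in the Fisher variance is
their mean. Summed $r^2$ above 1 is capped with a warning.

# Synthetic data: what it emulates, and what it does not

Summary statistics are simulated at the level the pipeline consumes:
region z-vectors drawn from $N(R\lambda, R)$ for LD matrix $R$ and
non-centrality vector $\lambda$, with $\hat\beta = z/\sqrt{n}$,
$se = 1/\sqrt{n}$ on the standardized-trait scale. This is orders of
magnitude faster than phenotype-level simulation and exactly matches the
sufficient statistics of a GWAS under standard assumptions. LD is
block-diagonal AR(1) ($r_{ij} = \rho^{|i-j|}$, default $\rho = 0.8$),
positive definite by construction.

The default scenario (`default_scenario()`) mirrors the emulated study's
shape at desk scale: 12 regions of 150 variants; an index disease trait
plus six metabolic traits whose sample sizes straddle the 60,000
significance-gate threshold; three planted pathway clusters
(adiposity: BMI+, visceral fat+; lipid: triglycerides+, HDL−;
glycemic: fasting glucose+, HbA1c+) over regions 1–4, 5–7, 8–10, with a
two-signal region (4) exercising the fine-mapping stage and two null
regions; 5% of non-causal variants planted as ambiguous palindromic A/T
variants with allele frequency near 0.5. Planted causal variants use
$\lambda = 8$, a strong but ordinary GWAS signal.

Two design choices matter for the network stage and deserve emphasis.
First, every planted cluster signature spans at least two traits: a
single-trait signature makes member rows correlate at exactly $\pm 1$ by
algebra (two vectors sharing a single varying coordinate), which is a
degeneracy of the toy dimension, not a feature of real data — and the
glucose-driven cluster in the emulated study is indeed defined by
several glucose traits. Second, one region per cluster (and one variant
per cluster in `simulate_zmatrix()`) colocalizes with only part of its
pathway's signature. Real sparse colocalization maps always contain such
partially-supported loci, and they are what give the variant network a
moderately-correlated periphery; without them, every vertex's best edge
sits in the extreme upper tail of the correlation distribution, and the
highest min-degree-preserving cutoff prunes the cluster cores themselves.
With them, the cutoff settles around 0.6–0.7 — qualitatively matching
the moderate cutoff reported for the full-scale analysis — and the cores
stay dense.

What the generator does *not* emulate: realistic human haplotype
structure (LD is stylized AR(1)), ancestry stratification, imputation
error, sample overlap between trait GWAS, winner's-curse in the lead
table, and trait–trait phenotypic correlation beyond what shared causal
variants induce. Passing tests therefore demonstrate that the
implementation is correct and calibrated under the stated statistical
model, not that the pipeline is robust to the full messiness of
consortium data.

Cohorts for PRS validation are simulated with Binomial(2, EAF) dosages,
a continuous outcome `effect * standardized_true_score + covariates +
N(0,1)`, and a logistic binary outcome with a prevalence-setting
intercept.

# Numerical and design notes

* Coordinates are 1-based with closed intervals, the GWAS convention.
* Allele reconciliation tries identity and effect/other swap only;
  strand flips are never attempted because ambiguous palindromic
  variants are removed outright (with a max-$r^2$ proxy substituted for
  a removed lead when $r^2 > 0.8$). Variants with missing frequency are
  exempt from the palindromic rule but retained otherwise.
* Overlapping region specifications are processed independently;
  duplicate events rediscovered by overlapping specs are deduplicated by
  (region, lead, trait set).
* Ties at the network cutoff are kept ($\ge c$).
* `coloc_abf` regions with fewer than 2 variants, and harmonized panels
  with an empty variant intersection, are skipped with a logged reason
  rather than an error.
* Experiment problem sizes (200 calibration regions, 100 fine-mapping
  replicates, 50 cohorts of 20,000, 500 IVW replicates, the 12-region
  end-to-end scenario) are the package's chosen desk-scale study
  conditions; they complete in well under a minute each on one CPU.

# Known limitations

The multi-trait posterior is a greedy approximation, validated against
the pairwise enumeration rather than against an exhaustive subset
search; with many weakly-colocalized traits the greedy path can stop at
a local optimum. Fine-mapping assumes the LD matrix is the one the
z-scores came from. The spinglass stage is stochastic — seeds and
restarts make it reproducible, not deterministic in principle. Cluster
labels (adiposity, lipid, glycemic) are generator bookkeeping; on real
data, interpreting clusters requires external biological annotation,
which is out of scope.
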