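---
title: "Methods: multifunctionality indices, co-occurrence networks, and the complexity–function cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhizofun)
```

# Scope and model

rhizofun implements the analysis chain that connects a replicated field
design (treatments × replicate plots) to soil multifunctionality through
rhizosphere microbial data: ASV count tables for bacteria and fungi, a
samples × functions matrix of measured soil properties, and optional
phylogenies. The chain has four stages — multifunctionality scoring,
diversity/composition summaries, co-occurrence network complexity, and a
linking inference layer — plus a synthetic-data generator that provides
ground truth for validating all of them.

# Multifunctionality indices

Every measured function is min–max standardized over samples,
`STD = (X − X_min)/(X_max − X_min)`, so each column attains 0 and 1 and
units cancel. Three indices are derived:

* **single-function indices** — the standardized columns themselves;
* **AMI** — the per-sample mean of all standardized functions;
* **PMI** — the first five principal coordinates of Bray–Curtis distances
  between standardized function profiles.

Decisions taken where the procedure is underdetermined:

* **Constant function columns.** A constant column has no min–max image.
  Defaults abort (`degenerate = "abort"`) because silently dropping a
  column changes the AMI denominator invisibly; `"drop"` discards with a
  warning.
* **Bray–Curtis input for PMI.** Computed on the *standardized* matrix:
  raw functions mix units (g/kg, mg/kg, enzyme activities), for which
  Bray–Curtis is meaningless; standardized values are non-negative and
  commensurable.
* **Axis signs.** Principal-coordinate signs are arbitrary, so each PMI
  axis is oriented to correlate non-negatively with the AMI (exact ties
  broken by making the largest-magnitude function loading positive). PMI.1
  is therefore interpretable as increasing overall multifunctionality.
* **Negative eigenvalues.** Bray–Curtis is non-Euclidean; negative
  eigenvalues are dropped and their magnitudes reported. No
  Lingoes/Cailliez correction is applied — the retained leading axes are
  insensitive to it at these problem sizes and the uncorrected form is the
  common default.
* **C/N/P groups.** The element-cycle memberships (C = SOC, MBC, SSC;
  N = TN, AN, NN, MBN, Ure; P = TP, AP, MBP, ALP) follow the conventional
  reading of the twelve functions' chemistry; they are a configurable
  convention (`computeGroupAMI(group_map = ...)`), not a measurement.

# Diversity and composition

Counts are rarefied once to the minimum sample depth (a single seeded
draw, matching common practice, rather than an average over draws).
Richness is the observed-ASV count; Faith's PD is *rooted* (the minimal
spanning subtree includes the root path; unrooted trees are
midpoint-rooted with a message). The combined microbial diversity index
averages the min–max standardized bacterial and fungal richness — PD does
not enter it, as the index is defined on richness values; PD is reported
alongside. Genus-level composition pools ASVs by lineage (truncated
lineages become `unclassified_<deepest rank>`), and treatment effects on
Bray–Curtis composition are tested by single-factor PERMANOVA with whole
label permutation, `p = (#{F* ≥ F} + 1)/(n_perm + 1)`.

# Co-occurrence networks and complexity

Core ASVs (mean relative abundance > 0.5%, computed across **all** samples
jointly so there is one core per community type) are tested pairwise with
Spearman's rho (average ranks for ties) and the two-sided t approximation
on n − 2 degrees of freedom; perfect correlations map to the smallest
representable p. All pairs tested within one network form a single
Benjamini–Hochberg family (each network is its own inference); edges
require |r| > 0.70 and adjusted p < 0.01 by default. Both edge signs are
retained and the positive count reported separately — `positive_only =
TRUE` reproduces the stricter positive-edges-only reading.

Per-sample subnetworks are induced subgraphs on the ASVs with rarefied
count > 0 (no abundance threshold). Seven topology metrics are computed
with fixed, testable conventions:

* average path length on disconnected graphs averages over *connected*
  pairs only (keeps the metric finite);
* mean local clustering with degree < 2 nodes contributing 0;
* betweenness normalized by (n−1)(n−2)/2 so subnetworks of different
  sizes are comparable; defined as 0 for n < 3;
* empty graphs yield zeros with an `is_empty` flag.

The **complexity score** z-scores the seven metrics across subnetwork
records (constant metrics dropped with a warning), ordinates Euclidean
distances by principal coordinates — Euclidean is chosen because the
z-scored metrics are signed, which Bray–Curtis cannot accommodate — and
takes axis 1, oriented to correlate positively with average degree.

**Network scope.** The default builds one network per community type from
all samples, with `scope = "per_treatment"` building one network per
treatment and drawing each sample's subnetwork from its own treatment's
network (all topology records are still ordinated together so scores share
one scale). Treatment-contrast analyses use the per-treatment scope, which
matches how treatment-specific networks are constructed in field studies
of this design.

# Linking layer

Pearson/Spearman correlation matrices (t-approximation p-values, constant
columns flagged `NA` rather than silently zero), OLS regressions, Mantel
tests (upper-triangle Pearson r; one-sided permutation p by joint
row/column permutation), random-forest importance (out-of-bag permutation
%IncMSE, 500 trees, seeded), and piecewise path models. In the path model
all variables are z-scored so coefficients are standardized estimates;
the d-separation basis takes every non-adjacent pair with at least one
endogenous member (exogenous–exogenous pairs are excluded, as their
dependence is not a model claim), conditions on the union of both
variables' parents, and tests the partial regression coefficient of the
earlier variable in the causal order. Fisher's `C = −2 Σ ln p` is compared
to χ² with 2k degrees of freedom; a saturated model gives C = 0, df = 0,
p = 1. Direct, indirect (sum over directed paths of coefficient products)
and total effects are reported; exact collinearity among parents
(condition number > 1e8) is an error.

How "community composition" enters the linking layer is underdetermined in
field practice; `runPipeline()` uses axis 1 of the genus-level Bray–Curtis
ordination as the standard scalar summary, and the feature table is plain,
so any alternative can be substituted.

# The synthetic generator

`simulateDataset()` draws, in order: (1) log-normal baseline mean
abundances per ASV; (2) per-sample log-abundance deviations from a
multivariate normal whose correlation is block-diagonal — ASVs belong to
guild blocks spanning both kingdoms, with within-block correlation set by
the sample's treatment; (3) multinomial counts at the kingdom's library
size from the softmax of log-abundances (a Dirichlet overdispersion option
exists; the multinomial default keeps expected relative abundances exact);
(4) a latent per-sample connectivity equal to the treatment's block
correlation plus N(0, 0.02) jitter (fixed so connectivity varies within
treatment and regression across samples is possible); (5) twelve soil
functions, each its baseline plus `complexity_effect` × connectivity on
the function's own scale plus Gaussian noise. Function baselines are
order-of-magnitude plausible for a black-soil topsoil (e.g. SOC ≈ 19.2
g/kg, TN ≈ 1.4 g/kg); they are cosmetic, not fitted.

Default study conditions are three treatments (CK, SBSH, SBSF) × three
replicates, 120 bacterial and 60 fungal ASVs, libraries of 1500 and 800
reads, six guild blocks covering 60% of ASVs, and block correlations
(0.2, 0.8, 0.5) so the half-dose treatment carries the most tightly
coupled community. The desk-scale ASV and library sizes keep
reads-per-ASV, sparsity (roughly 40–50% zeros among core ASVs) and the
number of core ASVs surviving the 0.5% filter in a realistic regime while
letting the full pipeline run in well under a second. The block fraction
of 0.6 was fixed at design time by a power analysis: the number of truly
co-occurring pairs grows quadratically with the number of blocked ASVs,
and below roughly half coverage the contrast between block correlations
0.2 and 0.5 sits at the edge of detectability at ten replicates.

What the generator does **not** emulate: sequencing error, chimeras,
realistic taxonomies, compositional mean shifts between treatments (only
the correlation structure and the connectivity-driven functions respond
to treatment — genus-level PERMANOVA is null by construction), phylogenetic
signal in abundances, or plant phenotypes. Passing recovery tests
therefore demonstrates that the pipeline detects connectivity-mediated
effects when present and stays at nominal error rates when absent; it does
not validate taxonomic or compositional inferences on real data.

# Desk-scale network calibration

At ten replicates per treatment the two-sided t-approximation p for
Spearman r = 0.70 is 0.024, so the strict defaults (|r| > 0.70 with BH
q < 0.01 over hundreds of pairs) retain only near-perfect correlations —
at field scale this is exactly the conservatism intended, but at desk
scale it leaves treatment networks empty and the treatment contrast
undefined. The synthetic recovery analyses therefore use a documented
desk-scale calibration: per-treatment networks, |r| > 0.60, unadjusted
p < 0.05. At n = 10, pairs with latent block correlation 0.8 (Spearman
≈ 0.79) pass with high probability, 0.5 (≈ 0.48) occasionally, 0.2
(≈ 0.19) rarely, and null pairs at ≈ 6% — a graded response that makes
edge counts, and hence subnetwork complexity, increase with the
ground-truth correlation. The calibration was fixed from this power
reasoning before the validation suite was assembled and is not a
recommendation for field data, where the strict defaults remain the
package default.

Problem sizes used by the validation suite (chosen as the smallest sizes
at which each property is sharp): brute-force network equivalence on ≤ 10
ASVs × 12 samples; PERMANOVA size on 1000 simulations of 9 samples with
199 permutations; Mantel uniformity on 500 replicates of 8 samples;
treatment-ordering recovery on 50 generator seeds at 3 × 10 samples;
effect recovery on 100 seeds each for `complexity_effect` 2 and 0.

# Known limitations

* The Spearman edge test uses the t approximation throughout; exact
  permutation p-values for very small n are not implemented.
* PERMANOVA is single-factor (the supported designs are one-way); no
  strata or sequential terms.
* The path model is piecewise linear-Gaussian; no latent variables,
  correlated errors, or model search.
* Subnetwork presence is binary (count > 0 after rarefaction); a
  minimum-abundance presence threshold is deliberately not offered.
* The complexity score is relative to the set of records ordinated
  together; scores from different ordinations are not comparable.
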