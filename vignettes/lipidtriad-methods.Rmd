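---
title: "Methods: trans-compartment lipidomics of mother-milk-infant triads"
author: "lipidtriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-compartment lipidomics of mother-milk-infant triads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidtriad)
```

## The analysis in one paragraph

Direct-infusion mass spectrometry (DIMS) surveys the glycerides,
phospholipids and sterols of a sample as a list of *m/z* signals without
chromatographic separation. For a cohort of breastfeeding mother–infant
pairs sampled in three compartments (maternal plasma, milk, infant plasma),
the pipeline (i) annotates and normalizes those signals into per-compartment
relative-abundance matrices, (ii) contrasts mothers and infants per
variable, (iii) traces each infant-plasma candidate growth biomarker (CBM)
through the milk to the maternal circulation with a two-stage Pearson
correlation chain, (iv) bi-clusters the concatenated three-compartment
feature matrix with a Bayesian hierarchical clustering model (the latent
structure model, LSM), and (v) quantifies how strongly marker sets
concentrate inside the resulting clusters.

## Preprocessing model and conventions

**Annotation.** A peak at observed mass $m$ matches a library species with
theoretical ion mass $t$ when $10^6\,|m-t|/t \le 8$ ppm (relative to the
theoretical mass — the standard mass-accuracy convention; the window is
symmetric). Peaks matching nothing are removed. Peaks matching several
species are *isobars*: all species linked by any shared peak are merged into
one composite variable, labelled by the earliest library entry with the
remaining members recorded as alternates. The bundled library keeps
PE(37:1), an exact sum-composition isobar of PC(34:1) at $[M+H]^+$
760.5851, so composite handling is exercised by default; the consequence is
that the measured "PC(34:1)" variable carries a small PE contribution.

**Blank subtraction.** The mean intensity over all blank samples is
subtracted per variable and negative values are clipped to zero. The mean
(rather than, say, the median) is the conventional estimator; with the
default four blanks the difference is immaterial. Because one blank profile
serves all compartments, subtraction shifts per-compartment class means by a
small amount (about 0.3 % relative at the default 1 % blank level) — exact
class-mean recovery in round-trip checks therefore requires blanks off.

**Presence filter.** A variable is kept iff it is nonzero in *strictly more
than* 5 % of study samples ("more than" read literally). QC samples pass
through the pipeline but are excluded from presence assessment and all
statistics.

**Normalization.** Each sample is scaled to percent of its total signal,
separately per ionisation mode; rows of a normalized matrix sum to 100
within $10^{-9}$ relative tolerance. Stage order is fixed: subtract →
aggregate → filter → normalize. Filtering commutes with normalization
(positive scaling preserves zero patterns), so its placement only matters
relative to blank subtraction.

## Mother-infant comparison

Per shared variable, a two-sided Student t-test — paired by mother–infant
pair identifier by default, since the samples are biologically paired;
Welch's two-sample test is available by flag. The multiple-testing threshold
for these strongly dependent variables is $\alpha/\sqrt{m}$ (0.0014 at
$\alpha = 0.05$, $m = 1248$), applied as strict `<`. Zero-variance paired
differences are flagged `degenerate` instead of aborting: all-zero
differences give $p = 1$ (no effect), constant nonzero differences give
$p = \mathrm{NA}$ — synthetic edge cases must not kill a cohort run.
Variance at floating-point noise level (exactly shifted data) is treated the
same way. PCA is computed by SVD on centred, unit-variance-scaled variables
(scaling is the common metabolomics default; a raw-scale option is kept),
with a deterministic sign convention: the largest-magnitude loading of each
component is positive.

## Correlation chain

Stage 1 correlates the five CBMs — healthy growth: PC(34:1), PC-O(34:1);
poor weight gain: PC(38:4), PC-O(36:4), SM(34:2) — with every milk
variable. Milk variables with at least one $|r| \ge 0.5$ are selected
(the boundary is included; "above 0.5 or below −0.5" leaves the boundary
unstated, so inclusion is declared and configurable). Stage 2 correlates the
selected milk variables with all maternal variables; no maternal subset is
imposed. Correlations use pairwise-complete observations with at least 10
complete pairs, else the entry is reported missing; no significance test is
attached — the chain reports coefficients only.

## The latent structure model

The LSM is Bayesian hierarchical clustering under a Dirichlet-process
mixture with a multinomial data model, written from scratch in this package.

**Discretization.** The multinomial model needs categories. Each *variable*
is cut at its empirical tertiles across individuals (ties at an edge go to
the lower bin; a constant column collapses to category 0 with a warning;
quantile coding is invariant to monotone transforms). Binning per variable
removes the between-feature abundance scale, so clustering reflects
co-variation patterns. Both the analyte tree and the individual tree are
built from this per-feature coding: binning each *individual's* values
across features was considered and rejected, because between-feature
abundance differences span orders of magnitude and would reduce every
feature's category to its abundance rank, erasing exactly the structure the
model is meant to find.

**Model.** For a cluster of $n$ items over columns $j$ with $m$ categories
and symmetric Dirichlet prior $\beta$, the marginal likelihood of the
"one cluster" hypothesis is
$$p(D\mid H_1)=\prod_j \frac{\Gamma(m\beta)}{\Gamma(m\beta+n)}
  \prod_{v=1}^{m} \frac{\Gamma(\beta+c_{jv})}{\Gamma(\beta)}.$$
Leaves start with $d_i=\alpha$, $r_i = 1$. A candidate merge $k$ of nodes
$i,j$ has $d_k=\alpha\Gamma(n_k)+d_i d_j$,
prior merge probability $\pi_k=\alpha\Gamma(n_k)/d_k$, tree evidence
$p(D_k\mid T_k)=\pi_k p(D_k\mid H_1)+(1-\pi_k)p(D_i\mid T_i)p(D_j\mid T_j)$
and posterior merge probability
$r_k=\pi_k p(D_k\mid H_1)/p(D_k\mid T_k)$. The pair with the highest $r_k$
merges; ties break to the lexicographically smallest pair of node indices,
so the tree is fully deterministic. All products run in log space through
log-sum-exp and log-gamma. The root evidence equals the sum over all
tree-consistent partitions of their DPM prior mass times their product of
cluster marginals — the test suite verifies this against a brute-force
enumeration to $10^{-8}$ relative tolerance, and the $n=2$ closed form
$\pi = 1/(1+\alpha)$ exactly.

**Hyperparameters.** Concentration $\alpha = 1$ and $\beta = 1$ with three
bins by default; `optimize_concentration()` selects $\alpha$ on a grid by
root evidence (ties to the smallest value). Clusters are read by severing
edges with $r_k < 0.5$ and numbering clusters in left-to-right dendrogram
order. Trees export to Newick with $r_k$ as internal support values; colour
scales of heatmap renderings are out of scope.

**Feature subset.** The pipeline caps the LSM input at the
`lsm_max_features` most variable features across pairs (default 120, chosen
to keep a routine run interactive); the analysed feature set is explicitly a
configurable subset of all detected variables.

## Enrichment arithmetic

With $k$ markers among $N$ features, a cluster (or union of clusters) of
size $n$ is expected to hold $kn/N$ markers under uniform placement;
enrichment is $100\cdot\mathrm{observed}/\mathrm{expected}$ percent,
reported to the nearest integer with full precision retained. The worked
numbers: $5 \times 46/428 = 0.537$ (0.54 at 2 d.p.); four of five markers
observed is $744\,\%$; nine of eleven cholesteryl esters against
$11\times46/428 = 1.182$ is $761\,\%$ by direct arithmetic — a printed
value of $762\,\%$ arises when the expectation is rounded before dividing,
and both roundings bracket the same conclusion. An exact hypergeometric
upper tail accompanies each enrichment as the natural companion statistic.

## The synthetic cohort generator

The generator emulates what the analysis assumes about the data, not the
biology of any particular cohort.

* **Cohort shape.** 30 mother–infant pairs; maternal plasma, milk and
  infant plasma per pair; four blanks and two QC samples; positive and
  negative ionisation modes normalized separately.
* **Class profiles** (percent of per-mode total, summing to 100 per
  compartment and mode): milk configured at TG 80 %, SM 4 %, PC 0.25 %;
  maternal plasma TG 16.9 % vs infant 30.5 %; maternal CE 20 % vs infant
  13 %; negative-mode PG 9 % (maternal) vs 16.4 % (infant). Three species
  means are pinned: PC(34:1) 5.66/3.61, CE(18:2) 8.05/5.18, TG(52:2)
  2.74/4.23 (maternal/infant). Remaining within-class weights are drawn
  once per cohort from a flat Dirichlet for realistic dominance structure.
* **Noise.** Multiplicative log-normal, $\sigma = 0.25$ on the log scale —
  a standard model for MS intensities; no noise model is imposed by the
  data themselves, so the value is declared rather than estimated.
* **Planted structure.** Standard-normal latent factors per pair carry the
  chain correlations (default: three CBM → odd-chain milk TG/SM → maternal
  CE links at $r = 0.7$) and the feature blocks (default: the eleven
  maternal CEs at Gaussian loading 0.8). Loadings are solved from the
  bivariate log-normal closed form and additionally corrected for
  compositional closure (dividing by the sample total attenuates
  correlations by a per-variable factor $(1-w)/\sqrt{(1-w)^2+s}$, $w$ the
  species' share and $s$ the other species' summed squared shares); without
  the correction a planted $r = 0.7$ realizes near 0.68. Species carrying a
  planted loading are floored at an equal share of their class, because a
  biomarker drawn at a negligible Dirichlet weight would vanish below the
  blank level and the planted correlation would be unmeasurable. When a
  species carries both a chain and a block loading, the chain loading takes
  priority within the unit variance budget, which slightly weakens that
  member's block coherence and can push its milk–maternal link a few
  hundredths above target.
* **Artefacts.** Each TG spawns a DG−H₂O fragment peak (loss of a 16:0
  acyl) at 17.4 % of its intensity; on the milk profile this puts the
  water-loss signal at ≈ 12.2 % of the measured total and the total
  apparent DG fraction near 15 %, of which ~80 % is artefact. Note the
  consequence: the *measured* milk TG share is ≈ 70 % although the
  configured (pre-artefact) share is 80 % — both numbers are meaningful and
  they differ by construction. Blanks run at 1 % of the cross-compartment
  mean signal; *m/z* values are jittered uniformly within ±4 ppm so every
  true peak survives the 8 ppm window while exercising it.

What passing tests do **not** show about real data: the generator has no
biological covariance between lipid classes, no batch or drift structure,
no adduct chemistry beyond one fragment rule, and no relationship between
its latent factors and any phenotype; recovery of planted structure
demonstrates correctness of the machinery, not sensitivity in a real
cohort.

## Numerical and scale choices

Simulation sizes used by the test suite and the acceptance script — clusters
of 10 features over 30 columns for recovery, 100 cohort replicates at 30
pairs for chain power, 1000 pairs for correlation fidelity, 100 random
instances of up to 4 items for the enumeration oracle — were chosen as the
smallest sizes at which the statistical contracts are sharp. The Fisher-z
approximation serves as the analytic power oracle; at $n = 30$ it deviates
from the exact $t$ tail by roughly 13 % in the far tail, which the null
check absorbs with a four-standard-deviation binomial band.

## Known limitations

* Composite (isobar) variables inherit the class of their label species;
  mass belonging to the alternate species is attributed to that class.
* The ppm window is applied per peak against theoretical masses only; no
  isotope-pattern deconvolution or MS/MS identification is attempted.
* Greedy BHC explores one merge path; it is exact for the evidence of the
  tree it builds, not a search over all trees.
* The enrichment null assumes uniform marker placement and ignores the
  dependence induced by the clustering itself.
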