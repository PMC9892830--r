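---
title: "Models and methods behind gaclnm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gaclnm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaclnm)
```

This vignette explains the statistical models the package implements, the
choices made where the workflow it codifies left room for interpretation,
what the synthetic-data generator does and does not emulate, and the
numerical details a maintainer would want written down.

## The measurement model

TMT reporter intensities are strictly positive and, on the log2 scale,
approximately additive in their nuisance components. The package works
with the model

$$\log_2 x_{fs} \;=\; \mu_f + \ell_s + b_{B(s)} +
  \Delta_f\,\mathbf 1[\text{LNM tumor}] + \varepsilon_{fs},$$

where $\mu_f$ is the feature's baseline abundance, $\ell_s$ a per-sample
loading factor, $b_{B(s)}$ a per-batch multiplicative effect, $\Delta_f$
the group effect of interest and $\varepsilon$ measurement noise. Each
preprocessing stage removes one term:

1. **Upper-quartile normalization** removes $\ell_s$: every sample is
   divided by the 75th percentile of its present intensities (linear
   interpolation, present values only) and rescaled by the geometric mean
   of all samples' quantiles, so the output remains interpretable as
   intensity rather than a dimensionless ratio. Pure division would be
   equally valid; the rescaling is cosmetic and cancels in every
   downstream ratio. Within-sample ratios are preserved exactly.
2. **Internal-standard correction** removes $b$: each TMT batch carries a
   pooled reference channel, and every feature becomes a ratio to that
   channel within its batch. Because the reference is a physical pool of
   the batch's samples, it carries the batch effect exactly, and the
   ratio cancels it. The correction is ratio-to-reference per feature,
   not a per-sample total-intensity scaling — with one pooled channel per
   batch this is the only identifiable choice. A provenance tag enforces
   single application: after correction the IS columns are gone, so a
   second application would silently divide by a biological sample.
3. **Missing-value filtering** drops features missing in strictly more
   than half of the samples ("more than 50%" read literally: a feature
   missing in exactly half is kept). The denominator is all non-IS
   samples in the matrix, not per group, so a feature cannot survive on
   the strength of one well-observed group.

The stage order — quantile, IS, filter — is fixed by `preprocess()` and
matters: the filter must see the final sample set, and ratios should be
formed from loading-corrected values.

Zero intensity is rejected rather than treated as missing. A reporter
intensity of exactly zero indicates an upstream processing fault;
conflating it with "not measured" corrupts both the missingness model and
every ratio.

## Differential expression

Testing runs on log2 intensities, where the noise is closer to symmetric
and variance more nearly stable; the fold change is reported on the
linear scale as the ratio of group arithmetic means, because the 1.5 /
0.67 gates are linear-scale conventions. Per feature and group, a
Shapiro–Wilk test at $\alpha = 0.05$ screens normality: if both groups
pass, a Welch $t$-test (unequal variances — the safer default when only
"t-test" is specified); otherwise a Wilcoxon rank-sum test with normal
approximation and tie-corrected variance (no continuity correction).
Constant data in both groups short-circuits to $p = 1$. Features with
fewer than three present values in either group are skipped with reason
`insufficient_n`.

Normality is screened per group by default; a pooled screen
(`pooled_normality = TRUE`) is available, since two shifted normals pooled
can fail normality even when each group is clean.

Significance follows the discovery convention this pipeline codifies: raw
$p < 0.05$ **and** a fold-change gate. No multiple-testing correction
drives the call; a Benjamini–Hochberg column is emitted alongside for
users who want it. This is deliberate: the package reproduces the
procedure faithfully while exposing the better-calibrated quantity.

**Phosphosite adjustment** divides each site by its parent protein per
sample, so a site's fold change reflects phosphorylation stoichiometry
rather than protein expression. Sites whose parent is not quantified pass
through unadjusted and flagged — dropping them would silently bias the
kinase analysis toward well-expressed proteins.

## Trend clustering

Profiles are per-feature mean log2 intensities over the six
tissue-by-stage conditions (para-tumor I, II, III; tumor I, II, III),
standardized to mean 0, SD 1 — clustering then compares *shapes*, not
levels. Constant profiles carry no shape and are excluded.

Fuzzy c-means is implemented directly: memberships
$u_{ij} \propto \big(\sum_k (d_{ij}/d_{ik})^{2/(m-1)}\big)^{-1}$,
centroids as $u^m$-weighted means, iterated until the largest membership
change falls below $10^{-6}$ (cap 500 iterations). The defaults are six
clusters and fuzzifier $m = 2$, the common choice when nothing is known
about cluster compactness. Five seeded restarts are run and the best
final objective kept; the objective $\sum u^m d^2$ is asserted
non-increasing at every iteration, so a numerical fault fails loudly
rather than silently converging elsewhere. Two numerical details:
memberships are computed from distances normalized by the row minimum, so
fuzzifiers near 1 do not overflow, and a feature coinciding with a
centroid receives membership exactly 1 there. Cluster labels are
arbitrary; reports order clusters by trend class and size, and no code
should rely on label identity.

A centroid is `increasing` when it is monotone nondecreasing across tumor
I→II→III with total rise above $\tau = 0.5$ standardized units (mirrored
for `decreasing`). The threshold is in standardized units by
construction; 0.5 SD across three stages is a visible trend without being
trivially attainable by noise.

## Hub ranking

On the interaction subgraph induced on a protein set (edges kept at
confidence ≥ 0.7, the conventional "high confidence" cutoff — inclusive,
so 0.700 is in), each node's maximal clique centrality is
$\mathrm{MCC}(v) = \sum_{C \ni v} (|C|-1)!$ over maximal cliques $C$. An
isolated node's only maximal clique is itself, giving MCC 1. Enumeration
uses pivoting Bron–Kerbosch (via igraph), with a guard that aborts beyond
$10^6$ maximal cliques — the subgraphs this analysis produces are a few
hundred nodes at most, so hitting the guard means the input was not what
the method expects. Ties in the ranking break lexicographically by node
id, making reports deterministic. Edge scores arrive on either the unit
interval or the STRING 0–1000 dialect, selected by an explicit flag;
auto-detection is refused because a silently misread scale corrupts the
0.7 threshold.

## Kinase activity

**KSEA.** For kinase $K$ with $m$ usable substrate sites,
$z = (\bar s - \bar p)\sqrt{m} / \delta$ with $\bar s$ the mean substrate
log2 FC and $\bar p, \delta$ the mean and SD of all site log2 FCs;
$p = 2(1 - \Phi(|z|))$, BH-corrected across scored kinases. Predicted
links need NetworKIN score ≥ 2.5; curated links always count; substrates
are deduplicated per site; kinases with $m < 5$ are not scored. The site
fold changes fed in are the protein-adjusted ones by default — the same
section of the workflow that defines site DE normalizes to protein, and
kinase activity should not echo substrate-protein expression — but
unadjusted FCs can be supplied to the same function. A zero $\delta$
(all sites identical) is a hard error: the statistic is undefined, and
inventing a fallback would hide a broken input.

**ABPP.** Replicate columns are upper-quartile normalized and averaged
per biological sample; one missing replicate leaves the other as the
estimate. Differential testing is the $t$ branch with the same FC gates.
Sites quantified in at least two samples of one group and none of the
other are *group-exclusive*: with $n = 4$ per group, an on/off pattern
carries more information than any test statistic, and such sites are
reported as exclusivity calls rather than forced through a $t$-test.
`min_detected = 2` mirrors a two-of-four detection being treated as
evidence.

**Motifs.** Position frequency matrices are built per site class over
±7 residues around the modified lysine (the flank width is a package
default; the classes' −2 signature — alanine for the ATP-binding-site
lysine, aspartate for the active-site lysine — sits well inside any
reasonable window). Termini contribute nothing at out-of-range positions,
so each column's frequencies are normalized by its own contributing-site
count. Sites whose stated position is not a lysine in the supplied
sequence are skipped and reported, never silently dropped.

## Survival and clinical statistics

Kaplan–Meier, log-rank and univariate Cox (Efron ties, Newton–Raphson on
the partial likelihood; Breslow available) are delegated to the survival
package behind this package's tabular interfaces. Cohorts come from a
median split — strictly above the median is "high", ties at the median go
"low", per the strict reading of "higher than the 50th percentile"; with
RNA-seq-style ties this choice changes cohort sizes, so it is fixed and
documented rather than left to chance. For a two-gene panel, the high
cohort is the intersection of both genes' high cohorts (likewise low);
discordant samples are excluded. Under a bivariate-normal model with
correlation $\rho$, the excluded fraction is
$2(\tfrac14 - \arcsin(\rho)/2\pi)$, which the tests verify by simulation.

Clinical contingency tables use Pearson chi-square **without** continuity
correction — verified to be the only variant reproducing the published
stage ($p = 0.00006$), N-stage ($\chi^2 = 23.0$, $p = 0.00004$) and
T-stage ($p \approx 0.1415$) values — with all-zero factor rows pruned
before testing and degrees of freedom computed after pruning. The age
comparison uses a pooled-variance Student $t$ (the table's own label);
Welch is a switch.

## The synthetic-data generator

`simulate_study()` generates what the analysis assumes, plus ground
truth. Defaults are the study conditions: 11 noLNM and 12 LNM subjects,
paired tumor/para-tumor except one LNM subject tumor-only, so 45
biological samples plus 5 IS channels exactly fill five 10-plexes;
channel assignment is randomized per seed since the real channel layout
is not part of the design. Stage labels follow the clinical table's
pattern (noLNM subjects stage I/II, LNM subjects II/III). Protein
intensities follow the measurement model above with a subject-level
random effect shared between a subject's two tissues (the paired
structure exists in the data even though the group tests are unpaired).
The IS channel is the linear-scale mean of its batch's member samples — a
simplification of pooling an aliquot of every sample — chosen because it
makes the batch factor *exactly* removable, turning the batch-correction
test into an identity check rather than an approximation.

Defaults worth knowing (all log-scale parameters in log2 units):
2000 proteins (a scaled-down default that keeps simulation-heavy tests
fast while leaving thousands of null features; any size can be
requested), baseline $\mu_f \sim N(20, 2^2)$, loading SD 0.25, batch SD
0.5, subject SD 0.3, residual SD 0.4, 10% planted effects at FC 1.5
(half up, half down), Poisson(1) phosphosites per protein with
S/T/Y drawn 85/14/1, site noise 0.3, 20 kinases × 10 substrates with 3
active at +1 log2, ABPP four samples per group with replicate noise 0.15
and biological noise 0.3 — set so that a 2-fold activity shift is
reliably detectable at $n = 4$ — and a survival cohort of 200 with
hazards $\beta_1 = 0.7$, $\beta_2 = 0.4$ on two markers correlated at
0.5, 30% uniform censoring.

Missingness is MNAR: each cell is missing with probability
$\mathrm{logit}^{-1}(s\,(m_0 - \log_2 x))$ (midpoint $m_0 = 16$, slope
$s = 0.8$, ≈10% overall), because TMT missingness is
abundance-dependent and the 50% filter behaves differently under MNAR
than under MCAR; an MCAR admixture is available. One measurable
consequence: censoring the low tail inflates observed group means more in
the lower group, compressing realized fold changes of planted-up features
a few percent below the planted 1.5 — which is why recovery checks
average over seeds instead of asserting per-seed medians.

What the generator does **not** emulate: peptide-to-protein rollup,
isotopic impurity and ratio compression, correlated feature blocks beyond
the site–parent tethering, batch-varying missingness, or informative
censoring. Passing recovery tests therefore demonstrate that the
*statistics* do what they claim under the stated model, not that the
model captures every pathology of real TMT data.

Two recovery caveats found worth pinning down. First, univariate Cox on
marker 1 estimates $\beta_1 + \rho\,\beta_2$ when the two markers are
correlated — ordinary omitted-variable confounding, not a bug — so
parameter-recovery tests use configurations with $\beta_2 = 0$ and
$\rho = 0$, while the default keeps correlated markers for realism.
Second, a two-record Cox toy with two events has a monotone partial
likelihood and no finite maximum; the brute-force oracle test uses a
three-record toy with an interior optimum.

## Problem sizes and determinism

The test suite and acceptance script run simulations of 120–500 proteins,
50 samples, and 10–50 Monte-Carlo seeds per property — sizes chosen so
the full suite completes in well under a minute of simulation time while
keeping Monte-Carlo standard errors far from the asserted bounds.
Everything stochastic is seeded: `simulate_study()` is byte-identical
given its seed, `fuzzy_cmeans()` seeds its restarts, and the acceptance
script derives every sub-seed from its `--seed` flag.

## Known limitations

* DE is unpaired and covariate-free (no age/sex adjustment, no moderated
  variances); the tumor-vs-para-tumor pairing is available in the
  annotations but deliberately unused by the group contrast.
* `ora_enrich()` is a generic hypergeometric over-representation test
  over user-supplied GMT sets; it does not ship term catalogs.
* The cluster count is a parameter, not estimated; no cluster-number
  selection criterion is provided.
* Protein identifiers are opaque strings throughout — no mapping between
  gene symbols and accessions is attempted.
* `median_split()` errors on all-equal expression rather than guessing a
  cohort; panels with an empty high or low intersection are an error
  naming the empty arm.
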