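---
title: "Differential correlation metabolic networks for paired biofluids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential correlation metabolic networks for paired biofluids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmnet)
```

## The question the method answers

Targeted metabolomics panels measure the same metabolites in more than one
biofluid of the same subject — for example plasma and the joint (synovial)
fluid collected during knee arthroplasty. Mean concentration differences
between the fluids are dominated by filtration and transport; what they miss
is whether the *relationships between metabolites* change between
compartments. If two metabolites move together in plasma but decouple in
joint fluid, some process local to the joint is interfering with their shared
regulation. dcmnet quantifies exactly this: for every metabolite pair it asks
whether the Pearson correlation differs between the two compartments,
collects the significantly different pairs into a signed network, and ranks
metabolites by how central they are to that network.

## The differential correlation statistic

For metabolites $i$ and $j$, let $r_{\mathrm{plasma}}(i,j)$ and
$r_{\mathrm{JF}}(i,j)$ be the Pearson correlations computed over the
$n_{\mathrm{plasma}}$ plasma and $n_{\mathrm{JF}}$ joint-fluid samples.
Each correlation is stabilised with Fisher's transformation
$z = \tfrac12 \log\frac{1+r}{1-r}$, under which a sample correlation is
approximately normal with variance $1/(n-3)$. The differential correlation
statistic subtracts the JF correlation from the plasma one on this scale,
weighting each side by its information content:

$$
r_{\mathrm{diff}}(i,j) \;=\;
\sqrt{\tfrac{n_{\mathrm{plasma}}-3}{2}}\; z_{\mathrm{plasma}}(i,j)
\;-\;
\sqrt{\tfrac{n_{\mathrm{JF}}-3}{2}}\; z_{\mathrm{JF}}(i,j).
$$

With equal group sizes this is algebraically identical to the textbook
normal-deviate test for the equality of two independent correlations,
$(z_1 - z_2)\big/\sqrt{1/(n_1-3) + 1/(n_2-3)}$, so under the null of no
differential correlation it is approximately standard normal — a property
the test suite checks both algebraically (equivalence to machine precision)
and distributionally (Kolmogorov–Smirnov distance of null statistics to
$N(0,1)$). A positive value means the pair is more strongly correlated in
plasma; a negative value, in joint fluid. `r_diff(weighted = FALSE)`
exposes the unweighted difference $z_1 - z_2$ for sensitivity analysis only.

Correlations of exactly $\pm 1$ (possible in degenerate fixtures) are clamped
to $\pm(1 - 10^{-7})$ before the transform; this perturbs any realistic
statistic negligibly while keeping the arithmetic finite.

## Significance by permutation

The null hypothesis — compartment labels carry no information about the
correlation structure — is tested by permutation. One shared set of $B$
label shufflings (default $B = 1000$) is applied to all pairs; for each
shuffling the entire $r_{\mathrm{diff}}$ vector is recomputed, and the
two-sided p-value of a pair is

$$
p = \frac{1 + \#\{b : |r^{(b)}_{\mathrm{diff}}| \ge |r_{\mathrm{diff}}|\}}{B + 1},
$$

the add-one estimator, so $p \in [1/(B+1), 1]$, ties count against
significance, and type-I error is controlled without distributional
assumptions. Two shuffling schemes are offered. The default, `pooled`,
re-assigns all samples at random to two groups of the original sizes; it is
the standard global-null construction and requires nothing of the design.
`paired` swaps the plasma/JF labels independently within each subject, which
respects the within-subject sampling but requires both compartments for
every subject. Using one shared shuffling set for all pairs (rather than
per-pair shuffles) is the usual choice for correlation-matrix screens and
makes the cost $B$ correlation matrices instead of $B \cdot m(m-1)/2$
statistics.

Multiplicity is handled at two tiers. The *nominal* tier flags
$p < \alpha$ (default $0.05$). The *adjusted* tier applies Bonferroni
($p < \alpha / \#\text{pairs}$; for a 167-metabolite panel that is
$0.05/13861 \approx 3.6 \times 10^{-6}$) or Benjamini–Hochberg. A
$B$-fold permutation p-value cannot fall below $1/(B+1)$, so with
$B = 1000$ the Bonferroni threshold for thousands of pairs is unreachable;
`adjust_significance()` warns loudly in this situation instead of silently
returning an empty tier, and the warning states the two numbers being
compared. Reaching the Bonferroni tier honestly requires on the order of
$B \ge 20\,\#\text{pairs}/\alpha$ permutations or an analytic approximation;
we deliberately keep the permutation p-value as the primary inferential
object and treat the adjusted tier as a stringency dial.

## Preprocessing

Two rules, both standard for targeted panels, precede all statistics:

* **Detection filter.** A metabolite is kept only if it is measured in
  strictly more than `min_detection` (default 80%) of the stratum's samples,
  plasma and JF pooled. Pooling keeps one common metabolite list per
  stratum, which the paired analysis requires.
* **Half-minimum imputation.** Remaining missing values — interpreted as
  below the limit of detection — are replaced by half the minimum observed
  value of that metabolite, again pooled across the stratum. Pooling keeps
  both compartments on the same concentration floor.

The filter is strict ("more than"), idempotent, and order-preserving; the
boundary case (exactly 80% detection is dropped) is pinned by a test. Zeros
are treated as valid measurements unless `zero_as_missing = TRUE`, for
vendors that encode below-LOD as 0. Sex strata are processed independently
throughout; there is no pooled-sex mode.

## The network and its hubs

Edges of the differential correlation network are exactly the pairs
significant at the chosen tier; nodes are the metabolites incident to at
least one edge, so metabolites with no differential edge do not appear and
the node count can be well below the panel size. Edge sign is the sign of
$r_{\mathrm{diff}}$ (positive conventionally drawn red, negative blue).
Mean degree is $2E/N$ by construction and the summary reports it from the
built graph, never from a separate tally.

Centralities use hop counts (edge weights and signs are ignored for paths,
as nothing in the statistic makes a strong differential correlation a
"shorter" route): degree; betweenness normalised by $(n-1)(n-2)/2$; and
closeness in the Wasserman–Faust form — within-component closeness scaled
by $(\text{component size}-1)/(n-1)$ — so values are comparable across
components of a disconnected network and bounded by $[0,1]$. All three are
verified against an exhaustive path-enumeration oracle on hundreds of random
small graphs.

A node is a *core metabolite* (hub) when its degree reaches the 90th
percentile of node degrees and at least one of betweenness or closeness
reaches its own 90th percentile (`combine = "and"` requires both). No
standard numeric definition of "high centrality" exists, so the rule is a
quantile cut with two deliberate choices. First, thresholds use the
median-unbiased sample quantile (`type = 8`): degree distributions of these
networks are heavily right-skewed, and the common `type = 7` quantile of,
say, a star graph's degrees collapses onto the leaf value, which would make
every node a "hub". Second, ties at the threshold are included by default
(`ties = "include"`); `ties = "strict"` requires exceeding the threshold,
under which a perfectly regular graph has no hubs. Both knobs are exposed
because hub sets, unlike the statistics, are definition-sensitive; the
defaults reproduce the qualitative picture of a handful of hubs among
~100–150 nodes.

Networks export to GraphML (lossless round trip, all attributes), SIF with
`pos_dc`/`neg_dc` interaction types plus a node-attribute table
(Cytoscape-friendly), and a plain edge table. Node order is lexicographic
everywhere, so re-running a seeded analysis reproduces every output file
byte for byte.

## The synthetic cohort generator

No raw concentrations accompany the study design this package targets, so
validation rests on a generator with known ground truth,
`synthetic_spec()` + `generate_cohort()`. Its defaults describe an
arthroplasty-style cohort: 50 subjects per sex stratum, each contributing
one plasma and one JF sample; a 186-metabolite panel composed of 90
glycerophospholipids, 40 acylcarnitines, 21 amino acids, 19 biogenic
amines, 15 sphingolipids and one hexose; subject age near 65 ± 8 years and
BMI near 32 ± 6 kg/m² with small per-sex differences.

Concentrations are lognormal: latent Gaussian vectors with a per-compartment
correlation matrix are exponentiated around metabolite-specific medians
(log-uniform between 0.1 and 100 concentration units, log-SD 0.5). The
latent correlation matrix shares a within-class backbone ($r = 0.5$ by
default, 0 between classes) in both compartments and differs *exactly* at
the planted differential pairs — by default 10 pairs at
$r_{\mathrm{plasma}} = 0.7$ versus $r_{\mathrm{JF}} = 0.1$, the
$\Delta r = 0.6$ condition used by the recovery tests. Planted metabolites
are decoupled from their class backbone (identically in both compartments)
and form their own correlation block: this keeps the targets exactly
realizable, since splicing a strong cross-class link into an
equicorrelated block otherwise makes the matrix indefinite and the
nearest-PSD repair would silently shrink the planted effect. Any remaining
indefiniteness (possible with user-supplied targets) is repaired by
`nearest_psd()` — eigenvalue clipping with unit-diagonal rescaling — and
the generator refuses targets whose repair moves any entry by more than 0.1.

Missingness mimics below-LOD dropout: the lowest `lod_missing_rate`
fraction (default 5%, consistent with panels where over 90% of metabolites
are successfully measured) of each metabolite's values in each
stratum-compartment block is censored. Nineteen randomly chosen metabolites
are instead censored at 40%, so the 80% detection filter removes them and a
186-metabolite panel yields the familiar 167 retained metabolites and
$\binom{167}{2} = 13\,861$ pairs. Rank-based censoring makes the realized
rate essentially exact.

Because Pearson targets live on the latent log scale, observed-scale
correlations are attenuated by the lognormal transform (about 0.03 at
$r = 0.5$ for log-SD 0.5). Convergence of generated data to its targets is
therefore asserted on the log scale, and recovery of planted pairs is
asserted through ranks and p-values, not through exact observed $r$ values.
One seed governs everything; the generator never reads or perturbs the
global RNG state, and equal seeds give bit-identical cohorts.

What the generator does *not* emulate: instrument batch effects and drift,
within-subject plasma–JF coupling (compartments are drawn independently,
so the `paired` permutation scheme sees no extra within-subject
correlation), heavy-tailed contamination, and the real study's unknown
covariance. Passing tests on this generator therefore demonstrate
statistical correctness and calibration of the machinery, not that any
particular biological network will be recovered from real data.

## Numerical and design choices collected

* Detection threshold comparison is strict (`> 0.8`), matching the
  "more than 80%" convention; applied per sex stratum by default.
* Correlation clamping at $1 - 10^{-7}$; Fisher transform via `atanh`.
* Permutation p-values use the add-one estimator; ties count as exceeding.
* Zero-variance metabolites (possible after aggressive imputation) are
  dropped with a warning rather than failing the run.
* Stratum $k$ of a pipeline run uses `seed + k − 1`, so strata are
  independent but the whole run is reproducible from one seed.
* Problem sizes in the test suite are chosen to make Monte-Carlo noise
  small relative to the asserted tolerances: null calibration uses 20
  independent-metabolite cohorts (20 metabolites, 50+50 samples, $B=500$),
  planted-pair recovery uses three 30-metabolite cohorts with ten
  $\Delta r = 0.6$ pairs each, and the distributional check uses 5,050
  null pairs at 100 samples per compartment.

## A worked run

```{r example, eval = FALSE}
library(dcmnet)

cohort <- generate_cohort(synthetic_spec(seed = 1))
out <- run_dcm_pipeline(
  cohort$concentrations, cohort$design, "dcm-results",
  classes = cohort$classes, B = 1000, seed = 1
)
out

res <- attr(out, "results")$female
glance(res$diffcorr)               # pair counts, significance by sign
tidy(res$networks$nominal)         # node table with centralities and hubs
autoplot(res$diffcorr)             # plasma-vs-JF correlation scatter
plot_centralities(res$networks$nominal)
```

## Limitations

* The permutation floor makes the Bonferroni tier unreachable at the
  default $B$; the package warns rather than substituting analytic
  p-values, which are deliberately out of the primary path.
* Hub calls depend on the quantile definition; treat hub lists as a ranked
  shortlist, not a sharp classification.
* Pearson correlations on concentrations are sensitive to heavy tails;
  no rank-correlation option exists in this version.
* Compartment independence in the generator means the `paired` scheme's
  advantages on real (within-subject correlated) data are not exercised by
  the test suite.
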