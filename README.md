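# dcmnet — differential correlation metabolic networks for paired biofluids

`dcmnet` asks a question that mean-difference metabolomics misses: for every
pair of metabolites measured in two compartments of the same subjects (for
example plasma and knee joint fluid), **does the correlation between the two
metabolites change between compartments?** Pairs whose correlation changes
significantly are assembled into a signed *differential correlation
metabolic (DCM) network*, and the metabolites most central to that network —
the "core metabolites" — are identified by degree, betweenness and closeness
centrality. The package is aimed at analysts of targeted metabolomics panels
(e.g. 186-metabolite p180-style kits) with paired two-compartment designs.

## The statistic

For metabolites $i, j$ with Pearson correlations $r_{\mathrm{plasma}}$ and
$r_{\mathrm{JF}}$ over $n_{\mathrm{plasma}}$ and $n_{\mathrm{JF}}$ samples,
each correlation is Fisher-transformed, $z = \tfrac12\log\frac{1+r}{1-r}$,
and the differential correlation statistic is the weighted difference

$$
r_{\mathrm{diff}} =
\sqrt{\tfrac{n_{\mathrm{plasma}}-3}{2}}\,z_{\mathrm{plasma}} -
\sqrt{\tfrac{n_{\mathrm{JF}}-3}{2}}\,z_{\mathrm{JF}},
$$

which for equal group sizes is exactly the classical normal-deviate test for
equality of two correlations and is approximately $N(0,1)$ under the null.
Significance is assessed by a $B$-fold permutation of compartment labels
(default $B = 1000$, add-one two-sided p-values), with Bonferroni or
Benjamini–Hochberg control across all $\binom{m}{2}$ pairs. Preprocessing
follows panel conventions: metabolites detected in more than 80% of samples
are retained, and below-detection values are imputed with half the
metabolite's minimum observed value.

A synthetic cohort generator with planted ground truth (correlation
backbone, differentially correlated pairs, below-LOD censoring,
low-detection metabolites) makes every stage testable without access to
patient data; see the methods vignette in `vignettes/`.

## Worked example

```r
library(dcmnet)

# a paired two-compartment cohort: 50 subjects per sex stratum, 186-metabolite
# panel, 10 planted differentially correlated pairs (delta r = 0.6)
cohort <- generate_cohort(synthetic_spec(seed = 1))

out <- run_dcm_pipeline(
  cohort$concentrations, cohort$design, "dcm-results",
  classes = cohort$classes, B = 1000, seed = 1, strata = "female"
)
#> [dcmnet] stratum 'female': 50 plasma + 50 JF samples, 167/186 metabolites retained
#> [dcmnet] stratum 'female': 691/13861 pairs significant (373 positive, 318 negative);
#>          network 164 nodes / 691 edges, mean degree 8.43, 16 hubs
```

The 186-metabolite panel loses its 19 low-detection metabolites to the 80%
filter, leaving 167 metabolites and 13,861 pairs. At the nominal 0.05 level,
691 pairs are differentially correlated (373 stronger in plasma, 318
stronger in joint fluid); the network over them has 164 nodes, 691 edges and
mean degree 2·691/164 = 8.43. Node-level results are tidy tibbles:

```r
res <- attr(out, "results")$female
nodes <- tidy(res$networks$nominal)
head(nodes[order(-nodes$degree), ], 5)
#> # A tibble: 5 × 6
#>   metabolite class               degree betweenness closeness is_hub
#>   <chr>      <chr>                <dbl>       <dbl>     <dbl> <lgl>
#> 1 AA_014     amino acid              44      0.145      0.516 TRUE
#> 2 AA_007     amino acid              31      0.0762     0.471 TRUE
#> 3 PC_066     glycerophospholipid     26      0.0539     0.448 TRUE
#> 4 AC_027     acylcarnitine           25      0.0488     0.450 TRUE
#> 5 BA_012     biogenic amine          24      0.0515     0.452 TRUE
```

The top metabolite touches 44 differential edges and carries the largest
betweenness — information flow in the differential network concentrates on
it. `autoplot(res$diffcorr)` draws the plasma-vs-JF correlation scatter,
`autoplot(res$networks$nominal)` the signed network (red = stronger in
plasma, blue = stronger in JF), and `plot_centralities()` the
centrality-vs-degree panels used to pick core metabolites. Each stratum's
outputs (pair table with run metadata, GraphML/SIF/edge-table exports at the
nominal and Bonferroni tiers, node and hub tables, JSON manifest and
summary) are written under `dcm-results/`; re-running with the same seed
reproduces them byte for byte.

A thin command-line wrapper with `simulate`, `run` and `network` subcommands
lives at `inst/cli/dcmnet.R`.

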