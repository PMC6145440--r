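# fgmhybrid

Hybrid fitness landscapes under Fisher's geometric model.

## The problem

When two diverged populations hybridize, some crosses show hybrid vigor
(crop line crosses), others severe breakdown (species crosses), and many
natural hybrid zones sit in between. `fgmhybrid` is for population and
speciation geneticists who want one quantitative framework for this whole
continuum. It summarises any diploid hybrid by two genome-wide
coordinates — the hybrid index *h* (fraction of alleles from parent P2 at
divergent sites) and the interpopulation heterozygosity *p12* (fraction of
divergent sites with one allele from each parent) — and predicts the
expected "breakdown score" *f* of that hybrid class from Fisher's model of
optimizing selection on *n* quantitative traits:

    f = fP1 + beta1 * h * (1 - beta2 * h) - p12

with `beta1 = 4 - 2*fP1` and `beta2 = (4 - fP1 - fP2) / (4 - 2*fP1)`,
where `fP1`, `fP2` are the parents' own scaled breakdown scores and
fitness declines as `ln w = -k * f^(alpha/2)`. Optimal parents
(`fP = 0`) give `f = 4h(1-h) - p12` — disruptive selection on ancestry,
directional selection for heterozygosity. Fully uncoadapted divergence
(`fP = 2`) gives `f = 2 - p12`, Wright's classical single-locus
inbreeding prediction. The same surface arises from a multilocus
Dobzhansky–Muller incompatibility model under partial recessivity, and
the package ships that equivalence as a severity preset.

Around the core landscape the package provides:

- a forward simulator of parental divergence and hybrid genotypes in
  trait space, validating the closed form (`draw_substitutions`,
  `simulate_class`, `bridge_validation_grid`);
- the incompatibility formulation and snowball contrast
  (`expected_dmi_breakdown`, `snowball_count`);
- sex-chromosome extensions: Haldane's rule, backcross-male selection on
  heterozygosity, paternal-X silencing and cricket-style cross tables
  (`haldane_gap`, `backcross_male_selection`, `cross_prediction_table`);
- ancestry estimation from diagnostic marker tables with the standard
  filtering and QC steps, and CDS-based X weights from GFF3/GTF
  (`individual_coords`, `diagnostic_markers`, `gx_from_annotation`);
- GLM estimation of the fitness surface with AIC model selection,
  profile confidence intervals, nested hX-interaction models, signed-rank
  heterozygosity tests and McFadden pseudo-r² (`fit_surface`,
  `profile_ci`, `hx_interaction_fit`, `wilcoxon_het`);
- a seeded synthetic-data generator with the Mendelian structure of
  F1/F2/backcross and wild-hybrid designs (`synth_scenario`,
  `generate_cross_dataset`, `generate_wild_dataset`).

## Worked example

Predict the landscape, check the classical F2 yield prediction, then
recover the surface from synthetic wild hybrids end to end:

```r
library(fgmhybrid)

params <- landscape_params(fP1 = 0, fP2 = 0)
params
#> Hybrid breakdown landscape parameters
#>   fP1 = 0, fP2 = 0
#>   beta1 = 4, beta2 = 1

expected_breakdown(fgm_coords(h = c(0.5, 0.5, 0.25),
                              p12 = c(0, 1, 0.5)), params)
#> [1] 1.00 0.00 0.25
```

The worst class (`h = 0.5, p12 = 0`) scores 1, the F1 scores 0, a
typical first-backcross class 0.25. In the single-locus limit the scaled
excess yield of an F2 equals its expected heterozygosity:

```r
excess_yield_ratio("F2", fP = 2, map = fitness_map(alpha = 2),
                   mode = "analytic")
#> [1] 0.5
```

Now simulate 800 wild hybrids genotyped at 600 diagnostic markers, with
binary survival generated from the optimal-parents landscape through a
logistic link (slope 3), estimate each individual's coordinates from its
markers, and fit the surface:

```r
sc <- synth_scenario(d = 600, crosses = c(F2 = 1), family = "binomial",
                     response_scale = 3, seed = 42)
wild <- attach_fitness(generate_wild_dataset(sc, N = 800), sc)
co <- individual_coords(wild)
fit <- fit_surface(data.frame(h = co$h, p12 = co$p12,
                              fitness = wild$individuals$fitness),
                   family = "binomial")
fit
#> Hybrid fitness surface fit (binomial family, n = 800)
#>   selected terms: p12, h, hh
#>   AIC = 1009.88, logLik = -500.94, McFadden r2 = 0.053
#>   beta0 = 3.628, beta1 = 3.954, beta2 = 0.9878

profile_ci(fit, "beta2")
#>     lower     upper
#> 0.9460881 1.0320344
```

Model selection keeps all three terms; `beta0 > 0` says heterozygosity
is beneficial, `beta1` is near its optimal-parents value of 4, and
`beta2` is near 1 (symmetric disruptive selection on ancestry) with a
profile interval covering the generating value. Sex linkage comes for
free: with 37% of divergent sites X-linked, the expected extra breakdown
of the heterogametic F1 — Haldane's rule — is

```r
haldane_gap(genome_partition(gX = 0.37, system = "XO"))
#> [1] 0.2331
```

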