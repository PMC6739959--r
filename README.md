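# MorphoIntegr

Landmark-based geometric morphometrics and phenotypic integration for 2D
shape data, with phylogenetic comparative methods and a fully documented
synthetic data generator.

MorphoIntegr is self-contained (base R, `stats`, `MASS`, `ape`,
`jsonlite`) and implements the complete analysis chain for a comparative
study of two anatomical structures across species in two ecological groups:

- **I/O** — TPS files (exact round-trip), coordinate CSV, semilandmark
  slider tables, specimen metadata tables, Newick trees, all with strict
  validation and informative errors (`readTPS`, `readSliderTable`,
  `readNewick`, `writeStudy`, …).
- **Superimposition** — generalized Procrustes analysis with optional
  semilandmark sliding by minimum bending energy (`BEN`) or minimum
  Procrustes distance (`PRD`), ordinary Procrustes alignment, Procrustes
  distance, measurement-error decomposition (`gpa`, `alignOptimal`,
  `measurementError`).
- **Thin-plate splines** — TPS fitting and evaluation, analytic Jacobian
  log-determinant fields with fold detection, bending-energy spectrum,
  partial-warp scores (`fitTps`, `jacobianLogDetField`, `bendingSpectrum`,
  `partialWarpScores`).
- **Ordination** — between-group PCA (`bgPCA`).
- **Linear models** — multivariate models evaluated by residual
  randomization (RRPP) with sequential sums of squares; Procrustes ANOVA,
  evolutionary allometry, size correction, morphological disparity
  (`rrppModel`, `procrustesAnova`, `evolutionaryAllometry`, `sizeCorrect`,
  `morphologicalDisparity`).
- **Integration** — two-block PLS with permutation tests and effect sizes,
  comparison of integration strength (`comparePls`) and direction
  (`compareMaSlopes`), and the global-integration test based on regressing
  log partial-warp variance on log bending energy
  (`twoBlockPls`, `globalIntegrationSlope`, `compareGlobalIntegration`).
- **Phylogenetics** — Brownian-motion covariance, multivariate K
  phylogenetic signal, phylogenetic ANOVA, phylogenetic PLS
  (`bmCovariance`, `kmult`, `phyloAnova`, `phyloPls`).
- **Synthetic data** — a generative model with controllable group mean
  offset, disparity ratio, integration strength per group, allometry,
  spectral exponent and measurement error, on simulated phylogenies
  (`generatorConfig`, `simulateSpeciesShapes`, `simulateSpecimens`,
  `simulateWarpSample`, `simulateCorrelatedBlocks`, `simulateTree`).
- **Pipeline** — `runFullAnalysis()` chains everything and can write CSV
  summaries plus a provenance JSON.

## Worked example

Simulate a 37-species study (two lifestyles arranged as clades on a
birth–death tree, stronger latent integration in the subterranean group),
then run the core analyses:

```r
library(MorphoIntegr)

cfg <- generatorConfig(seed = 1, groupAssignment = "clade",
                       integrationRho = c(subterranean = 0.9,
                                          "non-subterranean" = 0.4))
sim <- simulateSpeciesShapes(cfg)
table(sim$species$group)
#> non-subterranean     subterranean
#>               21               16

# GPA with bending-energy semilandmark sliding
tpl <- makeTemplate("humerus36")
al  <- gpa(sim$humerus$means, sliders = tpl$sliders, method = "BEN")
al
#> AlignedShapes: 37 specimen(s), 36 landmarks
#>   sliding: BEN | iterations: 21 | converged: TRUE
#>   centroid size range: [0.9955, 1.156]

# lifestyle differences in mean shape
Yh <- t(apply(coords(al), 3, c))
g  <- sim$species$group
anovaTable(procrustesAnova(Yh, g, nperm = 999, seed = 1))
#>        term Df        SS         MS       Rsq        F        Z     P
#> 1     group  1 0.4040944 0.40409445 0.2800667 13.61561 3.720583 0.001
#> 2 Residuals 35 1.0387565 0.02967876 0.7199333       NA       NA    NA
#> 3     Total 36 1.4428510         NA        NA       NA       NA    NA

# disparity: the non-subterranean group is far more variable
morphologicalDisparity(Yh, g, nperm = 999, seed = 1)
#> Procrustes variance by group:
#> non-subterranean     subterranean
#>          0.04142          0.01056
#> Pairwise permutation p-values:
#>                  non-subterranean subterranean
#> non-subterranean               NA        0.002
#> subterranean                0.002           NA

# humerus-mandible integration across all species
alm <- gpa(sim$mandible$means,
           sliders = makeTemplate("mandible38")$sliders, method = "BEN")
Ym  <- t(apply(coords(alm), 3, c))
twoBlockPls(Yh, Ym, nperm = 999, seed = 1)
#> Two-block PLS: r-PLS (axis 1) = 0.8115, p = 0.001
#>   effect size z = 8.304 (se 1)

# ... which disappears once shared ancestry is accounted for
rownames(Yh) <- rownames(Ym) <- sim$species$species
phyloPls(Yh, Ym, sim$tree, nperm = 999, seed = 1)
#> Two-block PLS: r-PLS (axis 1) = 0.4147, p = 0.66
#>   effect size z = -0.5124 (se 1)

# global integration within the humerus
globalIntegrationSlope(coords(al), bendingSpectrum(tpl$template))
#> Global integration: slope = -1.033 -> self-similar
```

The contrast between the raw PLS (r = 0.81, p = 0.001) and the
phylogenetic PLS (p = 0.66) is the package's central use case: apparent
integration across species can be an artifact of shared ancestry, and
disentangling the two requires both analyses.

`runFullAnalysis(cfg, nperm = 999, seed = 1, outDir = "results/")` runs
the same study end to end — including size-free re-analysis, per-group
PLS, integration-strength and direction comparisons, phylogenetic signal
and a BEN-versus-PRD sliding sensitivity table — and writes CSV summaries
with a provenance JSON.

## Testing and reproduction

Run the full test suite against the installed package:

```r
testthat::test_dir("tests/testthat", package = "MorphoIntegr",
                   load_package = "installed")
```

`tests/testthat/test-acceptance.R` contains the end-to-end statistical
checks: analytic anchors of the global-integration slope, oracle
equivalences (OPA vs a brute-force rotation grid, RRPP vs closed-form
ANOVA, the Parseval identity of partial warps, analytic vs numerical TPS
Jacobians, star-tree identities for K and phylogenetic PLS), type-I error
calibration of every permutation test, recovery of generator parameters,
and the qualitative finding pattern of the default study configuration.

The same quantities can be recomputed and exported as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## License

MIT (see `LICENSE`).
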