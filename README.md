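# exurbia

Low-density housing beyond the urban fringe ("exurban development") is one
of the fastest-growing forms of land-use change in North America, and forest
birds are sensitive to it even at very low densities. Whether the *spatial
arrangement* of that development matters — scattered houses versus clustered
blocks — is harder to ask, because it needs a pattern metric on classified
imagery, survey counts cleaned of observer artefacts, and a
threshold-detection method along the resulting gradient. `exurbia` packages
that whole chain for landscape ecologists and avian monitoring analysts, and
ships a synthetic-data generator with known ground truth so every stage is
testable without any proprietary imagery or survey download.

## What it computes

* **MSPA** — morphological spatial pattern analysis of a binary raster into
  Core, Islet, Edge, Perforation, Bridge, Loop, Branch (erosion + geodesic
  dilation + connectivity analysis; 8-neighbour rule, edge width 1 by
  default), verified against a brute-force oracle on all 65,536 binary 4x4
  grids.
* **Compactness index** — within a buffer around a survey stop,
  `100 x (1 - Islet exurban pixels / all exurban pixels)`: 0% = fully
  dispersed housing, 100% = fully clumped; undefined where no development
  exists.
* **Landscape predictors** — percent forest, percent exurban, forest
  patches > 0.45 ha, forest edge length, and Moran's I autocorrelation
  screening with a permutation test.
* **Count adjustment** — a hierarchical over-dispersed Poisson model,
  `log(mu_it) = beta0_stop + beta1_stop*Year_t + beta2*FirstYear_it +
  Route_it + Observer_it + Error_it`, fitted by MCMC (JAGS), checked with
  split R-hat, and summarised as observer-standardised expected counts.
* **TITAN** — threshold indicator taxa analysis from scratch: per-species
  change points along the compactness gradient with permutation z-scores,
  a max-statistic permutation p, and bootstrap purity / reliability /
  change-point quantiles.
* **Loess screen + GAMs** — nonlinearity screening and Gaussian additive
  models (GCV-selected smooths) with backward AIC selection against forest
  loss and fragmentation predictors.
* **Synthetic scenarios + pipeline** — landscapes with controllable islet /
  block mixtures and temporal infill, counts simulated from the
  hierarchical model with planted step responses, and `run_pipeline()`
  producing composition, TITAN and GAM report tables with provenance.

## Worked example

A dispersed and a clumped landscape, and what the index says about them:

```r
library(exurbia)

g <- matrix(FALSE, 30, 30)
g[cbind(seq(2, 29, 3), seq(2, 29, 3))] <- TRUE   # 10 isolated pixels
dispersed <- binary_landscape(g, pixel_size = 30)
cm <- classify_mspa(dispersed, mspa_config(connectivity = 8, edge_width = 1))
class_summary(cm)
#>          class count area_ha
#> 1   BACKGROUND   890   80.10
#> 2         CORE     0    0.00
#> 3        ISLET    10    0.90
#> ...
compactness_index(cm, matrix(TRUE, 30, 30))
#> [1] 0            # every developed pixel is an islet: fully dispersed

g2 <- matrix(FALSE, 30, 30); g2[10:18, 10:18] <- TRUE   # one 9x9 block
cm2 <- classify_mspa(binary_landscape(g2, pixel_size = 30))
compactness_index(cm2, matrix(TRUE, 30, 30))
#> [1] 100          # no islets: fully clumped
```

The full chain on a synthetic study region (105 stops, four periods,
11 species with planted responses) runs in a few minutes:

```r
cfg <- run_config(preset = "study-scale",
                  titan = titan_config(n_perm = 250, n_boot = 100),
                  mcmc = list(chains = 2, draws = 1000, warmup = 1000),
                  seed = 1)
res <- run_pipeline(cfg)
head(res$table2[, c("species", "direction", "z", "change_point", "p")])
#>   species direction         z change_point           p
#> 1    AMRE        z+  5.849750    57.267688 0.011952191
#> 2    EAPH        z+ 10.922129     9.837739 0.007968127
#> 3    EATO        z-  7.103908    30.771479 0.011952191
#> 4    EAWP        z+  9.757118    23.298213 0.015936255
#> 5    GRCA        z+ 10.173071    23.811309 0.003984064
#> 6    INBU        z-  9.526987    40.527538 0.003984064
```

Each species' planted direction (written to `ground_truth.json` by the
generator) is recovered — all six forest species come back z+, EAPH's
planted change point of 10 is located at 9.8 and EAWP's 25 at 23.3. `res$table1` summarises
landscape composition per period (mean +/- s.d.), `res$table3` holds the GAM
model comparison (edf, p, deviance explained, GCV, delta-AIC), and
`provenance.json` records stages, timings, seeds and convergence.

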