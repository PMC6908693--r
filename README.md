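# oxynet

Analysis pipeline for **density-dependent oxylipin production in natural
diatom communities** and the chemically annotated co-occurrence networks
it implies.

Diatoms release lipoxygenase-derived oxylipins — here the particulate,
non-volatile fraction, the linear oxygenated fatty acids (LOFAs) — that
deter grazers and mediate plankton interactions. Field surveys quantify
six targeted LOFAs (a hydroxy acid and an epoxy-alcohol for each precursor
fatty acid HTrA C16:3, EPA C20:5 and DHA C22:6) alongside weekly
phytoplankton counts. `oxynet` implements the full statistical chain such
a survey needs:

* **Quantification** against a 1 µg internal standard
  (`ng = a_x × 1000 / a_S`), normalization to ng/L (filtered volume),
  fg per diatom cell (total diatom density) and ng-C/L (biovolume power
  law `pg C = 0.288 · V^0.811`), with per-precursor and per-oxidation
  class aggregates.
* **Density dependence**: log-log OLS of per-litre concentration and
  per-cell production on diatom density,
  `ln(fg cell⁻¹) = a + b · ln(cells L⁻¹)`, with 95 %-interval outlier
  exclusion, variance-inflation screening (VIF > 10 removed) and backward
  elimination (p > 0.05 dropped).
* **Community tests**: balanced one-way ANOSIM (group-mean padding;
  Bray–Curtis on raw counts, Jaccard on presence/absence), SIMPER
  decomposition, and non-metric MDS (Kruskal stress-1) across low / medium
  / high per-cell production classes (0–100, 100–300, > 300 fg/cell).
* **Global transcripts**: LOX transcript abundance normalized by total
  diatom transcripts, regressed on diatom metagenome abundance
  (log-log).
* **Networks**: salinity-defined water-mass windows (runs of weeks with
  near-constant salinity), pairwise Spearman edges (|ρ| ≥ 0.7, p < 0.05;
  exact permutation p for short windows), modularity modules (exact by
  enumeration at small size, refined Louvain beyond), per-edge mean LOFA
  class production, and module-wise reshuffling null tests (F-test-gated
  pooled/Welch t).
* A **synthetic-data generator** (`synth_config()`, `generate_dataset()`)
  that emulates all four inputs — guild-structured seasonal blooms,
  the planted density law, salinity windows, station transcript tables —
  with recorded ground truth, so the whole pipeline runs and is tested
  without any external data.

## Worked example

```r
library(oxynet)

ds   <- generate_dataset(synth_config(seed = 1))
dens <- colSums(ds$abundance)
prof <- lofa_profile(ds$peaks, diatom_density = dens)
table(prof$production_class)
#>    low medium   high
#>     21     21     10

# per-cell production falls with diatom density (natural-log axes)
x <- log(dens); y <- log(prof$fgcell.total[match(names(dens), prof$sample)])
keep <- exclude_outliers(x, y)$keep
fit_simple(x[keep], y[keep])
#> Linear regression (n = 49 )
#> (Intercept)           x
#>     10.3599     -0.4287
#> adjusted R^2 = 0.8460, F = 264.72 on 1 and 47 df, p = 6.14e-21

# the same inverse relation in transcript space (log10 axes)
fit_tara(ds$tara)$pooled
#> Linear regression (n = 146 )
#> (Intercept)           x
#>     19.5156     -0.6476
#> adjusted R^2 = 0.3350, F = 74.04 on 1 and 144 df, p = 1.2e-14

# co-variation network over the four water-mass windows
w     <- detect_water_masses(ds$environment)
edges <- do.call(rbind, lapply(w, function(v) spearman_edges(ds$abundance, v)))
net   <- find_modules(build_network(edges, rownames(ds$abundance)), seed = 1)
net
#> Co-variation network: 53 nodes ( 52 connected ), 839 edges ( 500 positive / 339 negative )
#> modules: 3  modularity Q = 0.2837
```

The fitted slope −0.43 recovers the planted density dependence −0.46
within its standard error: per-cell oxylipin production declines as the
community thickens, while per-litre concentration still rises
(slope `1 + b ≈ 0.56`). The transcript fit recovers the planted −0.7
slope within noise at 146 stations. One taxon ends up with no significant
co-variations and stays outside the three modules.

`run_pipeline(pipeline_config(...))` chains every stage on CSV inputs and
writes per-stage tables, a GraphML network and a YAML report that
reproduces byte-for-byte under the same seed.

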