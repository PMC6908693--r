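---
title: "Methods behind oxynet: density-dependent oxylipin production and diatom co-variation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind oxynet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Marine diatoms synthesize oxylipins — lipoxygenase (LOX) derived oxidation
products of polyunsaturated fatty acids — that deter grazers, shape
microbial interactions, and may act as infochemicals within the
phytoplankton. `oxynet` implements the complete analysis chain used to ask
how the particulate, non-volatile fraction of these molecules (linear
oxygenated fatty acids, LOFAs) varies with diatom abundance in a weekly
coastal time series, and whether the same density dependence is visible at
global scale in transcript data:

1. **Quantification** of six targeted LOFAs (one hydroxy acid and one
   epoxy-alcohol per precursor fatty acid: HTrA C16:3, EPA C20:5, DHA
   C22:6) from chromatogram peak areas against a 1 µg
   16-hydroxyhexadecanoic-acid internal standard,
   `ng = area × 1000 / standard area`, then ng/L (filtered volume) and
   fg per diatom cell (total diatom density).
2. **Density dependence**: ordinary least squares of log LOFA quantities on
   log diatom density, with a VIF screen, backward elimination of
   non-significant predictors, and exclusion of observations outside the
   95 % residual interval.
3. **Community composition**: balanced one-way ANOSIM (Bray–Curtis on raw
   abundances, Jaccard on presence/absence), SIMPER, and non-metric
   multidimensional scaling across low / medium / high per-cell production
   groups (0–100, 100–300, > 300 fg/cell).
4. **Global transcripts**: LOX transcript abundance normalized by total
   diatom transcript abundance, regressed on diatom metagenome abundance in
   log-log space.
5. **Co-variation networks**: within runs of weeks sharing the same water
   mass (near-constant salinity), pairwise Spearman correlations between
   diatom taxa (|ρ| ≥ 0.7, p < 0.05) define signed edges; modules are found
   by modularity maximization; edges are annotated with the mean per-cell
   production of each precursor class over their source weeks; and a
   reshuffling null tests whether annotations concentrate in particular
   modules.

A synthetic-data generator with recorded ground truth stands in for the
field data, so every stage is testable end to end.

## The planted density law and its axes

The generator plants, per precursor class,

$$\ln(\mathrm{fg\,cell^{-1}}) = a_c + b \,\ln(\mathrm{cells\,L^{-1}}) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

with defaults \(b = -0.46\) and total intercept \(a = 10.75\) split across
classes by their abundance fractions (EPA 0.766, DHA 0.22, HTrA 0.014, so
class intercepts are \(a + \ln f_c\) and noise-free class values sum
exactly to the planted total). The slope of a log-log fit is identical in
any log base; the intercept is not, and we define it on **natural-log
axes** because only there does an intercept of 10.75 with slope −0.46
place per-cell production in the tens-to-hundreds of fg/cell range that
particulate oxylipin surveys actually report (e.g.
\(\exp(10.75 - 0.46\,\ln 10^6) \approx 81\) fg/cell at \(10^6\) cells/L).
On log10 axes the same numbers would imply ~\(10^8\) fg/cell and the
0–100/100–300/>300 fg/cell production classes could never be exercised.
The pipeline therefore fits the density regressions on natural-log axes;
every slope-level result is base-independent. The transcript relation
(default slope −0.7, intercept 21.33) involves only relative units with no
magnitude constraint and is planted and fitted on log10 axes.

The residual SD is configured in log10 units (decades) and converted
internally; the default 0.20 was chosen together with the community
parameters so that the refitted density regression has adjusted R² near
0.85, the fit quality such weekly surveys typically achieve — tight enough
that the regression is clearly real, loose enough that outlier exclusion
and class grouping have work to do.

## What the community generator emulates — and what it does not

Taxa are partitioned into guilds (default 3, over 53 taxa). Each guild has
a Gaussian bloom envelope in log10 cells/L (background 10^2 × taxon
scaling, amplitude 3 decades, SD ≈ 4 weeks, peaks spread across the year);
each taxon multiplies its guild envelope by a fixed lognormal scale
(log10 SD 0.8, the realistic many-decade spread of taxon abundances) and
weekly lognormal noise. Abundances under a 50 cells/L detection limit —
about one cell per settling chamber — are recorded as absent, which is
what creates presence/absence structure for the Jaccard analyses. This
gives, by construction:

* strong positive within-guild and weak/negative between-guild rank
  correlation (the raw material of the network stage);
* total weekly density spanning > 2 orders of magnitude, so production
  classes and the density regression both have leverage;
* winter/trough weeks sparse enough that the "high" (> 300 fg/cell) class
  is populated.

It does **not** emulate microscopy counting error, LC-MS drift or batch
effects, taxon birth/death, zero-inflated blooms of rare taxa, or any
spatial structure; sudden week-to-week density spikes are absent by
default. Passing tests therefore demonstrate the correctness of the
statistical machinery under a clean seasonal-bloom model, not robustness
to every pathology of real count data.

Salinity is constant (± a small jitter) inside declared water-mass
windows. Between windows it follows a higher-variance random walk confined
to a fresher band (35.5–37.1 PSU) whose steps are at least 0.35 PSU, so no
undeclared 3-week run can satisfy the persistence criterion at the default
tolerance — window detection is exactly recoverable, which the tests
exploit. Real salinity series are smoother; the walk is deliberately
"spiky" to make the detector's negative space unambiguous.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `density_slope` | −0.46 | dimensionless | planted density dependence of per-cell production |
| `density_intercept` | 10.75 | ln fg/cell at ln density 0 | see axes discussion above |
| `noise_sd` | 0.20 | log10 decades | calibrated for adjusted R² ≈ 0.85 |
| `tara_slope`, `tara_intercept` | −0.7, 21.33 | log10 | planted transcript relation |
| `tara_noise_sd` | 0.686 | decades | gives R² ≈ 0.4 at predictor SD 0.8 |
| `rho_min`, `alpha` | 0.7, 0.05 | — | edge-inference thresholds |
| salinity `tolerance` | 0.15 | PSU | admits the widest realistic window half-range (~0.12) |
| production bounds | 100, 300 | fg/cell | low/medium/high split; upward boundary assignment |
| `detection_limit` | 50 | cells/L | one cell per 20 mL settling chamber |

## Numerical and design choices

* **Quantification**: ng→fg conversion is the SI factor 10^6. Division by a
  zero diatom density yields a missing value (propagated through all
  statistics), never zero or an error — weeks without counts simply drop
  out.
* **Production classes**: boundaries are half-open upward, 100 → medium and
  300 → high, keeping "> 300" literal.
* **Bray–Curtis** of two all-zero samples is defined as 0 (identical
  emptiness); the formula itself is 0/0 there.
* **ANOSIM**: dissimilarities are midranked; when the number of distinct
  label arrangements is within the permutation budget the null is
  enumerated completely and p is the exact proportion (identity included);
  otherwise p = (1 + count)/(permutations + 1), never zero. The balanced
  design pads every group to the largest size with group-mean
  pseudo-samples; padding never moves a group mean, and padded samples are
  excluded from SIMPER reporting. For Jaccard the matrix is binarized
  *before* padding, and the quantitative Jaccard form (2B/(1+B), defined
  for the fractional padded rows, identical to the set form on 0/1 data)
  is used.
* **nMDS** minimizes Kruskal stress-1 via isotonic regression
  (`MASS::isoMDS`) from a classical-scaling start plus 20 random restarts;
  zero off-diagonal dissimilarities are raised to a tiny epsilon so the
  monotone fit stays defined, which maps duplicate samples to
  near-coincident points.
* **Regression**: quantities entering log-log fits are strictly positive
  when detected, so zeros are excluded with a warning rather than offset.
  The 95 % interval rule is operationalized as |studentized residual| >
  1.96 on a preliminary fit (with an exact-fit guard); which observations
  were dropped is reported. Backward elimination breaks ties by larger p,
  then alphabetical label. Residual-assumption checks are reported, not
  gating.
* **Spearman edges**: p-values are exact by full enumeration of n!
  orderings for n ≤ 9 and t-approximated (df = n − 2) otherwise. The
  *significance gate* defaults to the t approximation because an exact
  test can never reach p < 0.05 at n = 3, yet 3-week windows are a normal
  part of the design; all edges from windows shorter than 5 weeks are
  flagged `low_support` so users can filter them.
* **Edge merging**: a pair significant in several windows becomes one edge
  represented by its strongest correlation (largest |ρ|, that window's p
  and sign) so the stored edge always satisfies the inference thresholds;
  `sign_consistent` records cross-window sign agreement, and the LOFA
  annotation averages across the source windows.
* **Modules**: modularity is maximized on the positive-edge subgraph only
  (the objective is ill-defined with negative weights); negative edges are
  retained for degrees and annotation. Graphs with ≤ 10 connected nodes
  are solved exactly by partition enumeration; larger graphs use Louvain
  with 20 restarts, each refined by greedy single-node moves and
  community-pair merges — the same exact-small / heuristic-large split as
  the Spearman test. Labels are 0-based, ordered by decreasing module
  size, deterministic given the seed.
* **Null tests**: the observed sample is a module's intra-module edge
  annotations (n1); the null pools the values landing on that module over
  1000 reshuffles of all intra-module annotations and subsamples n2 = n1.
  Each reshuffle is a permutation, so the annotation multiset is conserved
  exactly. An F-test at 0.05 chooses pooled (df = n1 + n2 − 2) versus
  Welch t. Comparing against a pooled-many-reshuffles null (rather than a
  single reshuffled replicate) is a deliberate design choice: it stabilizes
  the null mean without inflating its variance.
* **Pipeline**: one oxylipin replicate per week is assumed; every
  stochastic step takes a seed and the YAML report reproduces byte for
  byte under the same configuration.

## Problem sizes used by the test-suite

The suite verifies the engines against independent brute-force oracles at
sizes where enumeration is exact: all 2-group ANOSIM designs on ≤ 8
samples, all n! Spearman orderings for n ≤ 7, and exhaustive partition
search on 50 random graphs of ≤ 8 nodes. Parameter-recovery checks run 100
replicate surveys at 38 weekly samples (the usable-week count such a
yearly survey yields after exclusions) for the density slope and 146
stations for the transcript slope, asking for ≥ 90 % CI coverage of the
planted values; enrichment detection uses two 9-node-clique modules and
expects p < 0.01 in ≥ 95 % of 100 seeds. The acceptance script reports
noise-sensitive quantities as means over 20 replicate surveys at full
study scale.

## Known limitations

* Weekly samples are treated as independent; no autocorrelation correction
  is applied to the OLS fits (the analysis this mirrors did the same).
* Modularity at > 10 connected nodes is heuristic; the refinement makes
  misses rare but optimality is only guaranteed at small size.
* The low/medium/high grouping discretizes a continuous gradient; ANOSIM R
  between groups is an emergent property of the synthetic community, not a
  planted parameter, so its value is reported rather than asserted.
* The generator's guild blooms are symmetric Gaussians; skewed or
  double-peaked blooms, and the sudden density fluctuations real series
  show, are not modelled (a spike option was considered and left out of
  the defaults).
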