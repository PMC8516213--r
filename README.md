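# trajDEG

Trajectory classification of differentially expressed genes in
longitudinal two-group RNA-seq.

## What problem this solves

In exposure studies, animals (here: an exposed "ISO" group vs naive
controls) are profiled by bulk RNA-seq at several post-exposure
timepoints — days 1, 30, 240 and 360, with 5–6 animals per group per day.
The scientific question is not only *which* genes respond, but *how the
response evolves*: some genes react strongly right after exposure and
dissipate within weeks (**short-term** DEG), others are quiet early and
only become differentially expressed months later (**late-onset** DEG).

trajDEG packages that analysis for anyone with a gene × sample count
matrix and a design table:

* **QC**: counts-per-million filtering (drop genes with CPM < 0.5 in every
  sample), TMM normalization, PCA with per-group 95% confidence ellipses
  and leave-one-out outlier flagging;
* **Differential expression** per timepoint: NB GLM with dispersion
  shrinkage and the quasi-likelihood F-test (via edgeR), BH FDR within
  each day's table;
* **Trajectories**: per-gene log2 fold-change vectors across days, the two
  selection rules
  * short-term: `p(day1) < 0.05`, or sign-consistent with `p < 0.1` at
    days 1 and 30;
  * late-onset: `FDR(day360) < 0.05`, `p(day240) < 0.1`, shared sign;
* **Trend battery**: Mann-Whitney, Kruskal-Wallis and Jonckheere-Terpstra
  tests on the panel's fold-changes pooled by day, the JT test one-sided
  with the panel-appropriate alternative (implemented from first
  principles, with tie corrections and exact small-sample enumeration);
* **Enrichment**: hypergeometric overrepresentation of a panel in GMT
  gene sets within the measured universe;
* **Simulator**: NB counts with planted trajectory archetypes
  (amplitude `A ~ U(0.3, 1.2)` log2; short-term pattern
  `(A, 0.5A, 0, 0)`, late-onset `(0, 0, 0.5A, A)`) and a ground-truth
  table, so the whole pipeline is testable without access to raw data.

The central statistic: for an ordered set of days with per-gene
fold-changes pooled per day, the Jonckheere-Terpstra statistic

J = Σ_{i<j} #{ x ∈ day_i, y ∈ day_j : x < y } + ½ #{ties}

tests a monotone trend against the no-trend null (tie-corrected normal
approximation, or full enumeration for small samples).

## Worked example

```r
library(trajDEG)

cfg <- simulationConfig(nGenes = 2000, seed = 1)
tce <- simulateExperiment(cfg)
tce
#> TimecourseExperiment: 2000 genes x 47 samples
#>   days: 1, 30, 240, 360
#>   ISO    n per day: 5, 6, 6, 6
#>   naive  n per day: 6, 6, 6, 6
#>   planted archetypes: late_onset_down=302, late_onset_up=265, null=827,
#>     short_term_down=303, short_term_up=303

filt <- filterLowExpression(tce)
nf   <- tmmFactors(filt)
de   <- lapply(c(1, 30, 240, 360), function(d)
  testTimepoint(filt, d, normFactors = nf))
ts   <- buildTrajectories(de)

shortTerm <- selectShortTerm(ts)
shortTerm
#> PanelSelection (short_term): 594 genes (285 up, 309 down)

trendBattery(ts, shortTerm)[, c("panel", "test", "alternative", "p", "pText")]
#>   panel           test alternative         p     pText
#> 1    up   mann_whitney   two.sided  6.64e-01     0.664
#> 2    up kruskal_wallis   two.sided 3.29e-120 < 2.2e-16
#> 3    up     jonckheere  decreasing 1.42e-158 < 2.2e-16
#> 4  down   mann_whitney   two.sided  9.66e-01     0.966
#> 5  down kruskal_wallis   two.sided 7.52e-130 < 2.2e-16
#> 6  down     jonckheere  increasing 1.86e-167 < 2.2e-16

summarizeTrajectory(ts, shortTerm@up)
#>   day   n   mean  median   sd    se
#> 1   1 285 0.8109  0.7861 0.29 0.017
#> 2  30 285 0.3872  0.4235 0.26 0.016
#> 3 240 285 0.0022 -0.0120 0.22 0.013
#> 4 360 285 0.0051  0.0054 0.25 0.015
```

Reading the output: the selected short-term "up" panel starts at a mean
log2 fold-change of ~0.81 on day 1, halves by day 30 and is
indistinguishable from zero at days 240/360 — the dissipating pattern.
The Jonckheere-Terpstra test rejects "no trend" in favor of a decreasing
trend at p < 2.2e-16, while the Mann-Whitney comparison of days 240 vs
360 (p = 0.66) shows the two late, dissipated timepoints no longer
differ. `selectLateOnset(ts)` yields the mirror-image panel rising to
day 360, and `overrepresentation()` reports which gene sets a panel is
enriched in. `runAll(cfg, "out/")` drives every stage end to end and
writes each result as TSV plus a JSON manifest.

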