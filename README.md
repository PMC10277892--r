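# fragindex

Quantification of somatic short-tandem-repeat instability from
capillary-electrophoresis fragment analysis, for labs measuring whether an
intervention (e.g. mismatch-repair knockdown) blocks somatic CAG-repeat
expansion in mouse models of Huntington's disease and related repeat
disorders.

The pipeline goes from fragment-analysis exports (peak tables or raw
traces) to per-animal somatic instability indices, Bethesda-style
microsatellite-instability calls at mononucleotide loci, and the group
statistics used to compare treatments — plus a synthetic-data generator
(somatic expansion + PCR stutter + CE rendering) with known ground truth,
so every stage is testable without animal data.

## The statistic at the core

For the peaks $\{(r_i, h_i)\}$ of one sample inside the locus analysis
window, with main (modal) allele $m$ and signal-to-noise threshold
$\tau$ (default 5% of the main-peak height):

$$\mathrm{II} \;=\; \sum_{i\,:\,h_i \ge \tau h_m} \tilde h_i\,(r_i - m),
\qquad \tilde h_i = \frac{h_i}{\sum_{j\,:\,h_j \ge \tau h_m} h_j}$$

The signed index decomposes exactly into an expansion part ($r_i > m$) and
a contraction part ($r_i < m$) over the same jointly normalized peak set.
Supporting machinery: peak calling with parabolic apex refinement, size →
repeat binning with a lattice-residual guard, flank estimation from a
sample of known repeat count, Dunnett many-to-one comparisons by Monte
Carlo on the correlated multivariate t, and 4-parameter logistic IC50
fitting. See the vignette (`vignettes/somatic-instability.Rmd`) for the
model details and design choices.

## Worked example

```r
library(fragindex)

locus <- repeat_locus("HTT_CAG", "CAG", flank_bp = 100,
                      window_min_repeat = 70, window_max_repeat = 150)
peaks <- read_peak_table(system.file("extdata", "example_peaks.csv",
                                     package = "fragindex"))
rps <- bin_to_repeats(peaks, locus)
instability_index(rps, threshold_frac = 0.05)
#> <instability_result> example_peaks: main allele 110, threshold 5%, 5 peak(s) retained
#>   instability +0.4211 (expansion +0.5263, contraction -0.1053)
```

The five peaks bin to repeats 108–112 with heights 5/10/100/50/25; all
survive the 5% cutoff (5 RFU), and the height-weighted mean displacement
from the 110-repeat main allele is 80/190 ≈ +0.42 repeats, of which +0.53
comes from expanded peaks and −0.11 from the stutter side.

A synthetic three-arm study (untreated controls gaining ~4 repeats over
2 months, a treated arm nearly blocked):

```r
design <- cohort_design(list(
  cohort_group("baseline", n_animals = 6, true_gain = 0),
  cohort_group("NTC",      n_animals = 6, true_gain = 4),
  cohort_group("treated",  n_animals = 6, true_gain = 0.5)
), locus, seed = 2026)
sim <- simulate_cohort(design)
idx <- index_cohort(sim$samples, threshold_frac = 0.05)
aggregate(instability_index ~ group, idx,
          function(x) round(c(mean = mean(x), sd = sd(x)), 2))
#>      group instability_index.mean instability_index.sd
#> 1 baseline                  -0.13                 0.00
#> 2      NTC                   3.46                 0.90
#> 3  treated                   0.52                 0.84

run_stats(idx, read_run_config(), control = "baseline", seed = 1)
#> <group_comparison> one-way ANOVA F(2,15) = 43.426, p = 5.767e-07; Dunnett vs 'baseline'
#>     group estimate     t   p_unadj  p_adj     mc_se stars
#> 1     NTC   3.5939 8.745 2.829e-07 0.0000 0.0000050  ****
#> 2 treated   0.6505 1.583 1.343e-01 0.2282 0.0009384    ns
```

The untreated arm is flagged against baseline (expansion occurred); the
treated arm is not (expansion blocked) — the qualitative pattern such
studies report. The small negative baseline mean is the minus-stutter
ladder entering the signed index.

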