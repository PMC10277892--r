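---
title: "Quantifying somatic repeat instability from fragment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic repeat instability from fragment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragindex)
```

## The measurement problem

Expanded CAG tracts — such as the ~110-repeat tract of the Hdh^Q111 knockin
mouse or the ~120–130-repeat tract of the BAC-CAG model — continue to
lengthen somatically in post-mitotic striatal tissue, producing length
mosaicism within months. The standard readout is fragment analysis: the
repeat-containing amplicon is PCR-amplified with a fluorescent primer and
sized by capillary electrophoresis, giving a trace with a ladder of peaks
spaced one repeat unit (3 bp for CAG) apart. Interventions that block the
mismatch-repair-driven expansion machinery (e.g. MSH3 knockdown) are judged
by whether treated animals retain the near-baseline peak ladder while
controls accumulate an expanded shoulder.

fragindex turns this comparison into a tested pipeline: trace and peak-table
I/O, peak calling, binning of fragment sizes to integer repeat counts, a
signed somatic instability index, Bethesda-style microsatellite-instability
calls at mononucleotide loci, and the group statistics used to declare
expansion blocked. A synthetic-data generator with known ground truth makes
every stage testable without animal data.

## The instability index

For a per-sample peak set $\{(r_i, h_i)\}$ (repeat count, peak height in
RFU) inside the locus analysis window:

1. the **main allele** $m$ is the tallest peak (ties go to the smaller
   repeat);
2. peaks with $h_i < \tau\, h_m$ are discarded — $\tau$ is the
   signal-to-noise threshold, default $\tau = 0.05$;
3. retained heights are normalized, $\tilde h_i = h_i / \sum_j h_j$;
4. the signed index is $\mathrm{II} = \sum_i \tilde h_i\,(r_i - m)$.

The **expansion index** restricts the sum to $r_i > m$ and the
**contraction index** to $r_i < m$, both using the *jointly* normalized
$\tilde h_i$; the decomposition is therefore additive,
$\mathrm{II} = \mathrm{EI} + \mathrm{CI}$, and the package computes the
signed index as that sum so the identity holds to the last bit. Signed
contraction contributions are essential: young or expansion-blocked samples
can have negative indices (the minus-stutter ladder below the main allele
outweighs the expanded side), which an expansion-only index cannot express.

Interpretation notes:

* "5% signal-to-noise threshold" is implemented as 5% of the main-peak
  height within the analysis window, the convention of the instability-index
  literature; fragment-analysis software does not define "noise"
  operationally in its exports.
* The threshold makes the index deliberately insensitive to baseline noise
  but also truncates genuine low-abundance tails. In simulated cohorts this
  attenuates a true mean gain of 4 repeats by roughly 5–10%; because every
  group is truncated similarly, *differences* between groups — the quantity
  compared across treatments — are much less affected.
* No stutter correction is applied before indexing. Stutter shifts every
  sample's index by a similar small negative amount (about $-0.13$ for a
  single allele at the default minus ratio 0.15), which cancels in
  between-group comparisons against a baseline; deconvolving stutter would
  couple the index to a stutter model that real data do not come with.

`main_allele()` ties break to the smaller repeat so that an exactly
symmetric tie cannot inflate the index.

## From trace to peak set

`call_peaks()` replaces interactive peak picking: moving-average smoothing
(default window 0.3 bp), rolling-minimum baseline subtraction (default
window 20 bp, clamped to the trace span — at the clamp it reduces to
global-minimum subtraction), local maxima filtered by height and
prominence, and a three-point parabolic refinement of each apex on the
smoothed signal. Parabolic interpolation gives sub-grid sizing (error well
under 0.01 bp on clean Gaussian peaks at the default 0.1-bp grid) without
fitting a peak model, and makes calling translation-equivariant.

`bin_to_repeats()` maps sizes to repeats via
$r = \mathrm{round}\big((s - \mathrm{flank})/\mathrm{unit}\big)$ and drops
peaks whose residual from the repeat lattice exceeds `residual_tol_bp`
(default 1.0 bp for a 3-bp unit — a half-unit guard against CE sizing error;
the tolerance must stay below half a unit or binning would be ambiguous).
When two peaks bin to the same repeat the taller wins, deterministically.
An empty post-filter result is a signal (empty peak set plus warning), not
an error, so cohort batches continue past degenerate samples.

The analysis window matters biologically: heterozygous animals carry an
unexpanded wild-type allele whose peak would otherwise be the tallest in
the trace. The window (default: expected main allele ±40 repeats, set per
locus) excludes it; how the original studies gated the wild-type signal is
not documented, so the window is this package's explicit assumption.

The amplicon's non-repeat flank length for a primer pair is rarely
published. `estimate_flank()` fits it from any sample with a known
main-allele repeat count (flank = tallest-peak size − unit × known repeat),
after which binning places that allele exactly.

## The synthetic cohort generator

The generator exists to give every pipeline stage inputs with known truth.
Its layers:

**Cell population.** Each expansion-competent cell accrues
$\mathrm{Poisson}(\lambda_e t)$ one-repeat gains and
$\mathrm{Poisson}(\lambda_c t)$ one-repeat losses over $t$ months, floored
at 1 repeat — the simplest process with time-linear mean gain and
overdispersion. A fraction `expanding_frac` of cells is
expansion-competent; the rest retain the inherited length. In bulk striatal
tissue the non-expanding cell types (glia and other non-MSN populations)
anchor the modal allele at the inherited repeat while the competent
fraction builds the expanded shoulder — exactly the trace morphology real
studies show. Without this anchoring a mean gain of ~4 repeats would move
the modal allele itself and the instability index (which measures
displacement from the mode) would no longer track the gain.
`expansion_params()` defaults to `expanding_frac = 1` (the pure
single-population model); `cohort_group()` defaults to 0.6 as the realistic
bulk-striatum condition. The designed group truth is
`expanding_frac × (expansion_rate − contraction_rate) × months`.

**Between-animal variability.** Printed group SDs in repeat-expansion
studies are 0.3–1.8 index units, far above what cell-sampling noise at
$10^5$ cells could produce, so each animal's true gain is drawn from a
Gamma distribution with mean equal to the designed group gain and SD
`animal_sd` (default 1.0 repeat, chosen once from that observed range).
Zero-gain groups are exactly non-expanding — a limitation (their
between-animal variance is zero) that keeps the zero-rate invariants exact.
The realized per-animal gains are emitted in the truth table, which is what
parameter-recovery tests compare against.

**PCR stutter.** Each template at repeat $n$ contributes weight
$\mu^k$ at $n-k$ and $\pi^k$ at $n+k$ for $k = 1..K$, then the distribution
is renormalized. Defaults $\mu = 0.15$, $\pi = 0.01$, $K = 4$ match typical
trinucleotide stutter; mononucleotide loci are simulated with a higher
minus ratio (0.25) as such markers stutter more.

**Rendering.** Gaussian peaks (σ default 0.6 bp) on the repeat lattice,
tallest peak scaled to `amplitude` (default 4000 RFU), per-peak sizing
jitter (SD 0.05 bp), additive baseline noise (SD 5 RFU), and a mild
amplitude decay per repeat above the modal allele (default 0.99/repeat,
for the poorer amplification of longer fragments). Cohorts can emit either
rendered traces (exercising the full calling path) or peak sets built
directly from the stuttered distribution with a 20-RFU detection floor
(fast, noise-free apart from sampling and stutter).

**Seeding.** Per-animal seeds derive from the design seed, group label and
animal index through a 31-bit polynomial hash, so cohorts are
bit-reproducible without reusing streams across groups.

What the generator does **not** emulate: dye pull-up, off-ladder artifacts,
size-standard miscalibration, heteroduplex or -A peaks, baseline drift,
inter-run sizing offsets, or biological age-dependence of the expansion
rate. Passing tests therefore validate the *quantification machinery*, not
the instrument model; real traces should still be inspected.

## Group statistics

`dunnett()` implements many-to-one comparisons versus a named control: the
pooled-variance t statistic per contrast, with adjusted p values obtained by
Monte Carlo from the joint null distribution of $\max_j |T_j|$ over the
correlated multivariate t (correlation induced by the shared control and
pooled variance). Monte Carlo rather than table lookup supports unbalanced
groups (n = 4–6 are typical) at controllable precision; the default
$2\times10^5$ draws put the Monte Carlo SE of a p value near 0.05 below
$5\times10^{-4}$, and each adjusted p is reported with its MC SE. With one
treatment group the procedure reduces to the two-sided two-sample pooled t
test, and the suite cross-checks the adjusted p values against the
`multcomp` reference implementation.

Conventions: all tests two-sided; Student's pooled t is the two-group
default with Welch available by flag; data that are exactly constant give
$t = 0, p = 1$ (and the analogous ANOVA degenerate case $F = 0, p = 1$) —
"no evidence of difference" is the only defensible reading, and it arises
routinely at perfectly stable simulated mononucleotide loci. Significance
stars follow the usual figure conventions (\*, \*\*, \*\*\*, \*\*\*\* at
0.05, 0.01, 0.001, 0.0001).

`fit_4pl()` fits $y = b + (t - b)/(1 + (d/\mathrm{IC_{50}})^h)$ by
Levenberg–Marquardt least squares, so the fitted response at the IC50 is
exactly halfway between the plateaus. Initialization: plateaus from the
responses at the dose-range ends, IC50 from the first dose crossing the
half-response, unit Hill slope. Non-convergence sets an explicit flag. With
a 7-point 2× dilution series measured in triplicate at 5% proportional
noise — the standard assay design, and the regime of reported siRNA
potencies (15–479 nM) — the median IC50 recovery error is under 10%;
single wells roughly double that, which is a property of fitting four
parameters to seven points, not of the optimizer.

## MSI calls

`msi_compare()` reduces Bethesda-style locus comparison to two numbers: the
main-allele shift (sample − reference, repeat units) and the difference of
signed instability indices, with `unstable` raised when
|shift| ≥ `min_shift` (default 1 repeat — the smallest detectable novel
allele). The published studies do not state their numeric MSI metric; this
pair is the minimal quantitation that is symmetric under sample/reference
swap and reduces to zero on identical inputs.

## Problem sizes used by the test suite

The packaged checks run cohorts of 6 animals per group at $10^5$ cells per
animal, 100 replicate scenario seeds for flag-rate estimates, 1000
null replicates for Dunnett family-wise error, and 100 seeds per IC50 for
dose-response recovery; the acceptance script uses the same designs with
40 scenario and 600 null replicates. These sizes were chosen so the whole
suite runs in about a minute while keeping binomial error on every rate
well inside the margins being asserted.

## Known limitations

* Binary chromatogram formats (ABIF/.fsa) are not parsed; export peak
  tables or two-column traces first.
* No multi-dye deconvolution or pull-up correction.
* The expansion model is phenomenological; it reproduces mean gain,
  overdispersion and mode anchoring but not locus-specific length
  dependence of the expansion rate.
* Zero-gain groups have no between-animal variance in the generator.
* No modal-allele-change-over-time tracking and no stutter deconvolution;
  both are natural extensions behind the existing types.
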