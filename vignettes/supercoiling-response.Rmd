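---
title: "Methods: transcriptome response analysis for DNA supercoiling perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome response analysis for DNA supercoiling perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supercoilr)
```

## Scope and scientific background

Topoisomerases set the supercoiling state of bacterial chromosomes:
gyrase introduces negative supercoils, topoisomerase I relaxes them.
Perturbing either (overexpression of *topA*, knockdown of *gyrA*/*gyrB*)
triggers a genome-wide transcriptional response in cyanobacteria such as
*Synechocystis*, with three analysis questions this package addresses:

1. **Which temporal response groups exist?** Model-based clustering of
   induction time series on Fourier features.
2. **How do responses organize along transcription units (TUs)?**
   Gene-to-TU transfer of the clustering, immediate-response labels, and
   5'→3' fold-change gradients (the twin-domain signature).
3. **What distinguishes the promoters of the response groups?**
   TSS-anchored motif profiles (A-tracts, AT2, TpA), helical-pitch
   periodicity, PWM divergence, and discriminator statistics.

A synthetic-data module generates inputs with the statistical structure
these stages assume, so the whole pipeline is exercised and validated
against planted truth without any external data.

## Time-series clustering

Each gene's TPM series is arcsinh-transformed
($\mathrm{arcsinh}(x) = \ln(x + \sqrt{x^2+1})$, variance-stabilizing and
$\approx \ln 2x$ for large $x$), then Fourier-transformed:
$X_k = \sum_t x_t e^{-2\pi i k t / N}$. Each non-DC component is
normalized by the mean amplitude of all *other* non-DC components, and
the real and imaginary parts of components $k = 1..6$ form a 12-column
feature matrix. The normalization makes features amplitude-free, so
clusters are defined by the *shape* of the response, not its magnitude.

The published analysis clustered these features with flowClust, a
t-mixture with Box–Cox transformation. We use a Gaussian mixture with
full covariances, fitted by EM (compiled core; ridge
$10^{-6}\,\mathrm{tr}(\Sigma)/d$ on each covariance update; best of 20
seeded random restarts). The transformation chain has already stabilized
variance and tamed heavy tails, so the heavier-tailed mixture family is
an implementation detail rather than a modelling commitment; the
equivalence we claim — and test — is at the level of recovered cluster
structure, not parameter values. The cluster number is selected by
maximizing $\mathrm{BIC} = 2\log L - p\ln n$ over $K = 2..10$, ties
toward smaller $K$.

Ambiguity resolved here: "normalized to the mean of amplitudes at all
other components" is read as the mean over $j \ge 1$, $j \ne k$ (the DC
component is excluded; whether $k$ itself was excluded originally is not
recoverable from the description). If that denominator is zero — e.g. a
constant series, or a single non-zero component — the gene is excluded
and reported, never silently dropped, as is any gene with summed TPM
below 1 over the series.

Parameters that matter: `m = 6` components (12 features),
`n_restarts = 20`, `K_range = 2:10`, low-signal threshold 1 TPM,
pseudocount `delta = 0.5` TPM shared by all log-ratio utilities.

## TU-level statistics

TU expression is the mean over member coding genes. TU features are
built with the identical transform chain, then assigned by Lloyd's
k-means initialized *exactly* at the gene-level mixture means, with K
fixed — a transfer, not a re-clustering. Our Lloyd implementation
tolerates and reports empty clusters (a TU composition may populate
only part of the gene-level structure).

Immediate response: $r = \log_2((\bar{x}_{\mathrm{post}} + \delta) /
(\bar{x}_{\mathrm{pre}} + \delta))$ over samples 1:2 (pre) and 3:4
(post); labels are `down` ($r < -\theta$), `up` ($r > \theta$), else
`nc`, with strict inequalities. Defaults $\theta = 0.01$ at gene level
(a comprehensive directional picture) and $\theta = 0.15$ at TU level
(only confident responders feed the promoter analysis).

The 5'→3' gradient of a TU is $\Delta = \log_2\mathrm{FC}(\text{first
gene}) - \log_2\mathrm{FC}(\text{last gene})$, i.e. positive when the
downstream gene responds less (or more negatively) — the direction
expected for G+C-rich TUs under gyrase knockdown, where elongation
stalls without downstream gyrase activity. The published figures do not
state the sign of their axis; ours is documented here and recovered
exactly (to machine precision) from the noiseless generator. TUs below
`min_genes` (4 in the main figures, 2 in supplementary analyses) are
skipped, as are TUs missing from the fold-change table (reported).

ΔΔCt: the reported value is $-\Delta\Delta Ct$, the log2 fold change
with respect to the reference state, so that a *drop* in target Ct
(more transcript) is positive; the raw ΔΔCt is returned alongside.
TPM: rate = counts/(length/1000), scaled per sample to sum $10^6$;
zero-count samples are an error, not a silent NaN.

## Enrichment profiles

Two classifications over a shared item universe are cross-tabulated;
each cell is tested with cumulative hypergeometric tails,
$p_{\mathrm{enrich}} = P(X \ge x)$ and $p_{\mathrm{deplete}} =
P(X \le x)$ — "cumulative" plus enrichment semantics force the upper
tail. Raw p-values are displayed, matching the published profiles whose
color scale caps at $p_{\min}$; a Benjamini–Hochberg column is emitted
alongside for users but feeds nothing downstream.

The row-sorting procedure iterates over columns: rows enriched at
$p \le p_{\mathrm{sort}}$ in the current column move to the top
(ascending p within the block); leftovers sit below a "red line"
(`cut_row`) or are dropped. Sorting uses enrichment p-values only.
Rendering is a style-sheet contract (text, background intensity
$\min(1, \log_2 p / \log_2 p_{\min})$, hue black for counts or red/blue
for the sign of Welch t, white text at $p \le p_{\mathrm{txt}}$), kept
separate from any drawing toolkit.

## Promoter structure

All promoter analyses use chromosome TUs only (plasmid copy number
would bias motif frequencies). Coordinates: position 0 is the first
transcribed base, upstream positions are negative; internally 0-based
half-open, 1-based in all TSV interfaces. Minus-strand promoters are
analyzed on the reverse complement (sense strand), because sigma-factor
contacts are sense-strand defined; a motif occurrence is recorded at
the position of its *first* base. Windows that overrun a replicon
exclude the TU (counted, never padded or truncated).

Motifs: `GC`; `AT2` = {AA, AT, TT} (the A-tract dinucleotides); `TpA` =
{TA} (the flexible "twist capacitor" step); `ATRACT4` = the five 4-mers
over {A,T} with no TpA step. Windows containing N never match.
Overlapping occurrences all count — the simplest consistent reading of
an occurrence indicator vector.

Frequencies are computed in w-bp windows around each position
(w = 5 for dinucleotide/tetramer profiles, 66 for G+C content; the even
window is centered asymmetrically as [−32, +33]); only positions with
complete windows are reported. Per-position significance compares
cluster windows against the same windows over all TUs
(hypergeometric on slot counts); glyph sizes scale with $-\log_2 p$
capped at the series minimum, thinned to every 3rd (w = 5) or 10th
(w = 66) position.

Periodicity: the AT2 indicator over a promoter region (default
[−200, −1], configurable) is concatenated across TUs and
autocorrelated to lag 30, with products spanning promoter boundaries
masked out (naive concatenation would introduce spurious cross-promoter
terms). The dominant period is the ACF argmax over lags 6–15 refined by
a three-point parabolic interpolation.

PWMs use a pseudocount of 0.5 per base. Divergence between cluster PWMs
is the per-position Jensen–Shannon divergence in bits (bounded [0, 1]);
significance comes from a label-permutation test preserving group sizes,
$p = (1 + \#\{JSD_{\mathrm{perm}} \ge JSD_{\mathrm{obs}}\})/(B+1)$,
default $B = 1000$ — a generic, assumption-free stand-in for the
specialized PWM-difference significance tool used originally.
Discriminator statistics report the G+C fraction over positions −6..−3
and the frequency of T at −7, with hypergeometric tests of cluster base
counts against all TUs.

## What the synthetic data emulates — and what it does not

`simulate_timeseries()` draws, per cohort, lognormal baselines
(meanlog log 50, sdlog 1) and applies a fixed log2-scale waveform with
multiplicative lognormal noise (sd 0.15 on the natural-log scale):
$\mathrm{TPM}(t) = b_g \cdot 2^{w_c(t)} \cdot e^{\varepsilon}$, zero
response before induction. The six default waveforms mirror the
observed response classes: a damped 24-h cosine peaking at dawn, a
sustained down-step, an inverted cosine with an initial dip, a
near-flat low-amplitude oscillation, a delayed ramp from ~24 h, and a
delayed ramp with an overshoot (the plasmid-like transient). The
default design has 900 genes (220/190/160/120/120/90) over 16 time
points (−24 h, −35 min, then 5 min–72 h), of which samples 2..16 enter
clustering — the study's sampling scheme.

`simulate_genome()` tiles non-overlapping TUs on alternating strands of
one chromosome with i.i.d. background nucleotides (default GC 0.48,
near the *Synechocystis* genome).  `plant_promoter_motifs()` writes
A-tract 4-mers at $\mathrm{round}(\mathrm{anchor} - j \cdot
\mathrm{pitch})$ (half away from zero), defaults anchor −10, pitch
10.5, 3 repeats, in 80% of TUs. Two stochastic decorations make the
planted structure realistic rather than literal:

* **Upstream attenuation**: repeat $j \ge 1$ is present with
  probability $0.75^j$ (the anchor always). The observed profiles have
  their maximal peak at −10 with attenuated upstream repeats; without
  attenuation the planted profile would be a flat comb whose global
  maximum is a coin flip among peaks.
* **Per-promoter phase jitter**: each planted TU shifts its whole
  ladder by one draw from {−2..2} (probabilities .1/.2/.4/.2/.1).
  This spreads anchor positions *between* promoters (so the 5-bp-window
  profile has a unique maximum at −10 rather than a rectangular
  plateau) while preserving the helical spacing *within* each promoter
  — which is what keeps the concatenated-promoter ACF sharp at the
  pitch. Jittering each tract independently would destroy exactly the
  within-promoter phasing the ACF analysis relies on.

`simulate_foldchanges()` interpolates $\log_2\mathrm{FC}$ linearly from
`fc_first` at the 5' gene down a planted gradient Δ to the 3' gene,
plus optional Gaussian noise.

Not emulated: count-level (negative binomial) sampling and library-size
effects, genome composition beyond i.i.d. background (no codon
structure, no real intergenic grammar), TU overlap/antisense
transcription, and diurnal entrainment before induction. Passing
recovery tests therefore demonstrates correctness of the analysis
chain under its assumed generative structure, not performance on real
sequencing data.

## Numerical choices and problem sizes

EM: relative log-likelihood tolerance $10^{-8}$, max 300 iterations,
covariance ridge $10^{-6}\mathrm{tr}/d$; non-convergence returns the
best model with a warning flag. Seeded k-means: tolerance $10^{-8}$ on
center movement, max 300 iterations. All stochastic stages require an
explicit seed and are bit-reproducible given it. Planting positions
round half away from zero so ACF lag predictions are exact.

The validation suite runs the full design at study scale — 900 genes ×
15 clustered samples, $K = 2..10$ with 20 restarts (about 11 s per
selection on one core thanks to the compiled EM), 20 seeded replicates
for the modal-K check, 300 planted promoters for the anchor profile and
200 for the pitch recovery, and $B = 1000$ permutations for the null
calibration — sizes chosen to give stable recovery statistics at
interactive runtimes.

## Known limitations

* The Gaussian (rather than t) mixture can over-split in small,
  marginally separated designs; BIC margins there are a few units.
  At the default design scale selection is unambiguous.
* The period estimator is a three-point parabola around the ACF argmax;
  it assumes a single dominant peak in lags 6–15 and has a mild upward
  bias (~0.2 bp) for the alternating 10/11 spacing realized by integer
  rounding of a 10.5 bp pitch.
* Minus-strand orientation of the original scripts is not documented;
  our sense-strand convention is explicit and tested, but equivalence
  with the original code is unverified. Likewise AT2 is scanned on the
  sense strand only (the set {AA, TT} is strand-symmetric, AT/TA are
  not).
* Enrichment p-values are raw by design (display contract); the BH
  column is provided but not used by the sorting.
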