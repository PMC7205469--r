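---
title: "Quantifying 3'UTR shortening: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3'UTR shortening: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apakit)
```

# The problem

Many mammalian genes carry more than one polyadenylation (pA) site in their
3'UTR. Usage of a *proximal* pA produces a transcript with a short 3'UTR that
lacks the distal segment — the d3'UTR — and with it most conserved miRNA
binding sites. `apakit` implements a complete desk-scale analysis of this
phenomenon from short-read data: quantifying d3'UTR usage, classifying
condition-sensitive and tissue-restricted genes, screening probe-level
microarray data for ratio shifts, profiling 3'-end-complex binding around pA
sites, testing miRNA target-set enrichment, and linking 3'UTR shortening to
transcript stability in transcription-shutoff time courses.

# The d3'UTR ratio

For each gene, one transcript (the one with the longest annotated 3'UTR) is
split at its validated proximal pA into two contiguous regions of the last
3' exon:

* `upstream_last_exon` — the last coding-exon segment fused with the proximal
  3'UTR (present in *all* isoforms), and
* `d3utr` — from the pA to the distal 3'UTR boundary (present only in
  long-isoform transcripts).

A database pA is *validated* if it lies inside the terminal 3'UTR and at
least 20 bases from the distal boundary; with several candidates the most
proximal one (closest to the stop codon in transcript orientation) is used.
Using two contiguous regions of the same exon limits bias from non-uniform
coverage along the transcript.

Reads *strictly contained* in each region (`intersectBed -f 1.0` semantics,
strand-agnostic because the library prep is unstranded) are converted to RPKM
and the ratio

$$\text{d3'UTR ratio} = \frac{\mathrm{RPKM}(\text{d3utr})}
                             {\mathrm{RPKM}(\text{upstream})}$$

estimates the long-isoform proportion $\pi$: the upstream region sees every
isoform, the d3'UTR only the long ones. When no read maps to the upstream
region the ratio is `NA`, never zero — absence of evidence about the
denominator is not evidence of shortening.

**Numerical caveat (documented, not corrected).** Strict containment shrinks
a region of length $L$ to $L - \ell + 1$ valid read start positions for read
length $\ell$; RPKM divides by $L$. The ratio therefore carries a factor
$\frac{(L_d-\ell+1)/L_d}{(L_u-\ell+1)/L_u}$, about 2–5% for 50 b reads on
regions of 300–1500 b. The same bias affects the original analysis; the
synthetic-recovery criterion (mean $|\hat\pi - \pi| < 0.03$ at 20k reads per
gene) passes with it in place.

# Sensitivity classification

Differential expression between two single-library conditions uses
median-of-ratios size factors (the geometric-mean reference computed on genes
expressed in both samples) and the fold-change
$(\bar b + c)/(\bar a + c)$ with pseudocount $c = 0.5$ normalized counts.

The upstream publication names a "Z-score criterion" without defining it; our
documented stand-in bins genes into 20 equal-occupancy bins **by the
reference condition's normalized count** and computes, within each bin,
$z = (\log_2 \mathrm{fc} - \mathrm{median})/(1.4826\,\mathrm{MAD})$ with a
one-sided upper-tail normal p. Binning on the reference (not on the
two-condition mean) matters: planted up-regulated genes would otherwise
migrate into the top expression bins and inflate the robust scale estimate
there, masking themselves. Labels follow the published thresholds: sensitive
= fold-change $\ge 3$ and $p < 0.01$; neutral = fold-change strictly inside
$(1/2, 2)$.

# Size-matched comparisons

Rank-sum p-values fall with sample size, so a 3,000-gene control group would
make any tiny shift "significant". When the control is larger than the test
group, the comparison keeps only the $n_\text{test}$ control genes whose
expression fold-change is closest to 1 (smallest $|\log_2 \mathrm{fc}|$, ties
by gene id) — the most unambiguously unaffected controls. The rank-sum test
enumerates the exact null for group sizes up to 8 and uses the tie-corrected
normal approximation above that. Median confidence intervals are percentile
bootstrap (2000 resamples, seeded); the source figure legend names no CI
method, so this is a package design choice.

# Tissue restriction: SPM and CTM

For a gene with expression vector $x$ over tissues, the specificity
measurement for tissue $i$ is the cosine with the $i$-th basis vector,
$\mathrm{SPM}_i = x_i/\lVert x\rVert_2$, and the contribution measurement of
a tissue subset $S$ is $\mathrm{CTM}(S) = \lVert x_S\rVert_2/\lVert
x\rVert_2$. The publication states only the thresholds, not the formulas;
these cosine forms follow the cited TiSGeD method and are isolated in
`compute_spm_ctm()` so an alternative definition can be swapped. Per gene,
zero-expression tissues are dropped and within each similarity group (e.g.
the brain-derived tissues) only the highest-expressing member is kept.
Labels: specific if some SPM $> 0.9$; selective if exactly 2–4 tissues have
SPM $> 0.3$ *and* their joint CTM $> 0.9$; otherwise unassigned. For
selective genes the peripheral tissue used in ratio comparisons is drawn
uniformly (seeded) among the tagged tissues.

# Probe-level microarray screen

Probe-level d3'UTR ratios divide the mean intensity of d3'UTR probes by the
mean intensity of all probes of the transcript (linear scale), requiring at
least two d3'UTR probes. Probes must exceed the background — the 5th
percentile of each sample's intensities, a package choice since the original
filter threshold is unstated — in every compared sample. Per-gene direction
calls use a Welch t-test across replicate-level ratios at $\alpha = 0.05$
(the original defers to an unpublished script; Welch is the simple symmetric
choice given duplicate arrays), falling back to a flagged fold-change rule
when replicates are missing.

**Known conservatism.** With duplicate arrays the Welch test has null
rejection ≈ 0.022 at nominal 0.05 (Satterthwaite df between 1 and 2), so
per-gene calls are conservative, never anti-conservative. The genome-wide
imbalance test is unaffected: the 2×2 chi-squared comparing
{increase, decrease} counts between a candidate and a control screen is
calibrated (rejection 0.05 ± 0.01 in a 10,000-screen null simulation at
genome-wide screen sizes), because both arms share whatever per-gene rate the
test achieves. Star labels follow the published convention: `*` for
$p < 10^{-4}$, `**` for $p < 10^{-9}$; zero margins divert to Fisher's exact
test, flagged.

# Classic GSEA

The enrichment score is the unweighted Kolmogorov–Smirnov running sum: hits
add $1/N_{hit}$, misses subtract $1/(N - N_{hit})$; the ES is the extremum of
largest magnitude. The running sum is scored in exact integer arithmetic
(numerator $hN - iN_{hit}$), with the positive extremum preferred on exact
ties — floating-point accumulation would otherwise make tie-breaking
platform-dependent. Sets are filtered to 15–5000 members present in the
ranked universe; zero-metric genes are removed before ranking and ties break
lexicographically. With one library per condition a sample-label null is
impossible, so p-values and NES come from gene-set permutation (default
1000), with same-sign tail p-values and the standard pooled-NES FDR. The
leading edge is the prefix (suffix for negative ES) up to the ES-attaining
rank; genes appearing in ≥ 5 significant (FDR q < 0.05) set leading edges are
selected, mirroring the ≥ 5-miRNA selection. The ranking metric is the log2
fold-change of median-of-ratios-normalized counts.

# Coverage metaprofiles and decay

`site_metaprofile()` averages per-base coverage in windows of ±`window`
(default 1000 b) around pA sites, reverses minus-strand windows so bins run
5'→3', and averages into bins of `binsize` (default 10 b; typical defaults of
the sitepro-style tools, unstated in the original). The strand-reflection
property is exact on the per-base profile; binned profiles mirror only up to
the half-bin phase of the fixed bin grid. Sites whose window leaves the
chromosome are skipped with a warning.

Decay analysis compares transcription-inhibited samples with an untreated
control on total-count-normalized expression,
$\mathrm{rel}(g,t) = \frac{(n_{g,t}+c)/N_t}{(n_{g,0}+c)/N_0}$, $c = 0.5$
raw counts. Shortening classes from control/knockdown ratio pairs:
*decreased* iff $r_{ctr}/r_{kd} < 0.5$ (strict, so exactly 0.5 is not
decreased); *steady* iff within 1.2-fold (the original does not define
"steady"; the band is a documented choice); otherwise *other*. Groups are
compared per timepoint by a two-sided rank-sum test (`NA` below 3 genes per
group); loess curves (span 0.75, degree 2) are descriptive only and never
tested numerically.

# What the synthetic data does and does not establish

The generators plant every ground truth the analyses assume:

* **Annotation**: mammalian-scale geometry — 3'UTRs of 600–1500 b, last
  coding-exon segments of 200–800 b, d3'UTRs ≥ 300 b, 1–3 upstream exons;
  80% of genes carry a proximal pA, ≥ 20 b from the distal boundary by
  construction.
* **Reads**: 50 b single-end, unstranded, uniform within isoform bodies,
  molecules weighted by isoform length (standard shotgun sampling); a gene's
  long-isoform fraction $\pi$ is the planted truth the ratio must recover.
* **Conditions**: sensitive genes planted at 3–8× expression effects;
  their $\pi$ sits 0.3 below neutral genes *in both conditions* — in this
  world shortening is cell-intrinsic, the condition effect touches
  expression only, which is what makes the small-ratio concordance between
  conditions high.
* **Tissue matrices**: specific (1 tissue) and selective (2–4 tissues) genes
  at signal:background 50:1 with log-normal noise (sdlog 0.3 by default; the
  noiseless recovery criterion sets it to 0).
* **Probes**: ≥ 2 d3'UTR probes per gene (optionally demoted to 1 to
  exercise the exclusion rule), multiplicative log-normal intensity noise,
  duplicate arrays per condition.
* **Decay**: first-order decay $2^{-t/t_{1/2}}$ with Poisson counts and
  class half-lives (2 h / 6 h / stable anchors); timepoints 3, 6, 12 h.
* **CLIP coverage**: Gaussian peaks (sd 25 b) on uniform background at
  proximal pAs.

Everything is deterministic given the seed. What a green suite does **not**
establish: robustness to alignment artifacts, GC and positional coverage
bias, annotation errors, overlapping genes, multi-isoform mixtures beyond
two 3'UTR isoforms, or array normalization effects — none of these are
simulated. The probe-ratio statistic (d3'UTR over whole-transcript mean) is
a monotone but nonlinear function of the planted isoform fraction, so probe
screens validate direction calls, not ratio values.

# Degenerate inputs and tie-breaks, in one place

* pA coincident with the distal boundary, or < 20 b from it → gene treated
  as single-pA (no d3utr feature; excluded from ratios).
* Upstream read count 0 → ratio `NA`, propagated, never dropped silently.
* Library size 0 → error at RPKM; fewer than 50 genes expressed in both
  samples → error at size factors.
* MAD 0 within an expression bin → falls back to the bin SD, then to a
  machine epsilon (z = 0).
* Zero expression vector → tissue gene unassigned; constant vectors → error
  in the ratio/expression correlation.
* Multiple transcripts per gene → longest total 3'UTR, ties by transcript id.
* All randomized procedures (matching ties, selective-tissue draws,
  permutations) are seeded and permutation-invariant.

# Open design decisions taken

* The 20-base pA distance is measured in genomic coordinates within the
  terminal 3'UTR exon (the spliced-coordinate alternative is unstated
  upstream; terminal-exon splitting makes the two coincide except for
  multi-exon 3'UTRs, whose internal-exon pAs are ignored anyway).
* Paired-end data is consumed as independent reads.
* Configuration files are JSON rather than YAML (no YAML parser among the
  package's allowed dependencies); the R API takes plain lists.
* The loess x-axis in decay plots is the timepoint; the original legend is
  ambiguous and the curves are cosmetic.
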