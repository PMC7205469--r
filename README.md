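# apakit

Alternative polyadenylation (APA) analysis from RNA-seq, probe-level
microarray and coverage data, for transcriptome scientists studying 3'UTR
shortening — for example, the preference of promiscuously expressed,
tissue-restricted genes for short-3'UTR isoforms in medullary thymic
epithelial cells, and the escape from miRNA repression that follows.

## The core statistic

Genes with a validated proximal polyA site (pA) are split at that site into
two contiguous regions of the last 3' exon: the upstream segment (last
coding-exon portion fused with the proximal 3'UTR, present in all isoforms)
and the distal 3'UTR (**d3'UTR**, present only in long isoforms). A database
pA is validated when it lies in the terminal 3'UTR at least 20 b from the
distal boundary; the most proximal valid site is used. From reads strictly
contained in each region,

```
d3'UTR ratio = RPKM(d3'UTR) / RPKM(upstream last-exon segment)
```

estimates the long-isoform proportion π of the gene. Around this the package
provides:

* **Sensitivity classification** — median-of-ratios normalization, binned
  robust Z-scores; sensitive = ≥3-fold with p < 0.01, neutral = <2-fold.
* **Size-matched Wilcoxon comparisons** — controls matched to the test-group
  size by closest-to-1 fold-change; exact rank-sum null for small groups.
* **Tissue restriction** — cosine SPM/CTM scores; specific (SPM > 0.9) and
  selective (2–4 tissues SPM > 0.3, CTM > 0.9) labels.
* **Probe-level microarray screens** — per-gene d3'UTR ratio direction calls
  (≥2 d3'UTR probes, Welch across replicates) and a 2×2 chi-squared
  increase/decrease imbalance test (`*` p < 1e-4, `**` p < 1e-9).
* **Classic GSEA** — unweighted KS enrichment score in exact integer
  arithmetic, 15–5000-member sets, gene-set permutation p/NES/FDR,
  leading-edge summaries with the ≥5-set selection.
* **Coverage metaprofiles** around pA sites and **decay time-course**
  analysis (total-count-normalized relative expression, <0.5× shortening
  classes, per-timepoint rank-sum tests).
* **Synthetic data generators** with planted ground truth for every input,
  and an end-to-end pipeline.

## Worked example

```r
library(apakit)
s <- run_apa_analysis(default_pipeline_config(seed = 1))
```

runs the full synthetic analysis (500 genes, 80% with a proximal pA,
planted 3–8× sensitive genes whose long-isoform fraction sits 0.3 below
neutral genes, a 200-gene microarray screen with 60 planted shifts, a
22-tissue matrix, and a 3/6/12 h decay course). With seed 1 it prints, via
`str(s)` or the JSON summary:

```
sensitivity:      48 genes called sensitive; recovery 0.96, FDR 0.000
ratio comparison: median d3'UTR ratio 0.234 (sensitive) vs 0.578 (matched
                  neutral), size-matched Wilcoxon p = 6.4e-06 (n = 32)
small-ratio concordance between conditions: 0.69 (<0.25), 0.93 (>0.25)
screen:           chi-squared 26.0, p = 3.4e-07, label "*", 36 genes in the
                  <0.5x shortening class
enrichment:       both planted miRNA-style sets significant, top set
                  mir_planted_01
decay:            decreased-vs-steady rank-sum p < 1e-48 at 3, 6 and 12 h
```

Planted sensitive genes are recovered at their lower d3'UTR ratios, the
screen detects the planted ratio increases against a null comparison, and
the planted half-life classes separate at every timepoint. Per-stage tables
(`ratios_*.tsv`, `de.tsv`, `screen.tsv`, `gsea.tsv`, ...) and `summary.json`
are written when `out_dir` is given; a run is byte-reproducible under a
fixed seed.

A command-line wrapper with `annotate`, `quantify`, `diffexpr`,
`metaprofile` and `run` subcommands is installed at `inst/cli/apa.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/apa.R", package="apakit"))') run --seed 1 --out out/`).

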