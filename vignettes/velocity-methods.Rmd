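---
title: "Estimating Pol II elongation velocity from TT-seq and mNET-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Pol II elongation velocity from TT-seq and mNET-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velocitt)
```

## The measurement problem

Acute depletion of an elongation factor (for example via a dTAG degron) can
change how fast RNA polymerase II moves through gene bodies within an hour.
Neither of the two standard nascent-transcription assays measures velocity
directly:

* **TT-seq** sequences RNA synthesized during a short (5-minute) 4sU pulse.
  At steady state the labeled output at any gene position is proportional to
  the polymerase *flux* — initiation rate × pulse length — and is
  *independent* of velocity: slower polymerases are denser but each
  synthesizes proportionally less during the pulse.
* **mNET-seq** maps the last incorporated base of the nascent RNA in engaged
  polymerase, giving single-nucleotide occupancy. Occupancy is proportional
  to initiation rate ÷ velocity.

Their ratio,

$$ \hat v \;\propto\; \frac{\text{normalized TT-seq signal}}
                          {\text{normalized mNET-seq signal}}, $$

cancels initiation and tracks elongation velocity up to a global constant.
`velocitt` computes this statistic two ways, following the conventions of the
study design it models: per 50-bp genomic bin (TT-seq fragment **midpoint**
coverage over mNET-seq coverage; bins with no mNET-seq signal are `NA`), and
per gene (ratio of normalized counts over the gene body **excluding the first
1 kb**, which removes the promoter-proximal region where pausing and
divergent initiation would otherwise distort the ratio). Replicates are
normalized per sample and summed before the ratio is taken; summing rather
than averaging matches how replicate coverages are combined for profiles and
makes the two routes consistent.

Because the ratio is only defined up to the assays' capture constants, all
reported quantities are *changes* — `log2(treated / control)` per gene or per
bin — in which the constants cancel. Halving velocity should therefore appear
as a median per-gene log2 change of −1.

## Normalization

Global velocity changes move *every* gene in the same direction, which
defeats total-count normalization. Anchors of constant true abundance are
required:

* TT-seq and mNET-seq: synthetic spike-in RNAs (three 4sU-labeled, three
  unlabeled; only the labeled ones survive 4sU selection and are used).
* ChIP-seq: counts at non-transcribed regions, validated at construction to
  overlap no gene.

Size factors are median-of-ratios against a per-row geometric-mean
pseudo-reference, computed as `exp(median(log ratios))` — exactly the DESeq2
definition (a unit test asserts agreement with
`DESeq2::estimateSizeFactorsForMatrix` to 1e-10). Rows containing any zero
are excluded. Factors are not rescaled to geometric mean 1; only their ratios
matter downstream, and indeed only ratios are equivariant under rescaling a
single library (the pseudo-reference itself moves, so the often-quoted
"scaling one sample scales its factor" holds for factor ratios, not raw
factors).

## Counting conventions

Gene-level counts use strand-specific `IntersectionNotEmpty` assignment:
bases shared by two or more same-strand genes are discarded, and a record is
assigned if its remaining overlap is with exactly one gene. Records
overlapping genes but resolvable to none are tallied as ambiguous, records
overlapping nothing as unassigned; `assigned + ambiguous + unassigned` always
equals the number of input records, and a brute-force per-base enumeration
oracle checks the mode on overlapping toy sets. mNET-seq records are width-1
last-incorporated-base tags; TT-seq gene-body counts use whole fragments
(velocity bins use fragment midpoints). Expressed genes are those with median
reads-per-kilobase across TT-seq samples strictly above 10 that overlap no
other gene.

## Metagene profiles and heatmap matrices

Scaled metagene profiles divide each gene body into `n_body_bins = 100` equal
spans flanked by 50 fixed-width bins covering 2.5 kb on each side (the flank
layout is a package choice; fixed-bp flanks keep promoter-proximal features
aligned). Values are `log2(x + 1)` of normalized, replicate-summed coverage
— the pseudo-count of 1 makes silent positions map to 0. The mean profile is
reported with a 95% percentile bootstrap band over genes (10,000 iterations
by default, deterministic given a seed). The percentile interval was chosen
over BCa/normal variants as the simplest consistent bootstrap; its
calibration is itself tested — on Gaussian gene sets of n = 100 the interval
covers the truth in 95% ± 2% of replicate datasets.

Two heatmap matrices mirror the figure conventions: TSS-anchored fixed
50-bp-bin log2-change rows with the gene-end bin recorded (so heatmaps can
trace gene ends), `NA` where both conditions are silent; and
gene-center-anchored 500-bp-bin rows in which bins not fully inside the gene
body are masked `NA`, preventing neighbouring genes from contaminating the
signal (used for gene-body chromatin marks such as H3K36me3).

The downward **tilt** that develops in long genes after a velocity drop is
quantified as `tilt_statistic`: mean of the last quartile of body positions
minus mean of the first quartile of a per-gene change profile. Genes are
compared across empirical length quartiles (shortest → longest, remainders
assigned to the shorter groups, ties broken by gene id).

## The simulator

Every stage is verified by parameter recovery on data from an explicit
kinetic model:

* initiation is a Poisson process per gene (default 2 polymerases/min,
  typical of an actively transcribed gene);
* each polymerase moves deterministically at a piecewise-constant velocity
  over gene-body position (default 2 kb/min), multiplied by a condition
  factor from its onset time (control factor 1); depletion is modeled as an
  instantaneous global factor (default 0.5 at onset 0, sampled after 60 min
  — the one-hour treatment — with a 5-min label pulse);
* polymerases vanish at the TES; a warm-up of twice the slowest full-gene
  transit time precedes sampling so occupancy is at steady state at onset;
* mNET-seq emits each engaged polymerase's active-site base with
  Poisson(`mnet_depth`) sequenced copies; TT-seq fragments the gene segments
  traversed during the pulse (uniform fragment lengths 150–300 bp,
  Poisson(`ttseq_depth` per kb) counts); ChIP-seq draws gene-body signal
  plus genome-wide uniform background; spike-ins emit
  Poisson(copies × library scale) fragments on their own "chromosomes".

Depth parameters are capture *rates*, constant across conditions within a
sample: total mNET-seq output then scales with occupancy, which is exactly
the global shift spike-in normalization exists to expose. Per-library depth
differences enter only through `library_scale`. Defaults
(`ttseq_depth = 2`/kb ≈ RPK 20 for expressed genes, `mnet_depth = 40`
reads/polymerase ≈ 20–40 tags/kb, `chip_background = 20`/kb deep-input-like
background) give the per-gene counting depth at which recovery statistics
are dominated by biology rather than shot noise.

Two consequences of the model are worth knowing when reading test output.
First, per-gene coverage fluctuates with polymerase-count granularity
correlated over the ~5 kb pulse-wave scale, so per-gene ratios are noisy on
short genes; recovery checks therefore aggregate over ≥ 40 genes. Second,
after an instantaneous velocity drop the distal side of the post-onset
wavefront is supplied at the *old* polymerase flux through conserved
density, so labeled coverage beyond the wavefront is exactly
`v_new/v_old = 0.5` of the proximal level in expectation — the property
tests assert that value rather than a one-sided inequality.

What the simulator does **not** emulate: promoter-proximal pausing,
backtracking, termination dwell, RNA degradation, splicing and intron
retention, nucleosome barriers, sequence-level reads (no FASTQ or alignment
error), and empirical fragment-size distributions. Passing recovery tests
therefore demonstrates that the *statistics* behave as designed under the
stated kinetic model, not that every feature of real nascent-RNA data is
reproduced. One visible artifact of uniform fragmentation is a few-percent
coverage modulation near labeled-segment boundaries; it is identical in
both conditions and cancels in change statistics beyond ~±0.05 on short
genes.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout (BED native); conversion
  happens only at format boundaries. Strand-specific bedGraphs are written
  as a `.plus`/`.minus` file pair.
* Even-length fragment midpoints round right of center (`(s + e) %/% 2`).
* Genes no longer than the 1-kb exclusion get `NA` velocity with a warning;
  genes shorter than `n_body_bins` bases are skipped from metagene matrices
  with a warning.
* The Wilcoxon tests use the exact distribution for n ≤ 25 without ties and
  the tie-corrected, continuity-corrected normal approximation otherwise
  (zeros dropped first). Exact p-values are verified against exhaustive
  sign-pattern/assignment enumeration.
* Boxplot hinges are type-7 quantiles; notches are
  `median ± 1.58·IQR/√n`; whiskers are attained data values within 1.5·IQR
  of the hinges.
* Bootstrap resampling uses multinomial row weights (`rmultinom`), making
  10,000 iterations a single matrix product and the result reproducible
  from one integer seed.
* Per-bin change heatmaps report the difference of `log2(x + 1)` values
  (equivalently the log2 ratio of pseudo-counted normalized coverages);
  log2 changes of the velocity ratio itself propagate `NA` and treat
  non-positive ratios as `NA`.

## Pipeline reproducibility and problem sizes

`run_all()` (or the `exec/velocitt` command-line wrapper) chains
simulate → count → normalize → velocity → profiles → report from one YAML
configuration whose defaults are the constants above. One master seed
expands into fixed-order per-sample substreams, so identical (config, seed)
runs are byte-identical; every output table carries a provenance header
(package version, config MD5, seed).

The bundled recovery analyses use 200 genes of 10–100 kb for velocity and
tilt recovery, 100 genes for ChIP background checks, 1,000 replicate
Gaussian datasets for bootstrap calibration, and a 20-gene smoke
configuration (`inst/extdata/smoke_config.yaml`, 100–200 bootstrap
iterations) for end-to-end determinism — sizes at which every recovery
statistic is comfortably inside its tolerance while a full run stays in the
minutes range on one CPU.

## Known limitations

The velocity statistic is a proxy up to a global constant — no absolute
kb/min is reported. Significance calls on per-gene expression changes are
limited to rank tests and |log2FC|; negative-binomial per-gene testing
(dispersion estimation, Wald/LRT, shrinkage) is deliberately out of scope,
as are alignment, duplicate removal, exon-aware counting and intron-retention
analysis. Real-data import is via BED6 files of aligned fragments/tags
arranged like the simulator's output; BAM conversion is left to standard
tools upstream.
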