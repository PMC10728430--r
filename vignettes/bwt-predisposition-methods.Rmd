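---
title: "Methods: 11p15.5 imprinting, mosaicism and germline triage in bilateral Wilms tumor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 11p15.5 imprinting, mosaicism and germline triage in bilateral Wilms tumor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwtmosaic)
```

## The problem

Synchronous bilateral Wilms tumor is strong evidence of predisposition: two
kidneys independently develop tumors only when an initiating lesion precedes
the lateralization of the kidney primordia. Two lesion classes dominate. A
*pre-zygotic* germline variant is present in every cell and is detected by
sequencing blood DNA. A *post-zygotic* epigenetic lesion — gain of
methylation on the maternal *H19*/ICR1 allele at 11p15.5, i.e. loss of
imprinting (LOI) — occurs in an early embryonic cell and is thereafter
*mosaic*: complete in tumors, substantial in adjacent non-diseased kidney
(clonal nephrogenesis), and present at low fraction in blood, whose
hematopoietic progenitors share the mesodermal origin of the kidney.
`bwtmosaic` classifies each patient into one of these modes and grades the
anatomical spread of the mosaic evidence.

## Imprinting classification

Region means of probe-level β are computed over fixed GRCh38 windows,
chr11:2,019,974–2,024,738 (*H19*/ICR1) and chr11:2,721,228–2,722,228
(*KCNQ1OT1*/ICR2), both ends inclusive to match the printed hyphenated
ranges. The classifier is a threshold grid with strict inequalities
(ICR1 0.7, ICR2 0.3, both exposed in `bwt_config()`); a β exactly at a
threshold falls in no stated cell and is returned as INDETERMINATE with a
warning rather than silently binned. A copy-neutral-LOH call from
sequencing, when supplied, forces LOH: allelic imbalance is more direct
evidence than methylation, and partial cnLOH can leave β between thresholds.

Classification operates on *raw observed β*, with no purity pre-correction —
this mirrors how such cohorts are actually called, and keeps the classifier
a pure function of its stated inputs. The purity mixture model below is
provided as a diagnostic to show which low-purity samples risk a false-ROI
call.

## Purity mixture and mosaic fraction

A sample containing a fraction *p* of altered cells observes
`β_obs = p·β_state + (1 − p)·β_normal`, with pure-state betas LOI
(1.0, 0.5), LOH (1.0, 0.0), ROI (0.5, 0.5) and a normal baseline of
(0.5, 0.5). The baseline is config-exposed because real tissues sit slightly
off 0.5. The inversion `f = clip(2(β₁ − 0.5), 0, 1)` estimates the mosaic
fraction; for LOH the ICR2 inversion `2(0.5 − β₂)` is averaged in, halving
the estimator variance. Clipping absorbs probe noise at the extremes; at
region-level noise SD 0.01 the estimator's mean absolute error is about
0.016 (the test suite verifies ≤ 0.02 over 1,000 replicates).

## Low-level blood gain of methylation

Blood β never approaches the 0.7 diagnostic cutoff in mosaic patients; the
pipeline instead thresholds against a healthy-control cohort at
mean + 2·SD. The SD is the sample estimator (n − 1) — the controls are a
sample, and with the reference control summary (mean 0.499, SD 0.0248)
either estimator reproduces the 0.54864 cutoff to four decimals. The call
is strictly greater-than: a β exactly at the threshold is not a call.

## Germline triage

The decision procedure is a total, ordered rule list (every variant fires
exactly one rule): panel membership gate; automatic inclusion of
indel/nonsense variants; ClinVar pathogenic/likely-pathogenic in,
benign/likely-benign out (benign precedes and therefore vetoes predictor
evidence); uncertain variants in with PROVEAN-deleterious or PolyPhen-2
(possibly) damaging calls; finally, uncertain variants rescued by tumor VAF
enrichment. The enrichment test is deliberately conservative: a one-sided
Fisher exact test on the 2×2 alt/ref × tissue table *and* an effect-size
floor (tumor VAF − germline VAF ≥ 0.15, config-exposed), so ultra-deep
sequencing cannot promote a negligible shift. No multiple-testing correction
is applied across variants by default. Splice variants of uncertain
significance flow through the same uncertainty-plus-evidence rules as
missense — they are not auto-included. The shipped panel is the 21
Wilms-tumor predisposition genes; the full 565-gene cancer panel is a
user-supplied file since it is defined outside this package's sources.

## Pair concordance and embryonic timing

Coding variants match on (gene, protein change); entries transcribed without
a protein change never match, because a gene symbol alone does not identify
a variant. Noncoding variants match on exact (chrom, pos, ref, alt) — calls
from the same patient's WGS share coordinates, so fuzzy matching would only
add false sharing. Copy-number similarity is the Pearson correlation of
1-Mb-binned segment values, with uncovered bins imputed 0 (absence of a call
is closest to neutral); a constant profile makes the correlation undefined
and similarity is then defined as the identity indicator. The origin call is
monotone in sharing: ≥ 20 shared noncoding variants *and* similarity ≥ 0.9
(invented cutoffs separating the typical 1–6 range from the flagged 63) →
suspected multifocal tumor of one kidney; any sharing → a common early
embryonic clone; none → independent origins. For the transcribed reference
pairs no copy-number profiles are printed, so the fixture carries a
similarity of 0.95 only for the one pair described as having a nearly
identical profile and NA elsewhere; NA fails the atypical test by design.

## Mode assignment

Germline positivity takes precedence: tumor LOH in a *WT1* carrier is a
somatic second hit, not a competing mode, and the rarer germline-plus-LOI
combination is kept as GERMLINE_GENETIC with an `loi_coannotation` flag.
Otherwise any tumor LOI yields POSTZYGOTIC_MOSAIC_LOI; all-ROI patients
remain UNCLASSIFIED. The mosaicism tier escalates tumor → kidney → blood,
requiring the kidney step before blood evidence counts (a blood signal
without kidney involvement is more likely noise than a mesodermal mosaic),
and blood evidence is either the low-level GOM call or a supplied mosaic
cnLOH flag (quantitative blood cnLOH detection from WGS is consumed, not
computed). INDETERMINATE calls are excluded from association tables with a
logged count.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` plants a known mode per patient (default mixture 0.41
germline / 0.45 mosaic LOI / 0.14 other, approximating reported cohort
fractions), then emits blood, adjacent kidney and two tumors per patient
through the forward mixture model: kidney mosaic fractions Beta(6, 4)
(mean 0.6 — clonal nephrogenesis is extensive), blood fractions Beta(1, 19)
(mean 0.05 — low-level only), tumor purity Uniform(0.5, 1), probe β = latent
region mean + truncated Gaussian noise (SD 0.02). Germline carriers are
*WT1* with probability 0.36 (the reported carrier share), in which case both
tumors get 11p cnLOH segments with independent random breakpoints and
CTNNB1 exon-3 variants with probability 0.714; mosaic pairs share a
truncated-Poisson(2) ≥ 1 number of noncoding variants against Poisson(80)
private ones. Ground truth is emitted alongside and never read by the
pipeline.

Deliberately not modeled: probe-level chemistry and within-region
correlation (region means are the only consumed statistic, so β noise is
truncated Gaussian on the β scale rather than logit-normal), genome-wide
mutation spectra, clonal phylogenies beyond one embryonic split, and
tissue-specific baselines off 0.5. A green end-to-end test therefore
establishes that the pipeline's logic recovers planted truth under its own
forward model — not that the model captures every feature of real arrays.

## Numerical choices and degenerate inputs

β is clipped to [ε, 1 − ε] (ε = 1e−6) before the logit2 M-value transform.
An ICR window containing no probes raises an error rather than returning
β = 0. Zero sequencing depth makes the VAF test untestable (not enriched,
p missing). Degenerate contingency tables and constant correlation inputs
raise errors. Group comparisons use Welch t (2 groups) or one-way ANOVA
with pairwise Welch tests (≥ 3); the pairwise correction defaults to Holm —
valid without equal-variance or balance assumptions — switchable to Bonferroni or
others via `p.adjust` methods. Kolmogorov–Smirnov normality checks are
reported as diagnostics, never as gates.

## Known limitations

Purity is consumed, never estimated (methylation deconvolution is out of
scope); annotation itself (ClinVar/PROVEAN/PolyPhen lookups) is an input;
the 0.54864 cutoff is reproduced from the control summary, not re-derived
from raw control arrays; and the shipped reference tables are transcriptions
— where published summary and detail counts disagree (e.g. 15 vs 16 ROI
tumors), the fixtures follow the per-table numbers.
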