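---
title: "Classifying circulating rare cells and validating the pipeline on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying circulating rare cells and validating the pipeline on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcatlas)
```

## Scope and assumptions

`crcatlas` operates strictly downstream of image analysis. Its input is a
per-cell event table: one row per detected nucleated cell, carrying boolean
stain calls for CD45 (hemocyte), CD31 (endothelial), Vimentin (mesenchymal)
and one panel marker (a tumor marker such as EpCAM/CK18/PD-L1/AFP/HER2/CA19-9
on the tumor panel, or CD133 on the stem panel), a cell size (measured
diameter in µm and/or an explicit small/large class), and FISH spot counts
for CEP8 and optionally CEP12. Stain intensities, segmentation and spot
detection are upstream concerns; every call here is already boolean. Two
standing assumptions: every record is DAPI+ (the scanning platform only
emits nucleated events), and within one patient only the first sample is
aggregated, so repeat draws never inflate per-patient totals.

## Ploidy calling and what counts as aneuploid

A centromeric enumeration probe yields one spot per chromosome copy, so spot
counts map directly to copy-number classes; five or more spots are pooled as
`multiploid` because individual spots become unreliable to resolve in highly
polyploid nuclei. Two decisions here were genuinely open:

* **Zero spots is a QC failure, not a haploid call.** A nucleus with no
  hybridisation signal is indistinguishable from a failed hybridisation;
  `qc_fail` events are excluded from every count and never satisfy
  aneuploidy.
* **Haploid counts as aneuploid by default.** Monosomy 8 is a genuine
  karyotypic aberration and haploid rare cells are observed in clusters of
  circulating cells; since copy number 1 is not 2, the default aneuploidy
  rule is `class not in {diploid, qc_fail}`. Because single-spot calls are
  the most vulnerable to sectioning artefacts, every entry point accepts
  `aneuploid_min3 = TRUE` to restrict aneuploidy to three or more copies for
  sensitivity analyses; none of the shipped results depend on the switch.

## The gate order and the 71-leaf atlas

Small cells (diameter less than or equal to the mean WBC diameter — ties are
small; default reference 10 µm, overridable per slide, with an explicit
`size_class` taking precedence over the diameter) are gated on CD45 first,
because the dominant small-cell population is residual leukocytes. Large
cells are gated on ploidy first. Both branches apply the same row-wise
rules, so the implementation is one vectorised rule set; the 224-case truth
table in the test suite pins the partition against a branch-by-branch oracle
written from the gate description.

The atlas factorises as 2 sizes x 4 aneuploid ploidy classes x 8 marker
combinations (64 leaves) plus 7 size-agnostic diploid leaves with at least
one positive marker, 71 in total. The published leaf list is a figure, not a
machine-readable table; this factorisation was adopted because it matches
the printed total exactly, honours the small/large and ploidy-first
ordering, and accommodates the observed diploid multi-marker rare cell. The
atlas is exported as a data table (`enumerate_atlas()`, `crc atlas export`)
precisely so an alternative factorisation can be swapped in without touching
the classifier. Three related choices:

* **CD45+ aberrant cells and cluster status sit outside the 71 leaves** (as
  the `hematologic_crc` category and the `CTM_member`/`fusion_cluster`
  annotations) because the stated atlas axes are size, ploidy and marker
  expression only.
* **CD45− diploid marker-negative events are `diploid_null`, not rare
  cells**: they are indistinguishable from stripped normal cells, and
  "naked nuclei" rare cells are described as aneuploid.
* **The stem panel shares the PM axis** (one abstract panel-marker axis);
  `panel_marker_name` is carried through for reporting, and stem-panel
  events are excluded from the CTC predicate, which is defined on the tumor
  panel.

Annotations (`classical_CTC`, `EMT_CTC`, `classical_CTEC`,
`mesenchymal_CTEC`, `stem_like`, `endothelial_progenitor_like`,
`naked_nuclei`, `fusion_cluster`, `CTM_member`) are reporting vocabulary
only and never affect counting.

## Cohort statistics

Positivity is the percentage of patients with CTC count strictly greater
than zero — CTCs only, not CTC+CTEC, matching the convention of published
positivity columns. Rounding follows print conventions: percentages half-up
to one decimal, medians to two. The Kruskal–Wallis H uses pooled mid-ranks
with the tie correction `C = 1 - sum(t^3 - t)/(N^3 - N)` and a chi-square
upper-tail p-value with k−1 degrees of freedom regardless of group size (the
behaviour of standard statistical software; no exact permutation p-value).
All pooled values identical makes `C = 0` and the test undefined — that is
an error, not a silent `H = 0`. The dual-probe comparison uses a paired
two-tailed t-test on the within-patient differences of the per-patient
CEP8- and CEP12-aneuploid cell totals, because both totals come from the
same patients; a Welch switch (`paired = FALSE`) is provided. A constant
nonzero difference has zero variance and raises a degenerate-test error.

## The synthetic cohort generator: a stated world

The study's raw per-cell data are not deposited, so validation uses a
generator whose parameters are fixed up front:

* **Counts.** Per-patient rare-cell totals follow a hurdle model: zero with
  probability `1 - positivity`, else `1 + NegBin(size = dispersion, mu)`.
  Only medians, positivity and a maximum (1,636) are published, so a
  heavy-tailed overdispersed family was chosen, with default dispersion 1.5;
  `mu` is set by a deterministic grid search so that the analytic mixture
  median equals the rounded target median. A positive target median with
  positivity at or below 0.5 is reported as infeasible rather than fitted.
* **Shipped parameters.** All 31 disease groups get their published
  positivity (from the cohort-count table shipped in `extdata`); the six
  groups with published medians (infectious 22, pancreas 19, maxillofacial
  7, stomach 14, colorectal 15, ampulla 15) get them, all others a neutral
  default of 8. Marker-combination defaults put 0.55 of per-cell mass on
  CD31-involving combinations, 0.10 on tumor-marker-positive ones and 0.15
  on triple-negatives — invented placeholders encoding the qualitative
  claim that endothelial features are prevalent and epithelial markers
  low-frequency, never to be read as measured frequencies. Ploidy defaults
  are trisomy-dominated (0.05/0.10/0.45/0.20/0.20 over
  haploid/diploid/triploid/tetraploid/multiploid).
* **Closure by construction.** Cells are sampled so that every generated
  rare cell satisfies the CTC or CTEC predicate: CD31+ or fully
  marker-negative cells are restricted to aneuploid classes (diploid
  chromosome 8 is only compatible with the CTC definition via a positive
  tumor marker), and the first cell of every positive patient is drawn from
  the CD31− combinations so that count positivity coincides with CTC
  positivity. Residual WBCs are added as Poisson background (mean 8
  CD45+ diploid events per patient).
* **Dual probe.** The co-detection pseudo-group (`codetection`) emits CEP12
  counts for every event: concordant-aneuploid with probability 0.6, else
  diploid; with patient-level probability 0.5727 one CEP8-diploid /
  CEP12-aneuploid CD45− tumor-marker-positive cell is injected
  (unconditionally on the patient's drawn count). Its ploidy frequencies
  carry no diploid mass and its target median is 12, so the per-patient
  CEP8-aneuploid total equals the drawn count and its median recovers the
  published CEP8 median; positivity 0.95 is an invented operating point for
  this pseudo-group, which is used only for dual-probe statistics.
* **Determinism.** Every patient draws from an RNG substream derived by a
  counter-based hash of (seed, group, patient index), so generation is
  byte-reproducible and independent of which other groups are generated.

What a green test establishes: the classifier and aggregator invert the
generator (parameter recovery at the stated tolerances), and the statistics
reproduce published arithmetic exactly. What it does not establish: that
real cohorts follow a hurdle negative binomial, that the marker/ploidy
frequency defaults are realistic, or anything about image-level accuracy.

Two small, documented approximations: patients with zero generated events of
any kind leave no trace in the event table and therefore drop out of
aggregation (probability about `exp(-8)` per patient at the default WBC
background — negligible); and the 0.6 CEP12 concordance is an invented
constant, so the CEP12 median is emergent rather than calibrated (it lands
near, not exactly on, the published 8.0).

## Numerical choices and degenerate inputs

Half-up rounding is implemented explicitly (base R rounds half to even).
The hurdle-model grid search scans `mu` in steps of 0.01 up to 500 and takes
the midpoint of the feasible interval, so fitted models sit away from median
boundaries. Empty event tables classify to empty labeled tables (exit 0 with
a warning); a single-group cohort reports medians and skips the
Kruskal–Wallis test with a message; mixed patient ids in single-patient
aggregation, missing mandatory columns, and malformed boolean/count cells
are errors that name the offending column and row numbers.

## Known limitations

No probabilistic/soft classification or marker-intensity modelling; no
probes beyond CEP8/CEP12 and no spot pairing within nuclei; no longitudinal
modelling (`sample_id` is carried but only the first sample is analysed);
the generator makes no attempt at cluster/CTM synthesis, so cluster
annotation is exercised by constructed fixtures rather than simulation.
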