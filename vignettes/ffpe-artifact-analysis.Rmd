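---
title: "Quantifying FFPE artifacts in oncopanel sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FFPE artifacts in oncopanel sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncopanelQC)
```

## The problem

Formalin fixation and paraffin embedding (FFPE) is the routine preservation
method for clinical oncology specimens, and FFPE material is what targeted
("oncopanel") sequencing assays usually receive. Fixation chemistry damages
DNA: hydrolytic deamination converts cytosine to uracil, which downstream
reads out as C>T (equivalently G>A on the other strand) substitutions at low
allele fraction, and oxidative damage to guanine (8-oxoG) reads out as G>T /
C>A transversions. Against a known germline background these appear as
*false-positive* (FP) variant calls, inflating quantities such as tumor
mutation burden and potentially hitting actionable loci.

`oncopanelQC` implements a complete analysis pipeline for study designs that
measure this damage with a well-characterized diploid cell line: sections cut
at several depths from FFPE blocks fixed for different lengths of time are
sequenced on one or more panels, every call is compared against a consensus
known-variant set, and the excess calls are classified, rated, and compared
across sample groups.

## Pipeline overview

1. **Region algebra** (`region_set`, `parse_bed`, `build_ctr`). Panel target
   regions, low-complexity exclusions, and the consensus high-confidence
   targeted region (CTR — the intersection of exonic/benchmark/exome-panel
   regions minus low-complexity regions) are canonical interval sets with
   BED semantics (0-based, half-open). All rate denominators are base counts
   of these sets.
2. **VCF cleaning** (`read_sample_vcf`, `normalize_variants`,
   `clean_sample`). Calls become atomic, normalized records: multi-allelic
   lines split, indels left-aligned and trimmed (single anchor base kept),
   MNVs decomposed into per-base SNVs. Cleaning keeps calls inside the
   panel's assessable region (target minus low-complexity), at or above the
   panel's VAF threshold (inclusive), and off the panel blocklist. Variant
   identity everywhere is the normalized key `chrom:pos:ref:alt`.
3. **Known-variant set** (`build_known_set`). A variant is *known* when
   called in strictly more than 75% of the reference replicates (the
   default; "over 75%" is a strict inequality, so 12 replicates require
   support from at least 10). Entry VAF is the median across supporting
   samples — the median rather than the mean so that one aberrant replicate
   cannot move an entry between zygosity bins. Bins: HOM (VAF > 0.8),
   HET (0.2 < VAF ≤ 0.8), and two low bins split at 0.1.
4. **FP analysis** (`call_false_positives`, `cutoff_sweep`). Any cleaned
   call absent from the known set is an FP. The FP rate is
   `fp_count / region_bases × 1e6` — FPs per million assessable bases — and
   is computed per scope: whole panel, inside the CTR, or outside it. Each
   scope uses its own base count as denominator (inside = panel ∩ CTR,
   outside = the complement within the panel); this is a deliberate,
   configurable choice, since a per-scope rate should be normalized by the
   bases actually assessable in that scope. FPs are partitioned into INDEL,
   G:C>A:T (deamination), G:C>T:A (oxidation), OTHER. Sensitivity is the
   fraction of in-scope known variants recovered by the sample; it is
   defined per sample and aggregated by averaging.
5. **Sample QC** (`categorize_positions`, `vaf_tail_statistic`,
   `flag_contamination`, `qc_classify`). Five checks: cell count, DNA
   yield, library yield, depth/complexity, and the VAF histogram. Sections
   are categorized from their cell-count profile (below), and every sample
   lands in exactly one analysis group: `PASS_INNER`, `FAIL_INNER`,
   `SURFACE`, or `EXCLUDED`. Exclusion is reserved for failures unrelated
   to FFPE processing itself — an explicit experiment failure or detected
   contamination; mere QC-threshold failures define `FAIL_INNER`.
6. **Group statistics** (`welch_t`, `yates_chi2`, `compare_groups`).
   Welch's unequal-variance t-test for group mean comparisons (one-tailed
   where the hypothesis is directional — FFPE damage can only increase FP
   counts), and Pearson's chi-squared with Yates' continuity correction for
   2×2 pass/fail tables. Raw p-values are reported; a Bonferroni column is
   appended for transparency only.

## Surface/inner categorization

Cell blocks show an "edge effect": sections from the top and bottom of the
block have depressed cellularity and harsher fixation exposure. The
categorizer encodes that rule set:

* `SURFACE_1`: consecutive end sections with cell count below 50% of the
  block mean;
* `SURFACE_2`: the next three sections at each end, extended by up to two
  more when their counts are closer (absolute difference) to the mean
  `SURFACE_1` count than to the mean of the remaining (provisional inner)
  sections;
* `INNER`: the rest.

Two conventions the rule text leaves open are fixed here: the extension
comparison uses the mean of that end's `SURFACE_1` counts (no extension can
fire at an end without a `SURFACE_1` section), and the provisional inner
mean is computed over the currently unlabeled sections excluding the
candidate. The procedure is symmetric in the position order, which the test
suite asserts by reversal.

## Contamination detection

Homozygous germline variants of a pure diploid sample sit at VAF 1.0.
Admixture of a second genome at fraction $f$ displaces the homozygous sites
the contaminant does not share down to VAF $1-f$ — a leftward tail from
100%. The detector is two-stage:

1. **Detect:** the tail statistic $T$ = 95th percentile of $1-\mathrm{VAF}$
   over calls with VAF > 0.7 (the homozygous cluster). A sample is suspect
   when $T$ exceeds `tail_multiplier` (default 3) times the cohort median —
   a scale-free rendering of "the tail is several times wider than normal".
   $T$ needs at least 10 cluster calls, otherwise it is `NA` with a
   warning. Quantiles, not histogram bins, drive the detector; the 0.01-bin
   VAF histogram is for diagnostics and plotting only.
2. **Confirm:** more than `overlap_min` (default 0.5) of the sample's FP
   calls must be present in a germline variant database (dbSNP/ExAC-style):
   a contaminating genome is made of common germline polymorphisms, true
   FFPE artifacts are not. A wide tail without database support — pure
   noise — is not flagged, and neither is database overlap without a tail.

Under the generator's mixing rule the closed-form expectation of the
statistic is $T \approx f + z_{1-0.05/h}\,\sigma$ where $h$ is the fraction
of homozygous sites the contaminant misses and $\sigma$ the VAF noise sd
(`expected_tail_statistic`; valid for $h > 0.05$, since then the displaced
component carries the 95th percentile). The fixed-seed suite checks zero
false flags at $f=0$ and full detection at $f \geq 0.10$.

## The synthetic cohort generator

`simulate_cohort` emulates the full study design and is the package's
ground-truth machine: every emitted call is tagged `truth`, `artifact`,
`contaminant`, or `noise`, so recovery tests can demand *exact* agreement
between the pipeline's FP set and the planted non-truth calls.

Default parameters, and why:

| parameter | default | rationale |
|---|---|---|
| panel size | 1.7 Mb | a typical mid-size hybrid-capture oncopanel |
| truth variants | 350 het + 150 hom | a few hundred germline calls per panel, as consensus sets of mid-size panels show |
| VAF noise sd | 0.015 | deep (≥1000×) targeted sequencing; binomial spread at VAF 0.5, depth ~2000, is ≈0.011 |
| VAF threshold | 1% | the lowest of the common panel recommendations (1–2.6%) |
| deamination rate (inner) | 2 /Mb | QC-passed inner sections show few but nonzero G:C>A:T calls |
| surface multiplier | 5 | surface sections show several-fold more deamination |
| fixation effect | 0 /h | the null the study design should *not* reject; a config hook adds an effect for power analyses |
| artifact VAF | Beta, mean 0.02, sd 0.002 | low-VAF damage above the 1% threshold, almost entirely below 2.5% and entirely below 5%, so the cutoff-sweep behavior (artifacts vanish at 2.5–5%) is reproducible by construction |
| sporadic noise | 0.5 /Mb, OTHER-type | background caller noise, distinct from damage signatures |
| sections/block | 12; surface-1 ×1, surface-2 ×3 per end | enough depth resolution for the categorizer's rule set |
| cell counts | inner 25k (cv 10%), ×0.2 / ×0.5 at surface | inner sections above 20k, first surface category below 10k |
| blocks | 2 per fixation time (1, 2, 6, 24 h), 3 sections drawn evenly per block per panel | 4 panels × 24 sections = 96 sequenced sections |
| contaminant mismatch h | 0.5 | two unrelated individuals share roughly half their common hom sites |
| germline DB inclusion | 0.9 | high but incomplete database coverage |

Artifacts are placed uniformly on C/G reference positions (the deamination
substrate) with the allele forced to C>T or G>A by the strand of the
reference base; noise calls are placed on A/T positions, so they always
classify as OTHER. A synthetic reference FASTA is emitted with each cohort,
making left-alignment and context placement self-contained — no external
genome is needed.

**What the generator does not emulate:** read-level error (no FASTQ/BAM),
caller-specific biases, mapping artifacts in repetitive regions, indel
errors (FP indels enter tests through hand-built fixtures, not the
generator), fixation-time chemistry beyond a rate multiplier, and VAF
overdispersion beyond Gaussian noise. Passing recovery tests therefore
demonstrates that the *analysis* is correct and well-calibrated on data
with the assumed structure — not that any particular real panel has these
rates.

## Numerical choices and degenerate inputs

* **Interval semantics.** BED is 0-based half-open; VCF positions are
  1-based; the conversion happens in exactly one place
  (`region_contains`). Book-ended intervals merge (base-set semantics);
  strand is ignored; chromosome names are compared as exact strings with
  an opt-in `chr`-prefix normalization — never silent remapping between
  genome builds.
* **Normalization.** Left-alignment keeps the standard single anchor base
  for indels; an indel pushed to position 1 falls back to a right anchor.
  The operation is idempotent and haplotype-preserving (asserted against
  an exhaustive-shift oracle).
* **Thresholds are inclusive.** `vaf >= threshold`, matching "down to a
  VAF of x%" phrasing; the known-set fraction is strict (`support > f·n`).
* **Duplicate keys** within one sample collapse to the highest-VAF record.
* **Degenerate statistics.** Welch's test on two constant groups returns
  p = 1 (equal means) or p = 0 with an infinite statistic (different
  means), each with a warning, instead of erroring mid-pipeline; the Yates
  correction floors $|O-E|-0.5$ at zero so proportional tables give
  exactly zero; zero-margin tables are an error.
* **Empty scopes.** A scope with zero assessable bases is an error (the
  rate is undefined); an empty known set inside a scope yields sensitivity
  `NA`, not a division error.

## Problem sizes in the shipped checks

The test-suite and acceptance-script runs use scaled problem sizes chosen
as a compromise between statistical resolution and turnaround: oracle
cross-checks on 0.5–1 kb toy genomes (200 region cases, 100 cohorts, 100
statistic draws); conservation on a 0.2 Mb panel cohort; rate recovery at
the full default 1.7 Mb with 30 samples per group; the surface-vs-inner
power sweep on 100 cohorts of a 0.4 Mb panel with 10 samples per group
(design power ≈ 99% at the default effect size); the fixation-time null
calibration on 1000 replicates of a 1 Mb panel with 12 samples per group
(Poisson mean ≈ 2.5 FP per sample, where the t-test is well calibrated);
and the contamination suite on 20 samples of a 0.2 Mb panel.

## Known limitations

* The recurrent-indel filter needs the cohort context; it cannot flag a
  platform artifact from a single sample, and its `min_samples = 3` default
  trades singleton protection against artifact capture.
* Sensitivity is measured against the consensus known set, which for a
  panel lacking fresh reference replicates may itself be built from
  high-quality FFPE samples; damage shared by most reference samples would
  then be invisible. The reference roster is therefore an explicit caller
  input, never chosen automatically.
* The contamination detector estimates no contamination *fraction* and
  does not identify the contaminant; it is a QC flag.
* p-values are reported raw, as group comparisons in this design are few
  and pre-planned; the Bonferroni column is informational.
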