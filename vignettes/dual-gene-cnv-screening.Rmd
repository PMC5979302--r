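---
title: "Dual-gene amplicon CNV screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-gene amplicon CNV screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliCNV)
```

## The problem

Targeted amplicon panels for hereditary breast and ovarian cancer
genotype the full coding regions of two genes — canonically *BRCA1*
and *BRCA2* — in a handful of multiplex PCR reactions ("plexes").
Such panels detect small variants well, but large genomic
rearrangements (whole-exon or whole-gene deletions and duplications)
only show up as *dosage* changes: an amplicon over a deleted exon
amplifies from one template copy instead of two, halving its peak
height on the capillary electropherogram and its read count after
sequencing.

Because an amplicon assay carries no external copy-number control,
dosage must be judged *relative to something inside the same sample*.
The natural anchor in a dual-gene panel is the other gene.  That
anchoring works — and it has a blind spot that this package makes
explicit, testable, and recoverable.

## The screening pipeline

`ampliCNV` implements the three evidence streams of a diagnostic
screening workflow and an integration layer:

1. **Fragment analysis (FA)** — electropherogram traces of the
   amplified plexes are calibrated from scanner units to base pairs
   against the co-electrophoresed LIZ-600 size standard, peaks are
   assigned to panel amplicons, and peak heights are normalized
   cross-gene against a confirmed copy-number-normal ("true negative")
   reference profile.
2. **Read counts (RC)** — per-amplicon read counts from the sequencing
   run are converted to within-plex frequencies; every sample is
   gated against per-amplicon 99% confidence intervals estimated from
   the run, and a per-sample global gene-1/gene-2 count ratio is
   compared with the cohort.
3. **Dosage assays (MLPA/MAQ)** — orthogonal probe- or amplicon-based
   quantification against reference probes and control samples,
   summarized as dosage quotients (DQ) or relative peak ratios (RPR).
4. **Caller** — per-amplicon flags from (1) and (2) are combined
   through an explicit truth table into LOSS/NEUTRAL/GAIN/NO_CALL
   states, gene-level events are derived, and whole-gene patterns are
   reported as a two-hypothesis ambiguity that only evidence from (3)
   may resolve.

## Cross-gene normalization and its identifiability limit

Let $h_a$ be the peak height of amplicon $a$ in the test sample and
$r_a$ its height in the reference profile.  For an anchor gene $g$,
the scaling factor is

$$s_g = \operatorname{median}_{a \in g} \frac{r_a}{h_a},
\qquad \text{ratio}_a = s_g \cdot \frac{h_a}{r_a}.$$

Anchor-gene amplicons center on 1.0 by construction; a true
copy-number change in the *other* gene appears directly in its
ratios.  The median (rather than mean) anchor tolerates a minority of
CNV-affected amplicons inside the anchor gene itself, which is what
keeps partial events — say, a three-exon deletion — visible under
*both* anchor choices, as long as the event covers strictly less than
half of the anchor gene's amplicons in each plex.

The blind spot is algebraic.  If every gene-2 amplicon is halved, the
gene-1-anchored profile shows gene 2 at 0.5; the gene-2-anchored
profile shows gene 1 at 2.0.  Exactly the same pair of profiles is
produced by a whole-gene-1 duplication.  Intra-sample evidence cannot
distinguish the two, and neither can read counts, which are subject to
the same within-sample normalization:

```{r ambiguity}
panel <- default_panel()
tr <- gen_trace(panel, "A", cnv = cnv_whole_gene(panel, "BRCA2", 1L),
                seed = 1)
ref <- calibrate_trace(gen_trace(panel, "A", seed = 1), panel)$peakset
ps <- calibrate_trace(tr, panel)$peakset
prof <- normalize_by_reference_gene(ps, reference_profile(list(ref)),
                                    panel, "BRCA1")
round(range(prof$ratios[prof$genes == "BRCA2"]), 3)
```

The caller therefore *refuses* to emit a whole-gene final call from
panel-internal evidence: `detect_ambiguity()` reports
`WHOLE_GENE_AMBIGUITY` with both rival hypotheses, and the only
constructor of a resolved final call, `resolve_with_dosage()`,
requires a classified dosage result.  A dosage result that contradicts
both hypotheses leaves the case `UNRESOLVED` rather than falling back
to panel evidence.  This refusal is asserted by the test suite over
planted whole-gene deletions and duplications of either gene.

## Read-count statistics

The read-count "frequency" of an amplicon is its count divided by the
total count of its plex in the same sample, which removes sample- and
plex-level loading effects.  Across a run of $n$ samples the package
estimates, per amplicon, the mean $\mu_a$ and standard deviation
$\sigma_a$ of this frequency and gates samples against

$$\mathrm{CI99}_a = \mu_a \pm 2.576\,\sigma_a ,$$

a normal-approximation interval on the run's empirical spread.
Laboratories with long validation histories would use archived
run statistics; the run-empirical interval is the reproducible
analogue and collapses to the same construction.  A leave-one-out
baseline (excluding the queried sample) is the default when the
sample under scrutiny is part of the run.  The per-sample global
gene-1/gene-2 ratio is the unweighted mean over plexes of
$\sum_{a\in g_1} c_a / \sum_{a\in g_2} c_a$; an unweighted mean (not
pooled counts) keeps each multiplex reaction's stoichiometry equally
weighted, and a whole-gene event roughly doubles or halves it.

## Dosage quotients

MAQ dosage quotients and MLPA relative peak ratios share one
computation, the standard double normalization.  With reference
probes $R$:

$$v(s, p) = \frac{h_{s,p}}{\operatorname{median}_{r \in R} h_{s,r}},
\qquad
\mathrm{DQ}(p) = \frac{v(\mathrm{test}, p)}
                      {\operatorname{median}_{c} v(c, p)} .$$

Under the proportional model (peak height $\propto$ copy number) and
diploid controls, $\mathrm{DQ} = \mathrm{CN}/2$ exactly: 1.0 for two
copies, 0.5 for a heterozygous deletion, 1.5 for a three-copy
duplication, 0 for a homozygous dropout (an absent test peak is a
legitimate value, not an error).  Median aggregation is used at both
stages for robustness to a single aberrant reference probe or control;
a `mean` switch is provided for comparison with software that
averages, since commercial implementations do not disclose their
choice.  Classification uses the closed normal range 0.7–1.3, the
MLPA convention; the same range is reused as the default gate on
FA height ratios, which the source workflow left unstated.

## Tunable parameters

| parameter | default | where | why |
|---|---|---|---|
| ratio gate (low, high) | 0.7, 1.3 | FA flags, DQ classification | MLPA normal range; closed at the boundaries |
| CI multiplier `z` | 2.576 | `run_ci99()` | two-sided 99% normal quantile |
| cohort flag multiplier | 2 | `global_gene_ratio()` | mean ± 2 sd gate on the global ratio |
| match tolerance | 2.0 bp | `assign_amplicons()` | panel sizes are spaced ≥ 4 bp, so 2 bp is unambiguous |
| smoothing window | 5 scans | `detect_peaks()` | centered moving average; plateau ties break to the leftmost scan |
| calibration gate | r² ≥ 0.99 | `fit_size_standard()` | rejects mis-identified ladders |
| NO_CALL tolerance | 10% | `detect_ambiguity()` | lets isolated dropouts survive the whole-gene rule |

Peak-detection parameters and the FA match tolerance are engineering
choices (the source workflow does not state them) and are exposed in
every relevant function signature and in the CLI.

## The synthetic-data generators

`gen_trace()`, `gen_counts()` and `gen_dosage_run()` emulate the three
input kinds under arbitrary copy-number states so that every stage is
testable without access to patient data (none is deposited for this
assay class).  The model is deliberately minimal:

* peak height / read count / probe height $\propto$
  efficiency $\times$ CN/2, with per-amplicon amplification
  efficiencies drawn once per cohort (lognormal, sd
  `efficiency_spread`) and multiplicative lognormal observation noise
  (sd `sample_noise_sd`);
* traces place one Gaussian peak per amplicon on a known affine
  scan model plus a clean LIZ-600 ladder channel; the ground truth is
  attached for oracle tests;
* `calibrate_gene_ratio` rescales gene-1 efficiencies per plex so the
  noiseless diploid count ratio equals a requested value — 0.7 is used
  throughout, the cohort-normal center of this assay design, making a
  whole-gene-2 deletion surface as a global ratio of 1.4, twice the
  cohort's;
* every generator takes an explicit seed and embeds it in its output.

Default study conditions used by the tests and the acceptance script:
20% efficiency spread, 3–5% observation noise, read depth 20 000 per
amplicon (5 000 for the 50-sample coverage cohort), cohorts of 8–50
samples, 4 dosage controls MAQ-style and 6 MLPA-style, 20 replicate
runs for the noise-envelope check.  These sizes keep the full suite
fast while leaving the statistics meaningful.

What the generators do **not** model: stutter and heteroduplex
artifacts, dye pull-up, primer-dimer signal, GC-dependent efficiency
drift between runs, FFPE degradation, or read-level sequencing error.
Passing tests therefore demonstrate the *algorithmic* correctness of
calibration, normalization, gating and calling — not robustness to
every artifact of production data.

## Numerical and degenerate-input choices

* Interval span is `end - start`, the coordinate-difference convention
  of the diagnostic reports this tool mirrors (documented prominently
  in `genomic_span()`); BED export converts to 0-based half-open.
* Ladder identification takes the n tallest peaks in position order;
  the r² gate, not the pairing step, is the quality control.
* Peak heights are read from the raw signal at the detected position,
  since box smoothing attenuates amplitude.
* Greedy amplicon assignment resolves exact distance ties toward the
  smaller expected size, never assigns a peak twice, and warns when a
  panel's expected sizes sit closer than twice the tolerance.
* All range gates are closed intervals: a ratio of exactly 0.7 or
  1.3 is in range.
* Zero-height reference probes and zero plex totals are errors naming
  the offending sample/plex; an absent target peak in a dosage test
  sample yields DQ 0.

## Known limitations

* **Whole-gene events need orthogonal dosage data.**  By design, no
  input pattern produces a whole-gene final call from panel-internal
  evidence; laboratories must run MLPA/MAQ (or equivalent) for such
  cases.
* **Renormalization shift.**  In a sample carrying a deletion, the
  within-plex frequencies of *unaffected* amplicons rise by the lost
  mass fraction.  With the conservative default truth table, a
  copy-neutral amplicon whose frequency drifts above CI99 while its FA
  ratios stay in range becomes NO_CALL (review) rather than NEUTRAL.
  On simulated three-to-five-amplicon deletions at 5% noise this
  affects roughly 5% of amplicons; definite states remain error-free,
  and FA-driven calling alone recovers over 95% of planted states.
  The truth table is plain data and can be tuned by laboratories that
  prefer recall over review burden.
* **Events covering half a gene or more within a plex** shift the
  median anchor itself and degrade toward the whole-gene ambiguity;
  only events strictly below half per plex are guaranteed unambiguous.
* The bundled panel's amplicon sizes and intervals are synthetic
  placeholders (commercial layouts are proprietary); replace the YAML
  config with your kit's true table for production use.
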