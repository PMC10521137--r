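---
title: "Quantifying replication-fork progression, proximity-labelling enrichment and nuclear fluorescence with traelkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replication-fork progression, proximity-labelling enrichment and nuclear fluorescence with traelkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traelkit)
```

## Scope

`traelkit` implements three quantitative procedures that commonly appear
together in studies of the budding-yeast replication checkpoint:

1. **Fork-progression analysis from TrAEL-seq.** TrAEL-seq maps 3′ DNA ends
   genome-wide at base-pair resolution, preferentially labelling the leading
   strand at replication forks. After cells are released from a hydroxyurea
   (HU) arrest, the position of the TrAEL signal relative to each replication
   origin measures how far forks have travelled.
2. **Proximity-labelling enrichment (TurboID/BioID LFQ).** Label-free
   quantification intensities from three samples — no ligase + treatment,
   ligase without treatment, ligase + treatment — are normalized to an
   endogenously biotinylated control protein and projected onto two
   log-ratio axes to call treatment-enhanced, tag-specific hits.
3. **Corrected nuclear fluorescence.** Per-cell corrected total nuclear
   fluorescence (CTNF) and nuclear/cytoplasmic intensity ratios, with a
   two-group t test, for split-fluorophore (BiFC) style readouts.

Each stage has a seeded synthetic-data generator with full ground truth, so
every downstream computation has a recovery test.

## The fork-progression model

### From reads to break-end signal

Mapped reads are truncated to a single nucleotide: the 5′-most base of the
read, which is the base adjacent to the strand break that the assay labels
(`extract_read_ends()`). Interval arithmetic is zero-based and half-open
throughout, so a plus-strand read `[start, end)` contributes `start` and a
minus-strand read contributes `end - 1`.

Ends falling in non-single-copy regions (rDNA, the 2-micron plasmid, mtDNA,
sub-telomeres, transposable elements) are removed against a BED exclusion
mask with union semantics (`filter_and_deduplicate()`). The same function
offers *optional, explicit* positional de-duplication (multiplicity collapse
to 1) for inputs that were not de-duplicated upstream; it is never applied
silently.

The retained ends are summed in running windows (default 1 kb window, 100 bp
step — both configurable, since the appropriate resolution depends on
sequencing depth) and scaled to reads per million. The normalization
denominator is, by default, the total multiplicity retained after masking;
this makes the conservation property exact and testable (with tiling
windows the normalized track sums to exactly $10^6$) and keeps the track
independent of reads in discarded regions. A `"mapped"` policy normalizing
by an externally supplied total mapped-read count is available where
cross-library comparability on the original scale matters.

### Active origins

Candidate origins (ARS sites) are scored by the total signal in a 10-kb
window centred on each, computed on a designated *reference condition* so
that the same active set is used for every sample. The bottom 40% of scores
are removed; retained count $= \lceil 0.6\,n \rceil$, with boundary ties
broken toward the earlier coordinate so the count is deterministic. Both
window and fraction are `fork_params()` fields. Note that the activity
window must suit the reference condition: for an HU-arrest sample forks sit
at or near origins and 10 kb is appropriate, while for a release timepoint
with forks ~12 kb out a wider window is needed (the package's end-to-end
tests use 30 kb for release-style reference data).

### Oriented probes, smoothing, peaks, distances

For each active origin two probes are built (`build_probes()`), one per
side, each spanning 20 kb and binned at 100 bp. The upstream probe's axis is
reversed so both probes read "distance from origin"; a read exactly at the
origin position contributes distance 0 to both sides, which keeps the two
probes exactly mirror-symmetric for symmetric input. Probes running past a
chromosome end are flagged `truncated` and excluded from distance
statistics.

Probe signal is smoothed by local polynomial (Loess) regression using the
15 nearest bins with tricube weights and a second-order polynomial
(`smooth_probe()`; `stats::loess` with span $=k/n$ and `surface =
"direct"`). Order-2 local fits reproduce constants and quadratics exactly,
and smoothing moves the argmax of a symmetric peak by at most one bin —
both are enforced by tests, since the fork distance is read off the
smoothed profile.

A *peak* is a local maximum of the smoothed profile with topographic
prominence at least half the profile maximum and at least 2 kb from any
higher peak (`detect_peaks()`). Neither the prominence fraction nor the
separation follows from first principles; they are declared defaults
(`fork_params()`), chosen so that a single fork population yields one peak
while a probe overlapping a neighbouring origin's fork yields two. A probe
with more than one peak is taken to contain a second origin and is dropped
(`retained = FALSE`). The *fork distance* of a retained probe is the
distance of the global maximum of the smoothed profile (`fork_distance()`);
ties report the smallest distance, and all-zero probes are undefined.

Origin-firing counts reuse the same peak criteria on the genome-wide
smoothed window signal, per chromosome, with prominence referenced to the
per-chromosome maximum: since each fired origin launches two divergent
forks, the fired-origin count is the genome-wide peak count divided by two
(`count_fired_origins()`; odd counts floor with a warning).

### Group statistics

The replicate-level statistic is the median fork distance over retained
probes (`condition_summary()`). Replicate medians are compared by ordinary
one-way ANOVA with all-pairs corrected comparisons — $g(g-1)/2$ pairs for
$g$ groups, e.g. 15 pairs for 6 groups (`compare_conditions()`). Tukey's
HSD is the default correction, the common choice for all-pairs comparisons
after a one-way ANOVA; Šídák and Bonferroni adjustments of pooled-variance
t statistics are selectable. Groups with a single usable replicate are
excluded with a warning.

## The LFQ enrichment model

Intensities enter in long format (protein × sample class × replicate).
Missing rows are completed as zeros, and every zero is converted to 1
*before* normalization — the conversion must precede the ratio so both
numerator and denominator are defined; this single imputation rule is the
reason absent proteins line up on a diagonal in enrichment scatter plots.
Each intensity is divided by the control protein's intensity in the same
sample and replicate (in yeast, the endogenously biotinylated acetyl-CoA
carboxylase Acc1), cancelling per-run scale: multiplying any replicate's
intensities by a constant changes no enrichment value, which is tested.

Per-protein sample averages are arithmetic means of normalized values over
replicates, and the two coordinates are

$$x = \log_2 \frac{\overline{s_3}}{\overline{s_2}}, \qquad
  y = \log_2 \frac{\overline{s_3}}{\overline{s_1}},$$

treatment enrichment within the tagged background ($x$) and tag enrichment
under treatment ($y$). The log base is configurable (hit calls are invariant
given matching thresholds); base 2 is the default because fold-change
thresholds are conventionally stated in doublings. A *hit* exceeds both
thresholds (defaults $x > 1$, $y > 1$, i.e. two-fold; always echoed in
output provenance, since the choice is a reporting convention, not a
statistic). The control protein normalizes to 1 everywhere, so it sits at
exactly $(0, 0)$ and is never a hit for positive thresholds.

**Limitation.** With zero→1 imputation, a protein that drops out of the
treated-tag sample entirely is unrecoverable, and heavy missingness in the
control samples manufactures diagonal artefacts. The generator's default
tables are complete (dropout probability 0), matching the intended use of
the procedure; tests assert perfect recovery of the planted
treatment-enhanced class in that regime and, under 10% dropout, recovery of
every enhanced protein that was actually measured in the treated-tag
sample.

## The fluorescence model

For each circled cell,
$$\mathrm{CTNF} = \mathrm{IntDen} - A \times \bar{B},$$
integrated density minus cell area times mean background fluorescence.
Negative values — background brighter than the cell — are retained and
flagged rather than clipped, so that population averages are unbiased. The
nuclear/cytoplasmic ratio uses mean intensities, making it invariant to
uniform illumination scaling; cells with zero cytoplasmic signal are
excluded with a warning. Groups are compared with a two-sided Welch t test
by default (no equal-variance assumption is warranted between strains);
Student's pooled test is selectable.

## What the generators emulate — and what they do not

`simulate_trael_experiment()` places, for every fired origin, two forks at
independent truncated-Normal distances (truncation at zero is the only
constraint the physics imposes; no distributional form is standard), emits
a fixed number of reads per fork with Gaussian positional noise, assigns
strands by the leading-strand preference (default fraction 0.8, reflecting
strong but imperfect leading-strand labelling), and adds uniform background
plus exact-copy duplicates. The desk-scale default is 2 × 500 kb
chromosomes with 10 origins at least 60 kb apart. The generator does *not*
emulate replication-timing gradients, fork stalling heterogeneity,
mappability, or sequencing error — so passing recovery tests demonstrate
correctness of the measurement pipeline, not robustness to every artefact
of real libraries. Read depth defaults (150 reads per fork) were chosen for
statistical power at desk scale, not to match any particular sequencing
run.

`simulate_lfq_table()` draws log-normal protein baselines (sdlog 1 around a
median of $10^6$, spanning the dynamic range typical of LFQ), multiplies
tag-specific proteins 8-fold in both ligase samples and treatment-enhanced
proteins 8-fold in the treated-ligase sample only, and applies multiplicative
replicate noise (sdlog 0.2, ~20% CV; the control protein uses 5% CV,
reflecting a highly abundant, precisely quantified housekeeping enzyme).
Intensity-dependent missingness — the dominant real-world pathology of LFQ —
is modelled only as uniform dropout, and peptide-level effects are not
modelled at all.

`simulate_cell_fluorescence()` draws per-cell area, background, cytoplasmic
intensity and a Normal nuclear/cytoplasmic ratio, and constructs integrated
density as `area * (nuclear + background)` so the CTNF identity is exact by
construction. Segmentation error and spatial intensity gradients are out of
scope; the package consumes measurement tables, not images.

## Numerical choices and degenerate inputs

* Loess: k-nearest-neighbour tricube weighting, direct (exact) surface,
  no statistical extrapolation — probes are evaluated only at their own bin
  midpoints. All-zero vectors short-circuit to zero without fitting.
* Peak ties and plateaus: plateaus report their middle bin; ties at the
  smoothed maximum report the smallest distance with a message.
* Activity-score ties: broken by coordinate order; an all-equal score set
  triggers a warning and coordinate-order retention.
* Zero denominators: an empty read set yields all-zero normalized tracks
  with a warning rather than NaNs; a zero control intensity is an error
  (impute first).
* Determinism: a single integer seed fixes every generator; pipeline runs
  are byte-reproducible given identical config and inputs, and the resolved
  configuration (no silent defaults) plus its MD5 are written to
  `provenance.yaml`.

## Problem sizes used in the test-suite

Recovery tests run at desk scale: 20-30 origins across 2-3 small
chromosomes, 100-150 reads per fork, 10-20 seeds per property; LFQ tables
of 40-300 proteins with 3 replicates per sample; 150 cells per group for
fluorescence. Null calibration of the group statistics uses 200 simulated
six-group designs against the 99% binomial band at $\alpha = 0.05$. These
sizes give the properties enough Monte-Carlo resolution while keeping the
whole suite inside a coffee break.

## Known limitations

* The probe reading — two oriented 20-kb half-probes per origin, each
  expected to hold one fork peak — is one of two defensible conventions;
  the alternative (a single folded 40-kb probe) is not implemented.
* Peak criteria (prominence fraction, minimum separation) are declared
  defaults, not inferred from any reference implementation.
* Whether strands should be windowed separately before probe construction
  is exposed (`strand_mode = "leading"`) but total-signal mode is the
  default.
* The ANOVA operates on replicate medians, deliberately discarding
  per-probe variance; with two replicates per condition its power is
  limited, matching the design it models.
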