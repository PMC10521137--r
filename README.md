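# traelkit

Quantitative analysis of DNA replication-fork progression from TrAEL-seq
read ends, proximity-labelling (TurboID/BioID) LFQ enrichment, and
corrected nuclear-fluorescence measurements — with seeded synthetic-data
generators carrying full ground truth for every stage.

## Who this is for

Researchers analysing replication dynamics in budding yeast (or any genome
with a defined origin catalogue) who have:

* **TrAEL-seq reads** — 3′ DNA-end sequencing that marks fork positions at
  base-pair resolution — and want per-origin fork distances, origin-firing
  counts, and between-strain statistics;
* **LFQ intensity tables** from a three-sample proximity-labelling design
  (no ligase + treatment / ligase alone / ligase + treatment) and want
  control-normalized, dual-axis enrichment scores with hit calls;
* **per-cell fluorescence tables** (integrated density, area, background,
  nuclear/cytoplasmic means) and want corrected total nuclear fluorescence
  and ratio comparisons.

## The methods in brief

**Fork progression.** Reads are truncated to the single nucleotide adjacent
to the strand break (the 5′-most base), filtered against a non-single-copy
exclusion mask, summed in running windows and scaled to reads per million.
Candidate origins are scored in a 10-kb centred window on a reference
condition and the bottom 40% removed. Each active origin gets two oriented
20-kb probes (upstream axis reversed, so both read "distance from origin"),
smoothed by Loess (15 nearest bins, order-2 polynomial, tricube weights).
Probes with more than one prominent peak contain a second origin and are
dropped; the fork distance of a retained probe is the distance of the
smoothed maximum,

```
d_fork = argmax_d  smooth(signal)(d),   d ∈ [0, 20 kb].
```

Replicate medians of `d_fork` are compared by one-way ANOVA with Tukey-HSD
all-pairs corrections (g(g−1)/2 comparisons for g groups). Because every
fired origin launches two divergent forks, the genome-wide peak count
equals twice the number of fired origins; `count_fired_origins()` halves
it.

**LFQ enrichment.** Zeros → 1, then every intensity is divided by the
endogenously biotinylated control (Acc1) in the same run. With per-sample
means of the normalized values,

```
x = log2( avg_sample3 / avg_sample2 )   # treatment effect, tagged cells
y = log2( avg_sample3 / avg_sample1 )   # tag effect, treated cells
```

and a hit is `x > 1 & y > 1` (thresholds configurable, always reported).
The control sits at exactly (0, 0).

**Fluorescence.** `CTNF = IntDen − Area × mean(background)`; the
nuclear/cytoplasmic ratio uses mean intensities and groups are compared
with a two-sided Welch t test.

## Worked example

```r
library(traelkit)

layout  <- default_trael_layout()    # 2 x 500 kb chromosomes
origins <- default_trael_origins()   # 10 origins, >= 60 kb apart

sim <- simulate_trael_experiment(layout,
  fork_sim_params(origins, firing_prob = 1, distance_mean = 12000,
                  distance_sd = 1000, noise_sd = 300, seed = 7))
sim$truth$counts
#> $fork_reads       [1] 3000
#> $background_reads [1] 60
#> $duplicate_reads  [1] 57
#> $total_reads      [1] 3117

probes <- process_probes(build_probes(sim$ends, origins, layout = layout))
head(probe_table(probes), 4)
#>   origin_id chrom       side truncated n_peaks retained fork_distance
#> 1    ori001  chrI   upstream     FALSE       1     TRUE         10950
#> 2    ori001  chrI downstream     FALSE       1     TRUE         12450
#> 3    ori002  chrI   upstream     FALSE       1     TRUE         12750
#> 4    ori002  chrI downstream     FALSE       1     TRUE         11150

median(probe_table(probes)$fork_distance, na.rm = TRUE)
#> [1] 12600        # planted truth median: 12586.5 bp

count_fired_origins(sim$ends, layout)
#> [1] 10           # 20 genome-wide peaks / 2 forks per origin
#> attr(,"peak_count") [1] 20
```

Each probe recovers the planted ~12-kb fork distance to within a bin or two
of the per-origin truth; the genome-wide peak count (20) is exactly twice
the number of origins that fired (10), and the median recovered distance
matches the planted truth within 14 bp here.

The same pattern holds for the other two assays: `lfq_enrichment()` on a
`simulate_lfq_table()` draw flags exactly the planted treatment-enhanced
proteins, and `nc_ratio_and_compare()` on `simulate_cell_fluorescence()`
with a 5-SD effect at n = 150/group reports p < 1e-4.

End-to-end runs with file inputs, YAML configs and provenance tracking go
through `run_trael_pipeline()`, `run_lfq_pipeline()` and
`run_fluor_pipeline()`; a thin command-line wrapper with subcommands
(`simulate-trael`, `trael`, `simulate-lfq`, `lfq`, `simulate-fluor`,
`fluor`) is at `inst/scripts/traelkit-cli.R`.

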