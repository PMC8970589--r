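# tfrepair

Single-nucleotide DNA damage mapping and base excision repair (BER)
analysis at transcription factor (TF) binding sites.

Sequence-specific DNA-binding proteins sit on the same DNA that damaging
agents attack and repair enzymes must reach. Lesion-tagged sequencing
assays (NMP-seq for methylation damage, CPD-seq for UV damage) localize
individual lesions at single-nucleotide resolution: each sequencing read
is ligated at the lesion cleavage site, so the damaged base is the
nucleotide immediately upstream of the read's 5′ end, on the opposing
strand. `tfrepair` turns aligned read 5′ ends into strand-specific lesion
tracks and asks two quantitative questions around TF footprints:

* **Damage formation** — is the lesion yield at bound motifs different
  from protein-free DNA? Cellular lesion counts are normalized to a
  naked-DNA control damaged in vitro, which factors out the strong
  sequence dependence of adduct chemistry:
  `ratio(i) = (cell_i / N_cell) / (naked_i / N_naked)`, rescaled so the
  profile mean over the plotted span is 1.
* **Repair kinetics** — is repair slower under the bound protein? Counts
  at a repair time point are divided by the initial (0 hr) damage to give
  the *fraction of remaining damage* `f(i, t) = n_i(t) / n_i(0)`
  (optionally corrected by a spike-in read ratio); high values mean slow
  repair. Under first-order repair `E[f] = exp(-k_i t)`.

Signals are aggregated around oriented motif midpoints or transcription
start sites (pooling counts across features per motif-relative offset,
then taking the ratio), averaged in 5 bp non-overlapping windows, and can
be stratified by binding-site occupancy, overlaid with nucleosome
density, laid out as TSS-aligned gene heatmaps, tested per window
(Welch t + Benjamini–Hochberg), and summarized by an inhibition-footprint
width estimator.

Because the interesting claims are about recovering small multiplicative
effects from sparse counts, the package ships a synthetic-data generator
(`sim_config()`, `simulate_lesion_field()`, …) that plants known
base-dependent lesion rates, footprint suppression, hotspots, and
position-dependent repair rates, and emits reads by the exact inverse of
the lesion-inference rule — so every pipeline stage is testable against
planted ground truth.

## Worked example

A complete synthetic experiment — 30 planted TTACCC sites (half bound,
half weakly bound), an MMS-like lesion field with 0.3× formation
suppression at bound motifs, a naked-DNA control, and 2 hr of
first-order repair slowed 10-fold under bound sites:

```r
library(tfrepair)

cfg <- sim_config(genome_length = 1e5, n_sites = 30, depth = 3e5,
                  timepoints = c(0, 2), seed = 7)
res <- run_demo(file.path(tempdir(), "demo"), cfg)

glance(res$profiles$formation_high)
#>   type      window flank_bp n_features core_mean flank_mean core_to_flank
#> 1 formation      5      500         15     0.539       1.01         0.535

glance(res$profiles$remaining_high)
#>   type      window flank_bp n_features core_mean flank_mean core_to_flank
#> 1 remaining      5      500         15     0.877      0.441          1.99

glance(res$profiles$remaining_low)
#>   type      window flank_bp n_features core_mean flank_mean core_to_flank
#> 1 remaining      5      500         15     0.350      0.423         0.828
```

Read: at the 15 bound sites, damage formation in the central ±10 bp is
about half the flanking level (the `core_mean` 0.54 mixes the fully
suppressed motif windows, ≈0.3, with unsuppressed edge windows), and
after 2 hr the core still retains 88% of its damage while the flanks are
down to 44% (background `exp(-1) ≈ 0.37` plus slow-repairing nucleosome
dyads) — a repair-inhibition peak. The 15 weakly bound sites show
neither effect (`core_to_flank ≈ 1` in both directions). The footprint
width of the bound-site repair peak:

```r
inhibition_width(res$profiles$remaining_high,
                 baseline_span = c(200, 500), threshold_frac = 0.2)
#> Inhibition footprint: [-18, 17] width 35 bp
#>   baseline 0.456, threshold 0.5472
```

close to the planted motif ± 15 bp inhibition window. `run_demo()` also
writes every stage as plain interchange files (FASTA genome, BED6+1
sites, BED6 reads, strand-split bedGraph lesion tracks, TSV profiles)
plus a JSON run manifest with md5 checksums and conservation counters,
so any single stage can be re-run on real aligned data in the same
formats; `autoplot()` on any profile draws the standard metaplot, with
`with_overlay()` adding the gray nucleosome background.

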