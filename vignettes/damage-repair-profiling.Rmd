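---
title: "Profiling DNA damage formation and excision repair at protein footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling DNA damage formation and excision repair at protein footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfrepair)
library(dplyr)
```

## The measurement model

Lesion-tagged sequencing libraries convert each DNA base lesion into a
sequencing read whose 5′ end is ligated at the repair-enzyme cleavage
site. The damaged base is therefore the nucleotide **immediately
upstream of the read's 5′ end, on the opposing strand**. With 0-based
coordinates (used internally and in all BED/bedGraph I/O; the package
converts to the 1-based convention only at the GRanges boundary), the
rule is:

* a `+` strand read with 5′ end at `x` implies a lesion at `x − 1` on
  the `−` strand;
* a `−` strand read with 5′ end at `y` implies a lesion at `y + 1` on
  the `+` strand.

"Immediately upstream" is read in the *read's own orientation* (one
base further 5′ along its strand). The assay does not fix this
convention unambiguously, so the package pins it operationally: the
simulator's `emit_reads()` is the exact inverse of `infer_lesions()`,
and the round-trip identity is enforced by tests on every simulated
field. Reads whose upstream base falls outside the chromosome are
dropped and counted, so `total lesions = reads kept + edge drops`
exactly. In dinucleotide (`cpd`) mode the two upstream bases form the
lesion, keyed by its 5′-most base on the lesion strand — one lesion,
one coordinate.

Lesion base identity is taken from the lesion strand, giving the usual
read classes: G reads (putative 7-methylguanine), A reads (putative
3-methyladenine), and so on. Duplicate reads are retained: lesion counts
*are* the signal, and deduplication would censor true recurrent damage.

## Normalization

**Formation.** Adduct yield depends strongly on local sequence, so
cellular lesion counts are normalized to a naked-DNA control damaged in
vitro. Both libraries are depth-scaled by their total lesion-class reads
within the analysis region, the per-position ratio is taken, and the
profile is rescaled so its mean over the plotted span (feature midpoint
± 500 bp pooled over features, by default) equals 1 — making "1.0"
read as "no protein effect". No pseudocount is added; instead positions
whose naked count falls below `min_naked` (default 1) are masked. This
controls ratio bias without inventing smoothing, and masking is
monotone: raising the floor never unmasks a position.

**Repair.** The fraction of remaining damage is the count ratio between
a repair time point and 0 hr. Values above 1 can only arise from noise
and are *flagged, never clipped* — clipping would hide normalization
failures. Three depth-handling modes exist:

* `scale = "none"` (default): the raw ratio. This is the correct scale
  whenever the two tracks are already commensurate — survivors of the
  same initial lesion field (as in the simulator), or libraries already
  spike-corrected upstream. On this scale the genome-wide mean equals
  the mean survival `exp(-k t)` under first-order repair, which is what
  the recovery tests assert.
* `spike = s0/st`: the spike-in correction — a damaged plasmid added at
  library preparation; multiplying by the 0 hr / t hr spike read ratio
  removes library-depth differences. This is the preferred correction
  for real libraries when spike counts exist.
* `scale = "total"`: per-library totals within the analysis universe,
  for independently sequenced libraries without a spike-in. By
  construction this forces the regional mean toward 1, so it
  re-expresses repair *relative to the regional average* rather than on
  the absolute survival scale; it is offered as an option, not the
  default, precisely because the two readings answer different
  questions.

**Windows.** Profiles are averaged in non-overlapping windows (default
5 bp) tiled outward from the feature-relative origin — the window
containing offsets 0…4, then 5…9, mirrored on the negative side — so
the origin always sits on a window boundary and the tiling is
deterministic. Window values average only unmasked member positions.

## Aggregation around features

Metaprofiles orient every position by its feature (motif midpoint or
TSS): offsets are read 5′→3′ along the motif/gene strand, so `−` strand
features are sign-flipped and profiles from both strands align. The
default aggregation **pools counts across features per offset and then
takes the ratio** (`damage_metaprofile()`, `repair_metaprofile()`).
At single-nucleotide resolution most individual sites have 0–3 counts
per position; a mean of per-site ratios would be dominated by
small-denominator noise, while the pooled ratio is the
minimum-variance estimate under the Poisson model. The mean-of-ratios
route is still available (`method = "mean_of_ratios"`, built on
`damage_ratio()` / `remaining_fraction()` + `site_metaprofile()`)
because the two differ in principle when per-site coverage is very
uneven.

Motif columns restricted to A/T on both strands cannot carry a G-class
lesion; `nonlesion_offsets()` identifies them and pooled naked counts
of zero mask them automatically in single-nucleotide plots.

Occupancy stratification splits sites at a configurable threshold
(default 10), with the boundary value classed *low* — the operational
definition of the source binding data. Target genes are linked to sites
whose midpoint lies within 300 bp of the TSS; a site flanked by two
divergently transcribed genes (nearest left TSS on a leftward gene,
nearest right TSS on a rightward gene, both in range) links both, two
exactly equidistant nearest TSSs are both linked (the symmetric
tie-break), and each gene is kept once at its closest site. Heatmap
rows are ordered by |site−TSS distance|, longest first, so the bound
site sweeps a visible diagonal band.

## Footprint width

The width estimator is deliberately simple and descriptive, because
repair-inhibition widths are conventionally reported without a formal
estimator: baseline = mean over a distal flank span (default
|offset| ∈ [200, 500]); the footprint is the longest contiguous run of
offsets containing the origin whose values exceed baseline × (1 +
`threshold_frac`) (or fall below baseline × (1 − `threshold_frac`) for
formation dips); width = right − left in bp. The default 20% excursion
is configurable and the estimator is exact on noiseless rectangular
profiles (a bump widened by 10 bp per side reports a width 20 bp
larger, the contrast used to compare repair pathways). Its outputs on
noisy profiles depend on the threshold choice and are not claimed to
equal any published width.

Per-window significance uses a Welch two-sample t-test on feature-level
window values with Benjamini–Hochberg correction across windows. Only
the t-test is conventional here; the FDR correction is this package's
choice, made because 5 bp windows over ±500 bp mean ~200 simultaneous
tests. Windows where both groups are constant and equal are reported
with statistic 0 and p = 1 rather than NaN.

## What the simulator emulates

`simulate_lesion_field()` draws per-position, per-strand lesion counts
as independent Poissons — the natural model for sequencing counts, and
the choice that makes every recovery test analytic (3-SD bands computed
from pooled counts). The generative assumptions:

* **Base-dependent rates.** Default relative rates
  G:A:C:T = 20:4:1:0.5 — ordered to reproduce the canonical read-class
  ordering of methylation damage (G ≫ A ≫ C ≈ T); the absolute scale is
  set by the library depth (rates are normalized so one library's
  expected total equals `depth`).
* **Footprint suppression.** At *occupied* sites only, a site-relative
  multiplier map (default 0.3 across the motif core) scales the rate;
  hotspot maps (≥ 1) model position-specific elevated damage.
  Occupancy acts as a binary bound/unbound flag at a configurable
  threshold — mirroring the high/low dichotomy used in the analysis
  rather than a continuous binding model, since no quantitative
  occupancy-to-protection relationship is established.
* **First-order repair.** Each lesion survives to time t with
  probability `exp(-k_i t)`; `k_i` is background (default 0.5/hr)
  × an inhibition multiplier inside occupied sites ± flank (default
  0.1 across motif ± 15 bp) × a dyad multiplier near nucleosome
  centers (default 0.5 within 30 bp of a dyad). Nucleosomes sit on a
  regular lattice (default 165 bp) excluded from a ±150 bp
  depleted window around each site — enough to reproduce the
  fast-in-NDR / slow-at-dyad pattern without an MNase model.
* **Read emission.** One read per lesion event, placed by the inverse
  of the inference rule; lesions whose read would leave the chromosome
  are dropped and counted, keeping the round trip exact on the
  retained set.

What it does **not** emulate: sequence-context damage chemistry beyond
per-base rates, fragment-length/adaptor artifacts, mappability, copy
number, or diploidy. Passing recovery tests therefore demonstrates that
the *analysis* is unbiased and correctly calibrated under the count
model — not that real libraries are free of those artifacts.

Genomes are uniform-random at a configurable GC content (default 0.38,
yeast-like); motif instances are sampled uniformly from the IUPAC
expansion and planted non-overlapping (slot-with-jitter placement,
guaranteeing the minimum gap by construction). All stages are
deterministic given the seed.

## Numerical and design details

* Coordinates 0-based half-open internally and in files; display/GRanges
  conversion in one place.
* Midpoint of an even-length motif = left-of-center base, giving a
  deterministic single-base origin.
* Motif search slop around a reported site interval defaults to 0
  (exact interval): the upstream binding data already localizes motifs.
* Replicate agreement is Pearson correlation over binned,
  depth-normalized counts on jointly nonzero bins; it approaches 1 only
  in the high-coverage regime where between-bin rate variance dominates
  counting noise (~tens of reads per bp at 50 bp bins on random
  genomes).
* Test problem sizes: parameter-recovery runs use 300 bound + 300
  unbound sites at 10^6 expected reads on 0.8–1 Mb genomes — large
  enough that 3-SD Poisson bands around the planted 0.3× suppression
  and exp(−1)/exp(−0.1) survival fractions are a few percent wide;
  exactness properties (round trips, oracle equivalence) run on 100 bp
  – 100 kb instances.

## Limitations

The pooled-ratio estimator weights sites by coverage; a handful of
hyper-covered sites could dominate a profile (inspect `n` columns).
The width estimator's contiguity requirement can fragment a footprint
interrupted by a masked window. TSS linkage assumes one TSS per gene
and takes any single-TSS annotation as given. The spike-in path assumes
the spike is subject to the same library losses as genomic DNA. And the
binary occupancy flag is a stand-in: nothing here estimates how
protection scales with fractional occupancy.
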