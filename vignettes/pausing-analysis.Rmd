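---
title: "Quantifying RNA polymerase I pausing from CRAC 3'-end profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA polymerase I pausing from CRAC 3'-end profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cracpause)
```

## The measurement and its kinetic reading

In CRAC (and NET-seq-like) experiments on an RNA polymerase subunit, the
3' end of each recovered nascent-transcript read marks the position of the
polymerase active site at the moment of crosslinking, at single-nucleotide
resolution. Counting 3' ends along a transcription unit therefore yields a
snapshot of where polymerases sit. Under three assumptions —

1. polymerases initiate at a constant flux and elongate independently
   (no queueing/exclusion),
2. the population is at steady state, and
3. crosslinking and library recovery are position-unbiased —

the expected density of active sites at position $i$ is proportional to the
mean time a polymerase dwells there. Writing $d_i$ for the per-position
dwell time (seconds), the expected fraction of read 3' ends at $i$ is

$$ f_i = \frac{d_i}{\sum_j d_j}. $$

Peaks in the 3'-end profile are positions of long dwell — pause sites —
and valleys are positions the polymerase clears quickly. This
proportionality is exactly what `expected_fractions()` computes from an
`elongation_model`, and it is the analytic oracle against which the whole
pipeline is tested.

## From reads to occupancy time

The analysis chain is:

1. **Count**: `count_three_prime_ends()` tallies the (weighted) read 3'
   ends per unit position, strand-aware (`to_unit_coordinates()` maps a
   plus-strand read to its rightmost aligned base and a minus-strand read
   to its leftmost; soft-clipped bases are not template-engaged and are
   ignored because alignments are taken at their reference span).
2. **Pseudocount**: `add_pseudocounts()` adds a constant $\alpha$ (default
   1) to every position so that fractions and log-ratios are defined where
   coverage is zero. The default of one pseudo-read per position is the
   conventional minimal choice; it is recorded in the profile metadata and
   freely configurable. At realistic depths (tens of reads per position)
   it perturbs fractions by about $L/N$, a percent-level, position-uniform
   shrinkage.
3. **Normalize**: `to_fractions()` divides by the total, making replicates
   and conditions comparable across library depths.
4. **Smooth**: `smooth_blackman()` convolves with a Blackman kernel
   $w(n) = 0.42 - 0.5\cos\frac{2\pi n}{M-1} + 0.08\cos\frac{4\pi n}{M-1}$,
   normalized to unit sum. Defaults are 31 nt for display/occupancy
   profiles and 51 nt for ratio inputs — the nearest odd sizes to the
   conventional 30/50 (a symmetric kernel needs odd support; an even
   request is adjusted with a message).
5. **Aggregate**: `aggregate_replicates()` takes the per-position median
   across biological replicates and a band between the second and third
   quartiles (linear-interpolation quantiles). For the common case of two
   replicates the median is their mean. Replicates are smoothed first,
   then aggregated.
6. **Convert**: `occupancy_time()` multiplies fractions by
   $T_{total} = L / v$, the total transcription time of the unit. With the
   defaults $L = 7800$ nt and $v = 40$ nt/s, $T_{total} = 195$ s and a
   uniform profile corresponds to 25 ms per nucleotide.

### A caveat on the occupancy-time convention

$t_i = f_i \, T_{total}$ is exact only when the true total dwell
$\sum_j d_j$ equals $L/v$. If $v$ is measured as the genuine average
velocity of the polymerase (pauses included) the two agree by definition;
but for a synthetic model whose pauses are added *on top of* a 25-ms
baseline, total dwell exceeds $L/v$ and the convention underestimates true
dwell by the ratio $T_{total}/\sum_j d_j$, uniformly at every position.
The demo's recovery table therefore reports both scales: true smoothed
dwell in seconds, and the noise-free value of the estimator itself
(smoothed expected fraction $\times\,T_{total}$), with the relative error
taken against the latter so that it isolates sampling and pseudocount
error. Ranks, ratios between conditions and peak calls are unaffected by
this uniform scale factor.

### Condition comparison

`log2_ratio()` smooths each condition's fraction profile with the ratio
window (51 nt) and takes $\log_2(\mathrm{test}/\mathrm{ref})$ per position.
The ratio is computed on pseudocounted fractions, not raw counts, so it is
depth-invariant and defined everywhere; smoothing precedes the division.
`compare_conditions()` bundles the full report: per-condition aggregate
profiles, the ratio track, occupancy times, pause tables matched across
conditions by nearest position (within the pause caller's `min_distance`),
and per-region signal summaries.

## Pause calling

No standard peak definition exists for this kind of track, so the caller
is deliberately simple and fully parameterized: local maxima (leftmost
position of a plateau; boundaries excluded) filtered by **topographic
prominence** — height above the higher of the two flanking saddles — and
then by a minimum separation (`min_distance`, default 50 nt; when two
peaks are too close the higher one wins, ties to the left).

The default prominence threshold is derived from the smoothing kernel
rather than guessed. A single-nucleotide pause of multiplier $m$ on a
locally flat baseline $b$ survives the normalized Blackman kernel of width
$M$ as a bump of height $(m-1)\,b\,k_{\max}$, where
$k_{\max} = \max_n w(n)/\sum_n w(n) \approx 1/(0.42\,M)$ — about $1/13$
for the default 31-nt window. A threshold of $0.25 \times$ the profile
median therefore calls single-nucleotide pauses with $m \gtrsim 4$ (and
broader clusters at correspondingly lower multipliers), while sitting one
to two orders of magnitude above multinomial sampling noise at realistic
depths (tens of reads per position, further averaged by the kernel).
Setting the threshold as a multiple of the *median* rather than the mean
keeps it anchored to the baseline even when a few strong peaks carry much
of the mass. Because the anchor is the *global* median, regions whose
local baseline is several-fold elevated (such as the 5' block) can admit
small noise bumps at high sequencing depth; the returned `prominence`
column makes it easy to filter such calls, or `min_prominence` can simply
be raised.

## The synthetic-data generator

`build_dwell_profile()` + `simulate_reads()` define the stated world used
by all tests:

* a 7800-nt unit at 25-ms baseline dwell (the uniform occupancy implied by
  40 nt/s);
* optional uniformly elevated dwell over the first 1300 nt, emulating the
  strong 5'-block enrichment characteristic of pre-rRNA profiles
  (factor 4 in the demo);
* discrete pause sites as multiplicative dwell elevations. Multipliers act
  on the *local* baseline, so a pause inside the 5' block compounds with
  the block factor. In the demo world pause loci are 7-nt clusters rather
  than single bases, because a paused polymerase protects a footprint and
  observed occupancy peaks are broader than one nucleotide; cluster
  multipliers (8–30) were chosen once so that the strongest wild-type
  smoothed occupancy peaks exceed 150 ms against the 25-ms baseline, the
  magnitude scale this field reports, and so that depleted-over-wild-type
  ratios at pauses reach the two-fold range;
* a "depleted" condition obtained by attenuating every pause multiplier,
  $m' = 1 + a\,(m-1)$ with $a \in (0,1]$ (default $a = 0.5$), emulating
  loss of a pausing factor;
* read 3'-end positions drawn multinomially from the model's expected
  fractions; read lengths from a truncated geometric (mean 30 nt, minimum
  15 nt — plausible insert sizes; configurable, and irrelevant to any
  3'-end statistic); reads truncated at the unit's 5' boundary; replicate
  seeds derived deterministically from one master seed.

The generator emulates the *location* statistics of CRAC libraries, not
their molecular noise: no PCR duplication, UMI structure, mapping error,
crosslinking sequence bias, or polymerase–polymerase exclusion (TASEP) is
modeled — the occupancy-time conversion itself assumes independent
polymerases, so adding exclusion would make the generator inconsistent
with the estimator it is meant to test. A green parameter-recovery test
therefore establishes that the pipeline inverts the stated sampling model
correctly, not that it is robust to library artifacts such as duplication;
real libraries should be deduplicated upstream (no deduplication stage is
implemented here, deliberately).

## Multi-mapping and the collapsed rDNA unit

rDNA is multi-copy, so rRNA-derived reads are typically multi-mapped.
The pipeline collapses the repeats onto one representative unit and, by
default, keeps every alignment at weight 1 (`multimap_policy =
"keep-all"`), which is the correct accounting when all copies are
collapsed onto one frame. `"primary-only"` and `"fractional"`
(weight $1/\mathrm{NH}$) are available for other designs.

## qPCR arithmetic

`chip_enrichment()` implements the $2^{\Delta CT}$ ChIP formula:
$\Delta CT = \overline{CT}_{input} - \overline{CT}_{IP}$ (technical
replicates summarized by the mean, no outlier rejection), abundance
$= 2^{\Delta CT}$, optionally multiplied by the dilution ratio
(input/IP, defaults 100/20). The correction is **off by default** and the
flag is recorded on the result, because published "arbitrary units" may
follow either convention; both are exactly reproducible.
`relative_expression()` implements $2^{-\Delta\Delta Cq}$ against a
reference gene. `simulate_qpcr()` generates CT sets whose noise-free
analysis recovers a programmed enrichment exactly (under the
dilution-corrected convention), giving the round-trip test its oracle.

## Numerical choices

* **Coordinates**: all internal coordinates are 0-based half-open; unit
  coordinates run 5' to 3' regardless of genomic strand. GFF3 input is
  converted on read; `GRanges` containers use the usual 1-based closed
  convention at the boundary.
* **Edge handling in smoothing**: the kernel is renormalized over
  in-bounds positions, so constant profiles are fixed points and real
  signal at the unit ends (the 3' pile-up) is not artificially decayed.
  The cost is that smoothing conserves total mass only approximately when
  signal sits within half a window of a boundary; the sum-to-one
  invariant is therefore enforced on `fraction` profiles but not
  `smoothed_fraction`, and `occupancy_time()` accepts smoothed fractions
  with a 2% sum tolerance. Smoothing itself stays strictly linear (no
  post-hoc renormalization).
* **All-zero counts** (no reads, $\alpha = 0$) are an explicit error
  directing the user to pseudocounts, never a silent NaN track.
* **Pause ties**: plateaus are attributed to their leftmost position;
  equal-height peaks inside one exclusion window keep the leftmost.
* **Determinism**: every stochastic entry point takes a seed; replicate
  seeds are fixed offsets from the master seed; reruns are byte-identical,
  and the run manifest records every tunable plus input content hashes.
* **bedGraph precision**: tracks are written with `%.17g`, so a
  write/read round trip is bit-exact.

## Known limitations

* The independence assumption breaks down at very high polymerase density
  (initiation-limited regimes are fine; convoy effects are not modeled).
* Pause calls on smoothed tracks localize to the kernel scale: a called
  position is accurate to roughly half the smoothing window, and pauses
  closer than `min_distance` merge into one call.
* Occupancy times inherit the $T_{total}$ convention bias discussed above
  whenever total dwell differs from $L/v$.
* Per-position differential statistics (p-values for condition
  differences) are out of scope; the ratio track is descriptive, as is
  standard for this assay.
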