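---
title: "Methods: comparative variation analysis of circular endosymbiont genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative variation analysis of circular endosymbiont genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiovar)
```

## Scope and model

`symbiovar` analyses sets of closely related, small circular bacterial
genomes — the motivating system is *Buchnera aphidicola*, the obligate
aphid endosymbiont, whose ~0.63 Mb genomes are structurally stable and
AT-rich (~75% AT). The package chains six analyses that together
characterize within- and between-host genomic variation, plus a simulator
that generates genome sets with known ground truth so every stage can be
validated without downloading data.

The statistical core is deliberately simple and transparent:

* **Nucleotide diversity.** For an alignment with rows $i < j$,
  $\pi = \binom{n}{2}^{-1}\sum_{i<j} d_{ij}/m_{ij}$, where $m_{ij}$ counts
  columns in which both rows carry an unambiguous base and $d_{ij}$ counts
  those columns where the bases differ (Nei–Li). The sliding profile
  evaluates $\pi$ in 500-column windows advanced by 200 columns — the
  windowing convention used for genome-scale diversity scans of organelle
  and endosymbiont genomes. Windows are alignment columns, not any single
  genome's coordinates, because diversity is a property of the alignment.
* **Variant calling.** From a pairwise alignment, a SNP is a column with
  two unequal unambiguous bases; an INDEL *region* is a maximal run of gap
  columns in one row, counted as a single event regardless of its length.
  Percentages are reported over the shorter ungapped genome by default.
* **SSR detection.** Perfect tandem repeats of primitive units of 1–10 bp,
  classified as *normal* (units 1–6 bp at their length thresholds),
  *potential* (exactly two copies of a 5–6 bp unit), and *extended*
  (units 7–10 bp).
* **SSR comparison.** Two SSRs from different genomes are homologous when
  their 60 bp flanks align on both sides with identity and coverage at or
  above 0.90; groups are connected components of this relation. Genomic
  coordinates never enter the grouping, since genome start positions are
  arbitrary on a circle.
* **Phylogeny.** Tamura–Nei (TN93) distances under pairwise deletion,
  neighbor-joining, and nonparametric bootstrap by column resampling.
  Host–symbiont congruence is summarized by per-host monophyly, a
  Robinson–Foulds distance between the host tree and the symbiont tree
  condensed to one tip per host, and the list of hosts in conflicting
  bipartitions.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `window_size`, `step` | 500, 200 | alignment columns | standard genome-scan windowing; windows overlap 60%, smoothing pair-sampling noise |
| `z_threshold` | 2 | population SDs | a window is peak-marked when above mean + 2 SD of the profile |
| `merge_gap` | 1 | windows | single sub-threshold windows inside a peak do not split it |
| `min_segment_windows` | 10 | windows | segments shorter than ~2 kb of profile are noise at these scales |
| `flank_len` | 60 | bp | flank length for SSR homology |
| `min_identity`, `min_coverage` | 0.90 | fraction | inclusive thresholds ("at or above 0.90"); the boundary case 54/60 passes |
| SSR thresholds | mono≥10, di≥5, tri≥4, tetra≥3, penta/hexa≥2, hepta–deca≥2 | repeats | smallest thresholds under which every reported SSR spans ≥10 bp |
| `bootstrap_replicates` | 5000 (full scale) | replicates | the conventional deep bootstrap; tests and examples use 5–200 |
| `anchor_k` | 31 | bp | rotation anchors long enough to be unique in a 0.6 Mb genome |

### Rotation normalization

Circular assemblies start at arbitrary positions, so genomes are rotated
into a common frame before alignment. `detect_rotation` finds a reference
k-mer that is unique in the reference, locates it in the query (both
strands, across the origin), and reports the offset such that the query
reads as the reference rotated by that offset; rotating the query by its
negation restores collinearity. Up to 50 successive anchors are tried; for
genomes ≤50 kb an exhaustive minimum-Hamming scan over all rotations is
the deterministic fallback. This replaces the interactive
repeated-pairwise-alignment procedure used in practice with a reproducible
equivalent. The rotation reference defaults to the longest genome
(configurable), since no convention identifies a canonical reference.

### Segmentation

`segment_regions` performs recursive binary mean-shift segmentation of the
π profile, accepting a split only when the reduction in within-segment sum
of squares exceeds a penalty and both sides retain `min_segment_windows`
windows. The default penalty is BIC-style, $2\hat\sigma^2\log n$, with
$\hat\sigma$ estimated robustly from first differences of the profile at
the smallest overlap-free lag (for 500/200 windowing, lag 3): overlapping
windows share data, so lag-1 differences understate the noise. On profiles
with independent Gaussian noise the procedure recovers planted
change-points within ±5 windows (see the test suite); on real or simulated
genome sets the substitution process is phylogenetically autocorrelated
along the genome, and the segmenter may resolve such wobble into extra
short segments — region counts should be read together with the segment
means. Peak counts from visual inspection depend on thresholds; the z=2
population-SD rule is a documented, reproducible choice, not a claim that
it reproduces any particular hand count.

## The simulator: what it emulates, what it does not

`simulate_genome_set` evolves a random ancestor (default 20 kb at GC 0.25,
a desk-scale stand-in for a 0.63 Mb endosymbiont genome) down a rooted
tree with branch lengths in expected substitutions/site:

* **Substitutions** follow an HKY model (transition/transversion ratio
  κ = 2 by default) with the rate matrix normalized to one expected
  substitution per site per unit branch length. Regional rate structure —
  the three-region mosaic observed in endosymbiont diversity profiles — is
  imposed by per-region branch-length multipliers (default 1, 3, 1.5 over
  thirds of the genome). Gamma rate variation is not modelled; regional
  multipliers are the intended source of rate heterogeneity.
* **Indels** arrive as a Poisson process at `indel_rate` events per site
  per unit branch length (default 0.05, matching the roughly 20:1
  SNP-to-INDEL-region ratio seen between close endosymbiont genome pairs),
  with geometric lengths of mean 3 truncated at 50 bp.
* **Planted SSRs** are inserted into the ancestor before evolution; the
  base immediately on each side of a plant is adjusted, if needed, so the
  run cannot extend by chance and is recovered with its exact coordinates
  and count. Each planted SSR can undergo **slippage** (±1 unit,
  probability 0.1 per SSR per branch) so that descendant genomes diverge
  in repeat number, exercising the repeat-variation detection of the SSR
  comparison stage.
* **Rotations**: each tip is circularly shifted by a recorded uniform
  offset.

The simulator does *not* model recombination, horizontal transfer, gene
gain/loss, ambiguity codes, or selection. Consequently, passing tests
demonstrate algorithmic correctness (recovery of planted structure under
the stated generative model), not robustness to assembly error,
annotation error, or non-treelike evolution in real data.

## Numerical choices and degenerate inputs

* Gap policy for π is pairwise deletion (per-pair exclusion of columns
  with gap or `N`); complete deletion is available. A pair with zero
  comparable sites is an error naming the pair, never silently zero.
* The built-in aligner is Needleman–Wunsch with affine gaps
  (match +2, mismatch −1, a gap run of length $g$ scoring $-4 - g$),
  intended for flank-scale sequences; genome-scale alignments are
  ingested from files. `N` scores as a mismatch and is excluded
  downstream.
* TN93 saturation (non-positive logarithm argument) maps to a configured
  maximum distance with a warning rather than `NaN`.
* SSR runs are reported from the leftmost position of each maximal
  periodic region with `floor(length/period)` repeats; units that are
  themselves periodic are suppressed (covered at the shorter period).
  Units are compared across genomes by their lexicographically minimal
  rotation; the reported unit keeps genomic phase. Origin-crossing runs
  are only joined under `circular_scan`, off by default, because rotation
  normalization should precede scanning.
* Terminal gap runs in pairwise alignments — the signature of comparing
  circular genomes whose starts were not normalized — are excluded from
  INDEL calls by default, with a flag to include them.
* Trees are unrooted internally; outgroup rooting happens only at
  presentation. NJ ties are resolved by `ape`'s deterministic
  implementation.
* All stochastic stages (simulation, bootstrap, pipeline) consume an
  explicit integer seed and restore the caller's RNG state.

## Open design choices

Where the underlying procedure was described only qualitatively, the
package fixes one behaviour and documents it:

* "Above 90%" flank similarity is implemented as ≥ 0.90 (inclusive).
* SSR groups are connected components rather than cliques: the relation
  is not transitive, components are order-independent, and near-matches
  chain — the alternative (cliques) would depend on enumeration order.
* SSRs must share a canonical unit *before* flank matching; since unit
  inspection happens anyway, pre-filtering changes nothing in the result
  but avoids aligning flanks of unrelated repeats.
* Which genome anchors rotation, and whether the deep-bootstrap count is
  run at desk scale, are configuration, not behaviour.

## Problem sizes

Tests and the acceptance script run entirely on synthetic data at
deliberately modest sizes chosen to exercise every code path with
comfortable statistical resolution: genomes of 2–30 kb, alignments up to
20 kb × 8 tips, 20-seed topology-recovery panels, 100–500-string SSR
comparisons against a brute-force scanner, and bootstraps of 1–200
replicates. The full-scale conventions (0.63 Mb genomes, 5000
pseudoreplicates) are the documented defaults of the pipeline
configuration.

## Limitations

* Nucleotide diversity, segmentation and peaks are computed in alignment
  space; a poor multiple alignment propagates directly into the profile.
* The NJ/TN93 tree is the in-package reconstruction; Bayesian or ML trees
  are consumed only as externally produced Newick files.
* Absolute SSR counts depend on the minimum-length thresholds; the
  defaults are the smallest choices consistent with a 10 bp floor, and
  other published pipelines may count differently.
* The congruence report treats the host tree as known; uncertainty in the
  host phylogeny is not propagated.
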