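---
title: "Homology segment analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology segment analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmentHomology)
```

## The question the package addresses

Polytene chromosomes form *ectopic contacts*: non-homologous pairings
between cytological bands, typically involving intercalary
heterochromatin. Cytology yields, for a region of interest, a table of
FECs — frequencies of ectopic contacts of every band with that region,
expressed as the percent of examined nuclei showing the contact. The
hypothesis under test is that short stretches of identical DNA
(dispersed repeats, satellite-like elements) mediate this pairing: bands
dense in sequence homologous to the region of interest should contact it
more often.

The package operationalizes this as *homology segment analysis*:

1. **Fragment extraction.** The source region is cut into all of its
   length-*k* fragments by a sliding window of step 1
   (`extract_fragments()`). A region of length *L* yields *L − k + 1*
   fragments; windows containing `N` are dropped. Duplicate sequences are
   retained with their offsets, so a repeat that occurs ten times in the
   source carries tenfold weight downstream.
2. **Localization.** Every exact, ungapped, case-insensitive occurrence
   of each fragment on the target chromosome is located
   (`locate_matches()`), on both strands by default. The implementation
   decomposes the target into its *k*-mers and joins them against the
   fragment set by hash, which is equivalent to — and tested against — a
   naive character-by-character scan.
3. **LFF profile.** Hits are aggregated per cytological band into the
   localized fragment frequency profile (`build_lff()`): raw counts and
   hits per kb of band. A hit belongs to the band whose half-open
   interval contains its start.
4. **Correlation.** The LFF profile is compared with a strain's FEC
   column by Spearman's rank correlation (`correlate_lff_fec()`); both
   distributions are far from normal, so a rank statistic is the
   appropriate choice. Significance is declared at *p* < 0.01.

Coordinates are 0-based half-open throughout, the BED convention; the
colon-separated region string (`":X:11982050:12772070"`, a ~790 kb
region) uses the same convention.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| fragment length `k` | 30 | nt | the working length for this analysis; 20 nt fragments pick up unspecific homology, 50 nt ones lose sensitivity (see the sweep below) |
| `strand_mode` | `both` | — | a single-stranded fragment can pair with either strand; `forward_only` is available since the original protocol's strandedness is not documented |
| `weighting` | `proportional` | — | each source occurrence × target occurrence is one hit, preserving repeat-density signal; `unique` counts each distinct fragment once per site |
| `exclude_self` | `TRUE` | — | hits inside the source region are omitted — a region cannot contact itself, matching the NA convention of FEC tables |
| significance `alpha` | 0.01 | — | correlations with *p* ≥ 0.01 are reported as non-significant |
| LFF variant | `raw` | counts | cytological bands are of comparable scale; `per_kb` normalization is available |
| quantum / threshold | 1 s / 5 mm/s | — | locomotion quantization constants |

Two deliberate conventions in `locate_matches()`: overlapping
occurrences are all reported, and a palindromic fragment that matches
both strands at the same position is counted once (deduplicated by
position and fragment), since both "matches" are the same duplex site.

## Statistical pieces

**Spearman rS** is computed as the Pearson correlation of mid-ranks
(tie-corrected; equals `1 - 6*sum(d^2)/(n(n^2-1))` when tie-free). The
two-sided p-value uses the large-sample t approximation for n ≥ 10 and a
seeded label-permutation estimate (10^4 permutations) below that, where
the approximation is unreliable; both can be forced. If either vector is
constant after NA removal, ranks carry no order information: rS is
reported as `NA` with *p* = 1 rather than a spurious 0. Bands with zero
hits and nonzero FEC (or vice versa) stay in the correlation — they are
informative — while NA cells are dropped pairwise.

**Mode-of-inheritance classification** (`classify_band()`) follows the
reciprocal-cross column logic with "no difference" meaning |t| < 1,
where t is the unpooled (Welch) two-sample statistic on per-nucleus
contact indicators. The choice of unpooled variance is this package's
(the source criterion does not specify it); with 0/1 data and similar
group sizes the two differ negligibly, and the scale-consistency
property (multiplying counts and nuclei by m never turns a difference
into a no-difference) holds exactly for the unpooled form. When a band
satisfies both the maternal and the paternal pattern, it carries no
origin information and is reported `unclassified` with a `concordant`
note; precedence elsewhere is absent > heterosis > concordant > maternal
> paternal > hybrid-specific, treating heterosis as the distinct flagged
class it is in the source tables.

**Behavioral statistics.** Tracks are divided into 1 s quanta; the mean
speed in a quantum is the path length travelled within it (segments
straddling a boundary are split by linear interpolation — the quantum
definition prescribes only the mean speed, and interpolation is the
least-committal reading) divided by the quantum width. A trailing
partial quantum is discarded. No smoothing is applied beyond merging
neighboring quanta of equal state: whether the original acquisition
software suppressed isolated sub-threshold quanta is not documented, so
the package does nothing it cannot justify. The learning index is
`LI = 100 (mean CI_naive − mean CI_trained) / mean CI_naive`; its
randomization test permutes group labels over the pooled courtship
indices with the add-one estimator `(1 + extreme)/(1 + reps)`, two-sided
by |LI|. A permutation that produces a zero naive mean (LI undefined) is
scored as extreme, which is conservative. "Two-way" is read as this
two-sided label permutation; the source protocol does not define it
further.

## What the synthetic generator emulates

`make_genome()` builds a desk-scale banded chromosome: by default 1 Mb,
20 bands of 50 kb, i.i.d. background with A/T fraction 0.6 (echoing the
A/T-rich repeat context of the real system). Two repeat families are
planted at uniformly drawn, non-overlapping positions:

* a **driver** family — a random 372 bp unit, the length of the
  middle-repetitive element implicated in the real pairing — whose
  per-band copy numbers form a fixed permutation of distinct values,
  highest in the source band and zero in the control band;
* a **bystander** family (200 bp) concentrated in the control band and
  scattered over a few bands whose driver densities span low to high, so
  its placement carries no information about FEC.

`make_fec()` then sets `FEC = clamp(5 + 2.5 × density + ε, 0, 100)`
percent with seeded Gaussian ε and an NA self-band. The link parameters
keep the densest band near 80 %, within the range cytology can report.
Because the driver densities are distinct and the link monotone, the
zero-noise Spearman correlation between a source-region LFF profile and
FEC is exactly 1 — the parameter-recovery check — while shuffling
densities before generating FEC destroys the association, and control
region scans (which share no driver homology) stay non-significant.
Default mutation rate is 0 so that recovery checks are exact; raising it
degrades LFF counts smoothly (≈ (1−µ)^30 of 30-mers survive per copy)
without reordering band ranks at moderate µ, which is tested at µ = 0.01.

`make_cross_design()` derives the four reciprocal-cross strains from the
same densities with fixed multipliers per planted mode (e.g. maternal =
parent A 1, hybrid A×B 1, hybrid B×A 0.3, parent B 0.3) at 500 examined
nuclei per band — within the 300–500 chromosome range typical of such
cytology — chosen so that every planted difference clears the |t| ≥ 1
criterion even at the lowest-density band.

`make_tracks()` realizes run/rest schedules (whole-second bouts, so bout
edges align with quanta and bout counts are recovered exactly) with
multiplicative speed jitter and a drifting heading; `make_courtship()`
draws truncated-Gaussian courtship indices.

What the generator does **not** emulate: polytene underreplication,
chromatin domain structure, sequence divergence between repeat
subfamilies, band-size heterogeneity of real cytological maps, arena
walls or tracking noise in behavior. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration on data with planted
truth, not biological conclusions about any real genome.

## Problem sizes and costs

The default test design (1 Mb, 20 bands, k = 30) scans in a few seconds:
the target decomposes into ~10^6 30-mers and the hash join is linear.
The full dm6-scale command the tool mirrors (a 790 kb source against a
23 Mb chromosome) extrapolates to a few minutes and ~2 GB, dominated by
the k-mer table. Oracle-equivalence checks run on hundreds of sub-3 kb
genomes, where the naive O(n·m) scan is affordable; correlation-oracle
checks use 10^3 random vectors; the shuffled-density null uses 200
replicates (binomial error on a 95 % bound ≈ 1.5 %).

## Known limitations

* `locate_matches()` holds the target's k-mer table in memory; a
  chromosome much beyond ~100 Mb at k = 30 would need chunking.
* Exact matching only — no mismatches or gaps. Diverged repeat copies
  contribute only their conserved k-length stretches.
* Per-fragment correlations in `rank_fragments()` inherit the heavy-tie
  regime of sparse per-band counts; their p-values are indicative.
* The classifier assumes the four-column reciprocal design; other cross
  schemes need their own contrasts.
* No multiple-testing correction across strains or fragments, matching
  the original analysis, which applied none.
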