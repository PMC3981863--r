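---
title: "Methods: consensus methylated-region comparison and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus methylated-region comparison and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mbdmr` compares the DNA-methylation landscapes of two cell types from
enrichment-sequencing peak sets. This vignette records the model, the
conventions and numerical choices behind each stage, what the synthetic
generator does and does not emulate, and the design decisions taken where
more than one reading was defensible.

## Coordinates and interval algebra

All coordinates are 0-based, half-open (the BED convention), and chromosome
names are compared as exact strings with no `"chr"` aliasing — a region set
on `"1"` never matches one on `"chr1"`. Region sets are merged at
construction: overlapping or book-ended records collapse, so "number of
regions" is unambiguous. Three primitives drive everything downstream:

- `merge_intervals(x, gap)` joins intervals separated by at most `gap` bp
  (default 0, which also joins book-ended intervals) via a sorted scanline;
- `intersect_bases(a, b)` returns the intervals covering exactly the bases
  covered by both inputs;
- `overlap_filter(query, subject, min_overlap)` keeps query regions sharing
  at least `min_overlap` bp (default 1) with at least one subject region,
  coordinates unmodified — the `intersectBed -u` presence semantics.

All three are verified against an independent per-base bitmap
implementation on randomized toy genomes in the test suite; the bitmap path
shares no code with the package internals.

## Consensus, DMR, CMR

The consensus of a cell type is the base-pair intersection across all of
its replicates. Two readings of "overlapping regions among one cell type"
are possible — base intersection, or replicate-1 regions confirmed in all
others — and we chose base intersection because it is symmetric in the
replicates and order-independent; the one-directional *comparison* variant
is still exposed (`direction = "a_only"` in `compare_cell_types()`) for
users who want only one side's consensus classified.

Each consensus-A region is then tested for presence in each B sample one by
one: present in none → DMR, in all → CMR, otherwise PARTIAL. Presence is
overlap of at least `min_overlap` bp with at least one region; the default
of 1 bp is deliberate (no overlap-fraction rule is imposed) and the
parameter is exposed. Three bookkeeping rules:

- PARTIAL regions are excluded from the total used for percentages, so
  DMR-A + DMR-B + CMR = 100%. Published three-way pie charts of this kind
  sum to 100 with only those categories, which forces this choice.
- The A-side and B-side CMR lists are unified by coordinate union before
  counting, so a region common to both cell types is counted once.
- Percentages are computed unrounded and rounded half-up to one decimal
  only at the report layer (whole percentages print without decimals).
  Half-up, not R's default half-even, because reference values of this kind
  are printed that way (e.g. 99.4502% → 99.5%).

Invariants asserted in the tests: the three labels partition each
consensus; a DMR of A shares no base with any B sample (checkable with
`intersect_bases`); swapping the argument order swaps the DMR sides and
leaves the CMR bases identical.

## Replicate concordance

`pairwise_concordance(a, b)` divides the number of overlapping regions by
the total regions detected in the two samples. The numerator counts
overlapping regions **from both sides** ($n_a^{ov} + n_b^{ov}$): with a
one-sided numerator the stated denominator could never reach 1 for
identical samples, and any concordance measure must score identity as 1. A
region overlapping several partners counts once (presence, not pairing).

## Annotation

Regions are assigned exactly one category with precedence
**promoter > exon > intron > intergenic**. The promoter window is
TSS−2000..TSS+500 bp, strand-aware (TSS = `tx_start` for `+` genes,
`tx_end` for `−` genes), clipped at position 0; both extents are
parameters, since no universal window exists. When a region overlaps
several genes within its winning category, the gene with the largest base
overlap is reported, ties broken by lexicographic gene name — deterministic
and documented, nothing more. Gene models load from compact 7-column or
full 11-column refFlat-style TSV, or BED12. The four-category scheme is a
stand-in vocabulary: exhaustive, exclusive, and conserved under genome
mirroring (a property test), but coarser than CpG-island- or
distance-based schemes, which are out of scope.

## Expression screen

"Quantile normalization (75%)" in the GeneSpring sense is implemented as
**75th-percentile shift** normalization: intensities are log2-transformed
and each sample is shifted by a constant so its 75th percentile equals the
across-sample median of 75th percentiles. It is *not* full quantile
normalization — that would equalize entire distributions and is not
parameterized by a single percentile, whereas the percentile-shift preset
is exactly what the named option does. The function tags its output
(`log2` attribute) so a second application is a no-op, and within-sample
relative differences are preserved exactly.

The per-probe test is Student's two-sample pooled-variance $t$
(`var_equal = FALSE` switches to Welch), vectorised over probes.
Zero-variance probes follow an explicit edge rule: $p = 1$ when the group
means agree, $p = 0$ when they differ with zero pooled variance.
Benjamini–Hochberg adjustment is the step-up
$q_{(i)} = \min_{j \ge i} (m/j)\,p_{(j)}$, capped at 1; the tests verify it
against both a brute-force evaluation of that definition and
`stats::p.adjust`. A probe is called up or down only when
$|log_2 FC| > \log_2(\text{fc\_threshold})$ **and** $q < q_\text{threshold}$
(defaults 2 and 0.05); "up" means higher in group A, and which group is A
is the caller's explicit choice, since figure-axis orientation is a
presentation detail. Hierarchical clustering of samples uses
$1 - r_\text{Pearson}$ distance with average linkage; qPCR relative
expression is $2^{-\Delta\Delta Ct}$ with the calibrator-group mean anchored
at 1.

## Methylation summaries

The clone, not the CpG, is the statistical unit: per-CpG percentages are
averaged within clone, then clone means are summarized per group (mean and
$n-1$ SD; a single-clone group reports SD 0 with `n = 1` as the flag) and
compared with the pooled $t$-test. Global repeat assays (B1/LINE1-style)
are ordinary loci with many CpG rows — no special handling.

## The synthetic world

The generator's defaults state one fixed world rather than a tuning
surface:

| parameter | default | rationale |
|---|---|---|
| `n_shared`, `n_specific_a`, `n_specific_b` | 200 / 50 / 30 | small enough for seconds-scale runs; specific:shared ratio echoes a reprogramming-type contrast |
| `region_length_range` | 500–2000 bp | enrichment-peak scale, not fragment scale |
| `boundary_jitter_sd` | 100 bp | anchored to the 100–300 bp sonicated-fragment size that limits peak-boundary resolution |
| `min_gap` | 1000 bp | keeps jittered neighbours from merging, so truth labels stay unambiguous |
| `n_replicates` | 3 per side | typical replicate count for such designs (3–4) |
| `p_detect` | 0.8 | yields pairwise replicate concordances around 60–80%, the range reported for real enrichment-seq replicates |
| `fp_rate` | 20 per replicate | a ~10% spurious-call floor |
| expression | 54,497 probes, 26 up / 12 down, $|log_2 FC| = 3$, sd 0.25, 6 vs 6 | the published screen's array size, hit counts and design |

Truth regions are non-overlapping by construction and false positives are
rejection-sampled into truth-free gaps, so a false positive can never
silently convert a DMR into a PARTIAL region in the noiseless bookkeeping —
a simplification: real spurious peaks do abut real ones. Jitter draws that
would invert an interval are dropped (that region keeps its true
boundaries), and endpoints are clamped to the chromosome. Replicate
generation seeds the RNG at `seed + 1` so its stream is decoupled from
truth placement while remaining a pure function of the config.

What a green test establishes: the deterministic bookkeeping is exactly
right (noiseless recovery is exact), and under independent per-replicate
detection the CMR yield follows its binomial expectation
($\text{Binomial}(n_\text{shared}, p^{2k})$ for $k$ replicates per side).
What it does not establish: behaviour under correlated replicate failures,
enrichment-strength-dependent detection, overlapping truth regions,
copy-number effects, or read-level artefacts — none of which the generator
models.

## Degenerate inputs and errors

Empty BED files parse to empty region sets (not errors); malformed
coordinates fail with the line number. Concordance of two empty samples is
an error, not 0. A comparison with zero total regions reports undefined
percentages. Zero-variance sample profiles make correlation clustering
fail with the sample named. Capacity errors (truth regions that cannot be
placed at the requested `min_gap`) are raised after a bounded number of
rejection retries rather than looping forever.

## Known limitations

- Presence/absence only: a region methylated in both types but at
  different enrichment strengths is a CMR here by definition.
- Consensus by base intersection shrinks regions toward the most
  conservative core; replicate-count-weighted or coverage-based consensus
  is out of scope.
- The annotation vocabulary is a four-category stand-in; no CpG-island or
  nearest-gene-distance annotation.
- Peak calling itself (alignment, fragment pileup, MACS-style detection)
  is upstream of this package: inputs are already-called peak BED files.
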