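---
title: "Methods: mapping-based profiling of long ribosomal amplicons"
author: "longamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping-based profiling of long ribosomal amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the approach

Species-level microbiota profiling from nanopore-class long reads trades
per-base accuracy (~89%) for amplicon length. `longamp` implements a
mapping-based workflow for two ribosomal markers — the full-length 16S
rRNA gene (~1.5 kb, nine hypervariable regions) and the 16S-ITS-23S
region of the rrn operon (~4.3 kb) — in which each read is aligned
against a taxonomically labelled reference set and assigned to the
species of its best-scoring alignment. The stages are:

1. **Trim** a fixed 45 bp from each read end (universal tags + custom
   primers flanking the amplicon).
2. **Length-select** trimmed reads: 1,200–1,800 bp (16S) or 3,500–5,000 bp
   (rrn), both bounds inclusive.
3. **Map** each read against the reference database with a minimizer
   seed–chain–extend aligner reporting Smith–Waterman-style AS scores.
4. **Remove chimeras** whose coverage profile shows an internal gap.
5. **Filter** hits to alignment blocks of at least 1,000 bp (16S) or
   3,000 bp (rrn), both inclusive.
6. **Assign** each read to the species of its maximal-AS hit; cross-species
   ties fall back to a genus-level LCA (reported as `ambiguous` with the
   genus filled in) or are dropped, per policy.
7. **Tabulate** species/genus abundances, rarefaction curves, database
   diagnostics and mock-community evaluation metrics.

Because the pipeline relies on large real reference databases and
sequencing runs that are not reproducible at desk scale, the package
includes a first-class simulator that emulates the relevant properties of
the data, so every claim about the pipeline can be tested end to end.

## The aligner

Candidate references are found by shared canonical minimizers
(`k = 15`, `w = 10`, invertible 64-bit hash). Anchors are grouped per
reference and strand, clustered by diagonal (single-linkage, 50 bp gap),
and extended with banded affine-gap local dynamic programming
(match +2, mismatch −4, gap open −4, gap extend −2; a gap of length *g*
costs 4 + 2*g*). These scoring defaults mirror the long-read mapper
conventions under which the downstream block-length and AS thresholds
were established, so those thresholds transfer unchanged.

Extension terminates when the running score drops more than `z_drop = 70`
below its maximum — the same role the z-threshold plays in minimap2-style
base-level alignment: it prevents alignments from walking across chimeric
junctions while never triggering on reads that match their reference at
the expected ~89% accuracy (the score drift is strongly positive there).
The band half-width is about twice the expected indel-error count of a
full-length read: 500 bp for rrn, 200 bp for 16S. Chains are filtered
region-aware: a chain occupying a read interval not already claimed by a
stronger chain is always extended (so both halves of a chimera are
aligned), while chains overlapping a stronger chain's interval are
extended only if they hold at least half its anchors — which keeps the
~97%-identical close relative in play as the competitive decoy while
skipping hopeless candidates. Ties in AS are broken by reference id, then
leftmost reference start, making runs bit-reproducible.

An exact O(nm) Smith–Waterman with the same scoring ships as
`smith_waterman()`. It is the package's reference implementation: tests
require the banded mapper's AS to equal it on the reported interval, and
it is itself checked against `Biostrings::pairwiseAlignment()` as an
independent oracle. N bases never count as matches anywhere.

## What the simulator emulates (and what it does not)

`synthesize_reference_set()` builds marker templates as
conserved/variable mosaics: alternating conserved blocks (divergence
0.02 between species) and variable blocks (divergence 0.30, plus small
indels), with a hypervariable ITS in the rrn template. The mosaic is what
makes the diagnostics realistic: reads whose species is missing from the
database still seed and align in conserved blocks, but their alignments
fragment in variable blocks — producing the short-block/low-AS second
mode that flags an incomplete database. Species 1 and 2 form a designated
close-relative pair built by an exact count of substitutions so their
global identity is exactly the requested 0.97 (the hardest realistic
decoy: congeneric species whose 16S genes are ~97% identical). Lineages
are synthetic (the close pair shares a genus; genera group into classes
of three) so taxon-subsetting experiments have a class to remove.

`simulate_reads()` draws amplicons by design weight and applies
independent per-base errors. The default split of the 11% total error is
half substitutions and a quarter each insertions/deletions
(0.055/0.0275/0.0275), giving an expected alignment identity of
(1−del)(1−sub)/(1+ins) ≈ 0.893; the generator also reports its realized
event counts so this identity can be verified without alignment.
Smith–Waterman-measured identity runs ~0.5 points higher because local
alignment clips terminal errors.

Every amplicon carries the constant 45 bp tag+primer stubs at both ends —
that is what the fixed 45 bp end-trim removes. Chimeras are modelled as
pore read-through events: a 3' portion of one tagged molecule (0.35–0.65
of its length) concatenated with the 5' portion of a second molecule from
a different species, leaving both molecules' tags (~90 bp of
non-biological sequence) at the junction. Short fragments are truncated
amplicons at 0.3–0.8 of the marker length; read length jitter is Gaussian
(σ = 3% of the molecule) applied as truncation; each read is
reverse-complemented with probability 0.5; qualities are a constant Q12
placeholder (the pipeline never uses them). `inject_carryover()` mixes in
reads from a previous run at a chosen fraction with `is_carryover` truth
flags, emulating barcode carryover of a few percent.

Not emulated: signal-level errors, homopolymer-specific error structure,
and PCR/primer amplification bias (real markers over/under-amplify some
taxa; no quantitative bias model is available to copy). Passing tests
therefore demonstrate correctness of the pipeline's logic under an
idealized error process, not robustness to primer bias or basecaller
artifacts.

## Chimera detection

Coverage profiles are the union of a read's hit intervals (multiplicity
≥ `min_cov`, default 1) against the classification database. A read is
`chimeric` when an internal uncovered run of at least `min_internal_gap`
bp lies strictly between two covered intervals, `uncovered` when less
than `min_covered_fraction = 0.8` of it is covered, otherwise `clean`;
end gaps never count. Under reference mapping both chimera halves are
fully explained by their parents, so the only unmappable junction
sequence is the retained tag/primer stubs: ~90 bp for a read-through
junction, 45 bp if only one tag survives, while alignment-end straggle on
clean reads is a few bp. `min_internal_gap = 50` sits between those
scales. On labelled simulations (rrn, 5% chimeras, n = 2,000) the
detector reaches sensitivity ≥ 0.9 at a false-positive rate ≤ 0.02;
chimeras that are filtered earlier by the length window never reach the
detector and are excluded from that sensitivity.

## Classification and reporting conventions

- Statuses partition the reads entering classification: `assigned`,
  `ambiguous`, `unassigned` (no hits), `filtered_block` (hits but none
  reaching the block threshold), `chimeric`, `uncovered`.
- A genus-level LCA call keeps status `ambiguous` with the genus field
  set; it counts in genus-rank abundance only. `n_best_ties` makes tie
  handling transparent.
- Relative abundances are normalized over classified reads (heat-map
  convention), not all sequenced reads.
- Accuracy against simulator truth is reported both unconditionally
  (correct / reads that reached classification) and conditionally
  (correct / assigned); the conditional figure is the one comparable to
  published assignment percentages, which are computed over classified
  reads. `filtered_block` reads count in the unconditional denominator.
- Abundance-vs-expectation regression is ordinary least squares in
  log10–log10 space with zero-count species excluded and reported, never
  pseudo-counted.

## Database diagnostics

Histograms of the winning hit's block length or AS (50 equal-width bins
from 0, moving-average smoothing over 5 bins) are scanned for modes. The
distribution is called bimodal when at least two modes each hold ≥ 5% of
the mass and are separated by a valley no higher than half the smaller
peak — the valley condition is what keeps noisy unimodal, left-skewed
histograms from being flagged. Removing a class that contributes ~24% of
the reads flips the rrn block-length histogram from unimodal to bimodal
in simulation, while paired full-vs-subset comparisons
(`compare_dbs()`) show the read-wise AS drop (removing references can
never raise a read's best AS) and the restored concordance once the
missing reference is added back.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere; block length counts all
  alignment columns including gaps.
- Window bounds and block thresholds are inclusive ("equal or larger").
- All randomness flows through R's RNG from a single seed per entry
  point; the same seed reproduces FASTQ, truth tables and pipeline output
  byte for byte.
- Problem sizes used by the shipped checks were chosen so each experiment
  represents its regime at desk scale: even mocks at 2,000 reads,
  the staggered design at 20,000 reads (enough that the 10^3-copy
  stratum is expected >3 times), carryover at 5,000 reads, identity
  measurement at 1,000 reads.
- Degenerate inputs are statuses, not crashes: reads emptied by trimming
  are `rejected`, reads without hits are `unassigned`/`uncovered`, an
  empty abundance table is returned (not an error) when nothing
  classifies; empty databases and empty read sets abort naming the stage.

## Known limitations

- The reference aligner is not a minimap2 replacement: no split/
  supplementary flag semantics, no MAPQ calibration, no SAM output.
- Species sharing >99% identity over the chosen marker are not reliably
  separable at 89% read accuracy; the close-pair experiments quantify the
  ~97% case only.
- The simulator's uniform per-base error process understates structured
  errors; accuracy figures on real flow cells will be lower than the
  simulation analogs.
- Operon copy-number correction is out of scope; staggered-mock
  regressions are on operon copies, not cell counts.
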