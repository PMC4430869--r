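---
title: "Inferring tandem duplication-random loss events from mitochondrial gene orders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tandem duplication-random loss events from mitochondrial gene orders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotdrl)
```

## The problem

Vertebrate mitochondrial genomes carry the same 37 genes (13 protein-coding
genes, 22 tRNAs, 2 rRNAs) plus a control region (CR), almost always in the
same circular order. When a species departs from that order, the dominant
explanatory mechanism is **tandem duplication-random loss (TDRL)**: a
contiguous block of genes is duplicated in tandem, the genome transiently
carries two copies of each gene in the block, and subsequent random
silencing of exactly one copy per gene shuffles the order. The silenced
copies degrade into pseudogenes and eventually into short non-coding
spacers, so a *recent* TDRL event leaves two kinds of evidence in a single
genome:

1. a **gene-order signature** — the rearranged block splits into exactly two
   clusters, each preserving the ancestral relative order; and
2. a **spacer signature** — unusually long intergenic gaps at precisely the
   junctions where silenced copies decayed.

`mitotdrl` formalizes both signatures and tests them against annotated
mitogenomes. Its motivating case is the flatfish genus *Symphurus*
(tonguefishes), where one species retains the typical vertebrate order while
its congener carries a large rearrangement between the CR and the WANCY tRNA
cluster — the first teleost genus known to contain both states.

## The model

Number the genes of the analysis window `1..n` by their rank in the typical
vertebrate order. A TDRL event is parameterized by a duplicated interval
`[a, b]` and a bipartition of `{a..b}` into copy-1 survivors and copy-2
survivors. Applying the event to the identity gives

```
1 .. (a-1), sort(copy1), sort(copy2), (b+1) .. n
```

because survivors of each copy retain their relative order and every copy-1
survivor physically precedes every copy-2 survivor. Inference inverts this:

* the **minimal duplicated interval** is `[min, max]` of the displaced
  ranks;
* the window is **explainable by one event** iff values outside that
  interval are at identity positions and the subpermutation inside it has
  exactly one descent (two maximal increasing runs);
* when the descent count is exactly one, the survivor bipartition (run 1 /
  run 2) is *forced* — no other split reproduces the observed order. The
  test suite verifies this uniqueness by brute force, and verifies against
  exhaustive enumeration that the analytic criterion accepts exactly the
  single-event-reachable permutations for all windows up to n = 6.

The reported interval is a lower bound ("at least"): a wider duplication
whose flanking genes survived in their first copy is indistinguishable from
the minimal one. For multi-step distances only the run-count bound
`ceil(log2(#runs))` is provided; maximum-likelihood multi-event
reconstruction is out of scope.

### Remnant sites

Every silenced copy decays where it sits, so each adjacent pair of
*surviving* genes in the post-event arrangement that brackets one or more
silenced copies is predicted to carry a spacer. The duplication **seam**
(junction between the last copy-1 survivor and the first copy-2 survivor) is
always emitted as a predicted site, even when no silenced gene lies there:
the boundary retains duplicated non-coding flanking sequence. This choice is
what reproduces the observed five-gap correspondence in *S. orientalis*,
where the gap between tRNA-Met and tRNA-Val sits exactly on the seam of the
minimal interval and no silenced copy maps there. Observed spacers are
matched to predictions by exact flanking-gene identity; spacers in the
window but beyond the duplicated region (the ND2/tRNA-Trp gap in
*S. orientalis*) are reported as "outside the duplicated region" and given
no origin.

By default `predict_remnant_sites()` returns only junctions that predict a
spacer (non-empty loss list or the seam); `keep_empty = TRUE` enumerates all
survivor junctions. When one entire copy is silenced the order is unchanged
and the whole silenced copy is predicted to decay at the seam.

## Worked example

```{r}
ori <- symphurus_annotation("orientalis")
summarize_annotation(ori)
tdrl_report(ori)
```

## Coordinates and spacers

All I/O is 1-based inclusive (GenBank convention). The intergenic length
between adjacent features is `right_start - left_end - 1`; negative values
are overlaps and are reported as-is. The wrap gap across the circular origin
is `(genome_length - left_end) + (right_start - 1)`. Nested origin-class
features (the O_L-like element inside the *S. plagiusa* control region) are
kept in the annotation but excluded from the spacer chain — they overlay the
CR rather than linking into the gene chain, and the published table itself
assigns them no intergenic value. A provided intergenic column is
revalidated on read and mismatches fail by default (`validate = "warn"`
downgrades them): transcription errors are the main input risk for
hand-typed coordinate tables. `write_table()` records the genome length in a
header comment because a trailing wrap gap cannot be recovered from feature
coordinates alone.

The large-spacer threshold defaults to 20 bp, the conventional cut for
"large" mitochondrial intergenic spacers; it is an argument everywhere it is
used.

## The hairpin scanner

The origin of light-strand replication (O_L) is a ~40-50 nt stem-loop,
normally inside the WANCY tRNA cluster. Both *Symphurus* mitogenomes lack it
there, and *S. plagiusa* instead carries an O_L-like hairpin inside the CR
near tRNA-Phe — the lynchpin of the dual-origin duplication hypothesis for
the rearrangement. `scan_stem_loops()` is a purely combinatorial inverted
repeat scanner: no thermodynamic folding, by design, so results are exactly
reproducible without an energy-model dependency (noted as an extension
point). A hit is defined by greedy maximal outward extension from each
candidate loop, trimming trailing non-pairing positions; this makes the hit
set well-defined without a maximum stem length. Defaults — minimum stem 8
bp, loop 3-20 nt, at most 1 mismatch — bracket the canonical teleost O_L and
the 52 bp O_L-like feature; the source publication draws its structures
rather than parameterizing them, so no numeric structure claims are attached
to these defaults and all are arguments. G.T wobble pairs count as
half-score pairs rather than mismatches (wobble pairing stabilizes the
hairpin). Scanning runs on the deposited H-strand: the O_L hairpin forms on
the displaced parental H-strand, so no strand flip is applied.

Two numerical notes. First, overlapping hits describing the same locus are
collapsed to the best score by default (ties broken by position, then
smaller loop); recall on planted structures is measured on the uncollapsed
set, since collapsing can prefer an overlapping chimeric frame. Second, the
mirrored-hit symmetry under reverse complement is exact only with wobble
pairing disabled: a G.T pair maps to A.C under
complement-and-swap, which no longer pairs. This is a property of the
pairing rules, not of the implementation; the symmetry test therefore runs
with `allow_wobble = FALSE`.

`scan_region()` resolves named regions against the annotation: `"WANCY"`
(tRNA-Trp through tRNA-Tyr — the canonical O_L location, where a scan may
legitimately return zero hits) and `"CR_flank"` (the CR plus a 100 bp margin
on both sides, wrapping across the circular origin, because the published
description places the second element "within the CR and very close to
tRNA-Phe" without fixing which side of the junction it touches).

## The simulator and what a green test establishes

`simulate_tdrl()` draws an interval and a survivor bipartition (each gene
surviving in copy 1 with probability 0.5) on a 13-gene window — the stated
world of the motivating analysis, tRNA-Phe through tRNA-Asn — and bookkeeps
ground-truth remnant sites by nearest-survivor search over the explicit
two-copy layout, independently of the inference code.
`generate_annotation()` lays gene coordinates out with remnant spacers of
20-150 bp (bracketing the observed 31-117 bp gaps) and background gaps of
0-5 bp; `generate_sequence()` adds IID background bases (optionally
AT-biased, as fish mitogenomes are) with perfect planted inverted repeats.
Single-gene intervals are rejected (they cannot rearrange anything), and
identical seed plus config gives bit-identical output.

The generator emulates the *combinatorial* consequences of TDRL, not
sequence evolution: remnants are anonymous gaps of the configured length,
not decaying pseudogene sequence; background gaps are IID; planted hairpins
are perfect repeats in random context. A green recovery test therefore
establishes that inference inverts the forward model and that the scanner
finds what the pairing rules define — not that real spacers retain
detectable homology, which is an empirical question about decay rates.

## Design choices on open points

* The permutation window excludes the CR (the published numbering starts at
  tRNA-Phe = 1, with the CR as boundary label); windows crossing the
  linearization anchor are rejected rather than silently unwrapped, since
  the analysis region never crosses it.
* Strand inversions relative to the reference are detected and make a window
  ineligible for TDRL analysis — a tandem duplication preserves strands, and
  inversion-containing rearrangements (as in *Cynoglossus*) need a different
  model.
* If the displaced interval has one descent but genes outside it are also
  displaced, inference fails rather than widening the interval
  heuristically.
* The second gene cluster of the published numbering extends beyond the
  inferred duplication (ranks 10-13 never move); the encoder keeps the full
  window and lets the interval localization decide, which reproduces the
  published "at least V..M" bound.

## Limitations

Single-event inference only (multi-step histories get a lower bound);
no inversions or duplicated control regions in the analysis window;
GenBank parsing covers the common mitogenome feature table, not the full
flat-file grammar; the hairpin scanner is combinatorial and will rank some
thermodynamically implausible stems above plausible ones.
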