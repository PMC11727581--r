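---
title: "Calling retrotransposition events from alignment nets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling retrotransposition events from alignment nets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retronet)
```

## The signal being detected

LINE-1 retrotransposition copies a transcript back into the genome by
target-primed reverse transcription (TPRT).  The ORF2 endonuclease nicks the
target (consensus `TTAAAA`), the transcript's poly(A) tail primes reverse
transcription, and second-strand cleavage a short distance away duplicates
the target sequence.  Every such event therefore leaves two scars on the
reference genome:

* a **target-site duplication (TSD)** — the same 7–20 bp sequence repeated
  immediately on both sides of the insertion, and
* a **poly(A) run** at the insertion's 3′ end (appearing as poly(T)
  5′-ward on the reference when the element inserted on the minus strand).

In a UCSC *net* file — the hierarchical summary of a pairwise whole-genome
alignment — a retrotransposed copy shows up as a characteristic topology: the
inserted sequence is present in the reference but absent from the query at
that locus (a `gap`), yet inside that gap the element body aligns back to its
source locus elsewhere in the query (a nested, deeper-level `fill`).  The
caller therefore visits every gap-enclosed fill, looks for the TSD pair and
the adjacent tail, scores them, and filters.

The same machinery works in *self* mode (a genome netted against itself,
finding intra-genomic copies) and in *cross* mode (netted against another
species); only the input net differs.

## Detection procedure

For each (gap, fill) pair, with fill reference interval $[s, e)$:

1. **Flank extension.** The left flank spans
   $[s - \mathrm{extendOut},\, s + \mathrm{extendIn})$ and the right flank
   $[e - \mathrm{extendIn},\, e + \mathrm{extendOut})$, clamped at chromosome
   edges.  Defaults are 30 nt each way: the outward reach must exceed the
   longest TSDs observed in practice (about 18 nt) with margin, and the
   inward reach covers tails partially absorbed by the alignment.
2. **TSD search.** The best *ungapped* local alignment between a left-flank
   substring and a right-flank substring is found by a banded scan over all
   diagonals (implemented in C++), under unit scoring
   ($\mathrm{score} = \mathrm{matches} - \mathrm{mismatches}$), a minimum
   aligned length (default 7), an edit budget (default 1 substitution), and
   positional anchoring of each copy to its fill edge.  Allowing indels
   inside a 7–20 bp duplication was judged not worth the ambiguity it
   introduces: TSD copies are created literally identical, point
   substitutions dominate their subsequent divergence, and an ungapped
   optimum has a clean exhaustive-enumeration oracle.  The `indels` field is
   carried (always 0) so the scoring identity
   `matches − mismatches − indels` remains explicit.
3. **Poly(A) search.** Within `extendIn` bases element-side of the 3′-TSD's
   inner edge, the longest A-dominated run is taken whose 3′ end lies within
   `polyAMaxGapFromTsd` (default 5) bases of that edge, with at most one
   internal non-A (terminal positions must be A, so interruptions cannot pad
   the run), and at least 5 bases long.
4. **Minus strand.** The extended region is reverse complemented and steps
   2–3 repeated; coordinates map back through the mirror.  The orientation
   with the higher total score wins; exact ties go to `+`.
5. **Scoring and filtering.** `totalScore = tsdScore + polyAScore`, additive
   and unit-per-base, with no length normalisation — the simplest scheme
   consistent with the published score range (typical calls score in the
   20–30 band: TSDs of 7–18 plus tails of 6–13).  A candidate passes when
   TSD ≥ 7, poly(A) ≥ 5 and `totalScore ≥ minScore` (default 12, exactly the
   floor implied by the two length filters, kept as an independent knob).

Determinism is part of the contract: all tie-breaks are specified (higher
score, longer alignment, fewer mismatches, left copy closest to the fill
edge, then leftmost coordinates), so identical inputs give byte-identical
candidate tables.

The insertion interval reported for a candidate runs from the inner edge of
the 5′ TSD copy to the inner edge of the 3′ copy, 0-based half-open —
i.e. the inserted material between the duplicated targets.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `min_tsd_len` | 7 nt | minimum aligned TSD length retained |
| `min_polya_len` | 5 nt | minimum poly(A) run length retained |
| `extend_out` / `extend_in` | 30 nt | flank reach beyond / into the fill |
| `max_tsd_mismatches` | 1 | substitution budget inside the TSD alignment |
| `max_polya_interruptions` | 1 | internal non-A bases tolerated in the run |
| `polya_max_gap` | 5 nt | max distance from run 3′ end to the 3′-TSD |
| `min_score` | 12 | total-score floor |

## Net input and output

No pre-installed package parses the UCSC net grammar, so `parse_net()` /
`write_net()` implement it directly: `net <chrom> <size>` headers, indented
`fill`/`gap` lines with six positional coordinate fields, free attribute
pairs kept verbatim and uninterpreted (so both raw chainNet output and
annotated net dialects pass through untouched; `type` is just another
attribute).  One leading space encodes one nesting step; tabs are accepted
on input but never written, which makes write∘parse the identity and gives
the test suite a byte-level round-trip oracle.  Structural invariants —
children inside their parent's reference interval, strict fill/gap
alternation, node ends within the chromosome size — are enforced at parse
time with line numbers in the error.

Reference coordinates are 0-based half-open on the + strand throughout;
query coordinates are on the strand named in the record, as in the
consumed format's own documentation.

## The insertion simulator

`simulate_retro()` reproduces the validation protocol end to end without an
external aligner:

1. a random i.i.d. genome (`chrSim`) is drawn — benchmark scale is 60 Mb,
   the desk default 5 Mb, which preserves all per-insertion statistics;
2. one parental copy of the element (bundled synthetic ~1 kb sequence; any
   FASTA sequence can be substituted) is planted — the source locus the
   emulated net points back at;
3. true insertions are built as `TSD · oriented(element + A^p) · TSD` with
   TSD length uniform on 7–20, tail length uniform on 5–20, random strand,
   and random-base TSDs; controls are the bare element with neither feature;
   insertion points are uniform with a guaranteed 1 kb minimum spacing
   (avoiding compound events, which are deliberately out of scope);
4. the net a pairwise aligner would produce is emulated directly: a level-1
   backbone fill, one gap per inserted block, and inside it a level-2 fill
   covering the element body (TSDs and tail outside the fill, as in real
   TPRT alignments), each fill edge independently jittered by up to
   `boundary_jitter` nt (default 3) to stand in for alignment-boundary fuzz.

Evaluation declares a true insertion recovered when a filter-passing
candidate overlaps its interval within 20 nt (the matching rule is not
dictated by the protocol, so it is explicit and configurable); specificity
is the fraction of controls yielding no passing candidate.  For the ROC,
each truth locus is assigned the best `totalScore` over all emitted
candidates — `minScore` is the swept threshold, so it is not applied
beforehand — and the AUC is computed by the trapezoidal rule, which is
checked against the Mann–Whitney rank formulation (to $10^{-9}$) and
against `pROC` in the tests.

What the emulation does *not* model: alignment failure or mis-chaining of
whole elements, 5′ truncation, twin priming, transductions, nested
insertions, and repeat-induced ambiguity.  Benchmarks on emulated nets
therefore bound what a real lastz→chainNet product would give; they validate
the caller's logic, not the upstream aligner.

### What the benchmark shows

At the desk scale (5 Mb, 200 + 200, jitter ±3, five seeds) the acceptance
script measures sensitivity ≈ 0.94–0.95 and specificity ≈ 1.00.  The misses
are informative rather than accidental: occasionally the *highest-scoring*
TSD alignment extends its start-side columns into the poly(A) tail (each
extra aligned A adds +1, and the substitution budget plus the longer-length
tie-break allow hopping one non-A base), which drags the 3′-TSD's inner
edge into the tail; when the remaining run drops below the 5-base floor the
locus yields no candidate.  The effect is independent of boundary jitter.
Short tails are hit hardest, which is why recall sits a few percent below 1
rather than at it — consistent with the recall reported for the original
aligner-based protocol.

## Genomic categories and motif scanning

Candidates are intersected (1 bp suffices) with user-supplied BED interval
sets, one file per category, and assigned the highest-priority overlapping
category, defaulting to `repeat > CDS > UTR > exon > intron > promoter`,
with `intergenic` for no overlap.  The priority order is a package decision
— overlap resolution is not specified anywhere upstream — and repeats-first
matches the repeat-dominant accounting of real catalogues.  Consuming plain
BED rather than a specific gene-annotation release keeps the module
independent of annotation churn.

`scan_motif()` scans ±20 nt (configurable) around each candidate's 5′
insertion edge, on the candidate's strand, for the L1 endonuclease
consensus `TTAAAA`: exact occurrences and "similar" ones at Hamming
distance ≤ 1 (the smallest well-defined neighbourhood; "similar" has no
standard definition).  The reported offset is signed from the motif's 3′
end to the edge, negative upstream; the occurrence closest to the edge wins,
ties resolving upstream.  Note the edge is the *inner* TSD boundary, so a
motif planted at distance $d$ upstream of an inserted block appears at
offset $-(d + \mathrm{tsdLen})$.

## Expression: RPM, expressed-copy filter, Tau

Counts are normalised to reads per million of the library
(`count / librarySize × 10⁶`); downstream log transforms use
$\log_2(\mathrm{RPM} + 1)$.  The pseudocount of 1 is a package choice (the
transform needs one and none is prescribed); it maps zero counts to zero on
the log scale, which is what the Tau formula expects.

A copy counts as *expressed* when strictly more than 20 reads are seen in
at least two samples — both inequalities taken literally as worded.

Tissue specificity uses the Tau index on per-tissue values
$x_1, \dots, x_n$ (log scale):

$$\tau = \frac{\sum_{i=1}^{n} (1 - x_i / \max_j x_j)}{n - 1}$$

$\tau = 0$ for a constant positive profile, $\tau = 1$ for a single-tissue
profile, invariant to positive rescaling, undefined (reported `NA`) for an
all-zero profile.  Per-tissue values are the *means* of sample-level
$\log_2(\mathrm{RPM}+1)$ within each tissue — means rather than maxima
because cell-line samples within a tissue are exchangeable replicates and a
max would reward single outlier samples.  Features with $\tau > 0.8$
(strict) are labelled tissue specific; peak-tissue ties go to the
lexicographically first tissue name.

## Numerical and degenerate-input choices

* Flanks and scan windows clamp at chromosome edges; a fill on an unknown
  chromosome is an error, a candidate chromosome absent from an annotation
  is simply intergenic.
* Emulated fill edges jittered outside their gap are clamped back in.
* Zero-length genomes, zero library sizes and truth tables without positive
  instances are rejected with explicit errors.
* All simulator randomness flows from one seed; every operation is
  deterministic given its inputs.

## Problem sizes used by the tests

The packaged checks run the benchmark at 5 Mb with 200 true + 200 control
insertions (single seed in the test suite, five seeds in
`scripts/acceptance.R`), property checks on hundreds of randomized flank
pairs up to 60 nt against an exhaustive oracle, and smaller simulations
(0.2–0.6 Mb) for structural and strand-symmetry properties.  These sizes
keep the full suite under a couple of minutes while leaving every
per-insertion statistic at benchmark values; the 60 Mb / 1000 + 1000
configuration runs unchanged through the same functions for users who want
the full-scale protocol.

## Known limitations

* Emulated nets idealise the aligner: real chainNet output can split, trim
  or drop element alignments in ways jitter does not capture, so sensitivity
  on real nets depends on the upstream alignment quality.
* The caller reports at most one candidate per gap-enclosed fill — the best
  orientation of the best TSD/tail pair — and does not model composite or
  nested events.
* TSD matching is ungapped by design; a TSD that has acquired an indel since
  insertion will be reported shorter or missed.
* Homology tracing of parental genes, repeat-family classification of the
  element body, and de novo motif discovery are out of scope; the package
  consumes their outputs (BED intervals) instead.
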