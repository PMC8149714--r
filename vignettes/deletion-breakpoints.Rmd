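---
title: "Characterizing deletion breakpoints and their repair-mechanism signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing deletion breakpoints and their repair-mechanism signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deljunct)
```

## The problem

When a bacterium repairs a chromosomal double-strand break (DSB) without its
main recombinase RecA, the repair can fuse two distant sites and delete
everything between them. The fused junction retains a molecular fingerprint
of the pathway that made it: the length of the exact sequence homology
(microhomology) shared by the two breakpoint flanks, and whether the junction
is otherwise unchanged.

* **SSA** (single-strand annealing) anneals long direct repeats, typically
  more than 25 bp, and leaves a precise junction with one surviving repeat
  copy.
* **A-EJ / MMEJ** (alternative or microhomology-mediated end-joining) uses
  short microhomologies of 2–20 bp, also leaving a precise junction.
* **NHEJ** (non-homologous end-joining) needs at most 0–4 bp of homology and
  frequently adds or loses bases at the junction.

`deljunct` implements the downstream half of a rearrangement study on such
genomes: given a reference assembly and a rearranged assembly (or a table of
deletion coordinates), it locates large deletions, characterizes the repeat
at each breakpoint, re-enacts the deletion in silico, verifies the predicted
junction in the rearranged assembly, classifies the compatible repair
mechanism, and computes the supporting genome statistics. A synthetic-genome
simulator with exactly known truth stands in for real long-read assemblies,
so every stage is testable offline. The motivating system is *Deinococcus
radiodurans*, whose *recA* mutants recurrently delete a region of
chromosome II between short (4–11 bp) direct repeats.

## Coordinates and the repeat-anchored convention

Internally every interval is 0-based and half-open, `[start, end)`; all
printed coordinates are 1-based, GenBank style. Published deletion tables
for this system anchor both coordinates at the *beginning of the repeat
copy*: `start` is where the left repeat begins, `end` is where the right
repeat begins. The excised segment is therefore `[start-1, end-1)` in
internal coordinates, the deleted length is exactly `end - start` as
printed, and one repeat copy survives at the junction. The bundled table of
five *recA* isolates follows this convention; where a published length
column disagrees with `end - start` (it does for four of the five rows) the
reader warns and reports both numbers rather than silently reconciling —
the published-versus-computed discrepancy is itself a finding worth
surfacing. Similarly, the region deleted in all five isolates is reported
from the table as 187,421–222,947 while the study's prose gives
187,425–222,947; the package reports the table-derived value and leaves the
four-base difference visible.

## Canonical placement and microhomology

A deletion between two repeat copies is ambiguous: sliding the excised
window by one base inside the repeat produces the same derived sequence.
`characterize_breakpoint()` normalizes to the **leftmost** placement (the
standard indel normalization), sliding left while the base before the start
equals the base before the end. The microhomology is then the maximal exact
common prefix of the two suffixes at the canonical bounds; maximality is
guaranteed because sliding has stopped on the left and the prefix comparison
stops at the first mismatch on the right. The full `slide_window` is
reported so nothing about the ambiguity is hidden. `N` bases never match
anything — including another `N` — so assembly gaps cannot inflate a
microhomology.

```{r}
el <- genome_element("toy", "TTACGTCCCCACGTGG")
characterize_breakpoint(el, 2L, 10L)
```

Re-enactment excises `[start, end)`; `reconstruct_junction()` returns the
repeat with 60 bp of flank on either side (the span used when confirming
junctions by alignment; configurable), and `verify_junction()` requires
exactly one exact, overlap-aware occurrence in the derived assembly.
The closure `verify(reenact(ref, call), reconstruct(ref, call))
== "verified"` holds for every call on every genome and is enforced by the
test suite.

## Mechanism classification

`classify_mechanism()` is a pure rule table over `(mh_length,
junction_exact, inserted_bases)`: any inserted bases or inexact junction is
NHEJ-like; an exact junction is SSA-compatible at ≥ 25 bp, A-EJ-compatible
at 2–20 bp, and **ambiguous** at 21–24 bp — the two published thresholds
(20 and 25) leave a gap, and forcing that band into either class would
manufacture certainty the features do not carry. Exact junctions with 0–1 bp
homology are unclassified. The classification is deliberately
"-compatible": a 4 bp microhomology does not prove A-EJ, it is merely
consistent with it, which is how the output should be read.

## Deletion calling

`call_deletions()` compares two assemblies by unique k-mer anchors: k-mers
occurring exactly once in each sequence, matched by content (default
k = 31 bp, long enough that anchors in a random megabase-scale genome are
effectively guaranteed unique and short repeat families cause no
confusion). The longest strictly collinear anchor chain is selected
(O(n log n), with a deterministic leftmost tie-break and a warning if
several maximal chains exist); each chain gap where the reference advances
at least `min_len` (default 1,000 bp) more than the derived sequence is
refined by exact outward extension from the bounding anchors, and the
leftmost consistent junction is emitted. Gaps where the derived sequence
advances more are insertions and are skipped. Every emitted call is checked
on the spot: excising it from the reference must reproduce the derived
sequence around the junction. Only forward-strand collinear comparison is
implemented; inversions and translocations are out of scope, as is SNP and
small-indel calling (`min_len` exists precisely to leave those to other
tools).

## Repeat-pair coverage

`repeat_coverage()` asks: at repeat length L, what fraction of genomic
positions lies inside at least one L-bp window whose sequence occurs at two
or more start positions in the pooled genome? Windows are encoded as
integers (two packed halves above L = 26), so the statistic runs in seconds
on a 3.3 Mb genome; windows containing `N` are excluded from numerator and
denominator; circular elements contribute wrap-around windows. The default
counts direct repeats only. With `include_revcomp = TRUE` occurrences of a
window's reverse complement count toward its multiplicity, which is the
behaviour of repeat finders that detect both direct and inverted pairs —
the convention used when reproducing the published "100% coverage at 11 bp"
regime, since the tool behind that number reports both orientations. On the
emulation profile (four replicons of 2,648,638 / 412,348 / 177,466 / 45,704
bp, iid bases at GC 0.67) both-strand coverage at L = 11 is ≈ 99.9%,
rounding to 100%; direct-only coverage is ≈ 99.3%. The iid profile slightly
understates a real genome, which carries IS elements and other repeat
families on top of its compositional background.

## Codon-usage and composition statistics

`gc_percent()` excludes `N` from the denominator. `gc3s()` measures GC at
third positions of the eight fourfold-degenerate codon boxes of the
bacterial genetic code (GCN, CGN, GGN, CTN, CCN, TCN, ACN, GTN; the
Ser/Leu/Arg sextets contribute only their quartet boxes). `scuo()` computes
synonymous codon usage order, the entropy-based bias statistic: for each
amino acid with degeneracy `n ≥ 2` present in the gene, the normalized
entropy deficit `(log2 n − H)/log2 n` is weighted by the amino acid's share
of counted codons. It is 0 at uniform synonymous usage, 1 when each amino
acid uses a single codon; Met, Trp and stops are excluded, log base cancels.
These are closed-form limits asserted in the tests. `region_report()`
aggregates GC over a region and median SCUO / pooled GC3s / COG class
histogram over the genes fully contained in it (lower median, so the value
is always an observed gene's value and even-count medians are
deterministic); genes overlapping the boundary are listed separately rather
than silently dropped, since published gene tables for the commonly deleted
region include one such boundary gene.

The published composition values for the real chromosome II (66.7% GC
whole-replicon, 67.4% in the deleted region, GC3 88%/91%, SCUO medians
0.3543/0.3831) require the deposited assembly, which is not bundled; the
statistics are exercised on synthetic replicons where composition is known
by construction. The SCUO medians additionally depend on an unspecified
variant choice in the original analysis software, so they are a qualitative
surface only.

## Terminus analysis

With a known origin (an input; position 1 for the chromosome II studied
here) and the assumption of replichore balance, `predict_terminus()` places
the terminus antipodally: `((ori − 1 + ⌊len/2⌋) mod len) + 1`, giving
206,175 ≈ 206,000 for a 412,348 bp replicon. `common_region()` intersects
deletion intervals and `spans_terminus()` flags whether each deletion
removes the terminus — all five bundled isolate deletions do, and their
intersection is the 35 kb region (`⌊35,526/1000⌋`).

## The simulator

`simulate_dataset()` generates replicons (iid or first-order Markov bases
at a configurable GC; defaults emulate the 3.28 Mb, 67% GC profile above)
and plants events with exact truth. For A-EJ/SSA an exact repeat of the
requested length is written at two sites the deletion length apart; the
four flanking bases are then resampled so the repeat extends in neither
direction and cannot slide left — parameter-recovery tests are therefore
exact, not probabilistic (500 planted A-EJ events recover length and
canonical coordinates in 500/500 cases). NHEJ events get exactly the
requested junction agreement plus an optional inserted or additionally lost
base count. All randomness flows from one stream per seed, consumed in a
fixed order (elements first, then events in list order), so
`reference.fasta`, `derived.fasta` and `truth.json` are reproducible.
What the simulator does *not* emulate: real repeat families (IS elements,
SRE/SNR repeats), SNPs between strains, assembly errors, and read-level
artifacts — so passing tests demonstrate algorithmic correctness on clean
assemblies, not robustness to misassembly.

## Numerical and design choices

* Anchor k = 31 default; k = 21 is used in some tests for speed (both far
  above the uniqueness threshold for the genome sizes involved).
* Chain tie-break: earliest-ending maximal chain, with a warning when a tie
  existed.
* `min_len` = 1,000 bp default: the experimental preselection behind the
  motivating study only detects events of tens of kilobases, and smaller
  indels belong to SNP callers.
* Degenerate zero-length deletion intervals are accepted and flagged, not
  errored, so published tables with placeholder rows survive ingest.
* Problem sizes in the test suite (genomes of 0.1–0.5 Mb for caller
  round-trips, 2 kb strings for brute-force oracle equivalence, one
  full-scale 3.28 Mb coverage run) were chosen so the whole suite completes
  in about a minute while still exercising every code path at
  biologically relevant scales.

## Limitations

Only collinear, forward-strand deletion detection; no inversion,
translocation, duplication or insertion characterization. Microhomology is
the forward maximal exact repeat after leftmost normalization — degenerate
(inexact) longer repeats are deliberately not scored, because the
re-enactment/verification closure already distinguishes exact-repeat
junctions from inexact alternatives. COG classes are inputs, not predictions.
The origin of replication is an input, not inferred from skew.
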