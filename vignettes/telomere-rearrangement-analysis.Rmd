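---
title: "Calling telomere and subtelomere rearrangements in budding yeast assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling telomere and subtelomere rearrangements in budding yeast assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telorearr)
```

## The problem

Chromosome ends in *Saccharomyces cerevisiae* consist of ~350 bp of
degenerate TG~1–3~ telomere repeats preceded by telomere-associated
sequences: an X element at essentially every extremity and, at a subset of
ends, 0–6 tandem Y′ elements in two size families (short ~5.2 kb, long
~6.7 kb) separated by short interstitial telomeric tracts. When telomere
capping fails, recombination reshuffles exactly this compartment: Y′
elements are lost, gained, tandem-amplified or recombined into new mosaic
variants; chromosome arms acquire BIR-like terminal duplications through
regions of shared homology; telomeres can be massively elongated by
rolling-circle copying of extrachromosomal telomeric circles (t-circles),
which leaves perfect tandem repeat arrays whose phase betrays a circular
template.

`telorearr` implements the computational side of that analysis for
telomere-to-telomere assemblies: per-extremity annotation, a Y′ variant
catalog, control-versus-survivor rearrangement calls, t-circle signature
detection, and telomere length distributions from assemblies or long reads.
Because real survivor genomes are large external data sets, the package
ships a first-class synthetic-genome generator with a planted-truth ledger:
every analysis stage can be validated against a genome whose rearrangements
are known exactly.

## Coordinate conventions

All per-extremity work happens in a canonical frame: the G-rich strand read
5′→3′ toward the chromosome end, so the telomere always sits at the right
edge. Left extremities are reverse-complemented into this frame; only I/O
(`write_annotations()`) maps intervals back to original chromosome
coordinates. Coordinates are 0-based half-open throughout (BED convention).
`N` bases never match in any alignment or exact-match operation.

## Annotation

**Telomere tracts.** The detector slides a 20 bp window (step 1) along the
canonical sequence and scores each window by the fraction of its 6-mers
that the TG~1–3~ grammar can generate (a "telomericity" score). Windows
scoring ≥ 0.8 are kept, gaps up to 10 bp are bridged, and the maximal run
reaching the sequence end is the tract (minimum 40 bp). The explicit 6-mer
dictionary makes the criterion testable; on planted tracts the measured
length is within a few bases (the window may start ≤ 3 bp before the true
tract when the junction base pairs happen to extend a valid 6-mer).

**Y′ elements.** Each library variant is matched against the extremity by
seeded maximal exact matches (21-mers) chained into local-alignment blocks;
blocks longer than 200 bp are kept, their union is taken, and the union is
split into instances wherever the gap between blocks contains an
interstitial telomeric seed (a 30 bp window of telomericity ≥ 0.8). The
containment split is deliberately window-based rather than whole-gap-based:
a heavily diverged instance has ragged block edges, and the non-telomeric
margins around a seed would otherwise mask it and merge two instances.
Instances are indexed centromere→telomere.

**X elements.** Best chained match of the X reference; a call requires 60%
of the reference length.

**Resolution status.** An extremity with more than 5 Y′ copies, two of
which are adjacent with the same label, is flagged `undetermined` and
excluded from all comparison denominators.

## The Y′ catalog

Detected Y′ sequences are homopolymer-condensed (every run longer than 4
collapsed to 4) to neutralize the dominant nanopore error mode. Pairwise
similarity is

\[ \mathrm{sim} = \%\mathrm{identity} \times
   \frac{\mathrm{alignment\ length}}{\mathrm{alignment\ span}}, \]

with %identity = matches / alignment columns and the span equal to the
alignment length plus the unaligned flanks of *both* sequences (this makes
the measure symmetric and penalizes length differences; the spanning
definition was chosen over per-sequence flanks for exactly that symmetry).
Alignments are seed-and-extend: maximal exact matches chained colinearly
with affine-gap global alignment of the small divergent gaps, the same
strategy BLAST-tier tools use; pairs small enough for full local dynamic
programming take that route instead, and the two routes agree to < 0.01 on
substitution-level divergence.

Two or more elements share a **label** when sim > 99.9. Because that
relation is not transitive, labels are connected components of the
above-threshold graph; components whose internal minimum falls below the
threshold are flagged `fragile`. Variant representatives (longest member)
are clustered by average linkage on `100 − sim`. The number of clusters is
the silhouette argmax over k (ties to the smaller k). We also compute the
discrete-curvature "elbow" of the silhouette profile and report it
(`elbow_k`), but do not use it for the choice: on the real profile the
curvature maximum locks onto an early bump created by the family-merge
dips, whereas the planted subfamily structure sits at the global silhouette
maximum.

## Rearrangement calls

Per extremity, the control and survivor label strings are aligned with
matches free, indels costing 1, and substitution disallowed (an LCS
alignment). Unmatched control labels are **losses**, unmatched survivor
labels **gains**; a replaced label therefore produces one loss plus one
gain through the indel path. We deliberately do not allow substitution
columns: with a unit mismatch cost the aligner pairs unrelated labels at
shifted positions and reports phantom loss/gain pairs. A gained label equal
to an adjacent survivor label is additionally a **tandem amplification**; a
gained label absent from the control catalog is a **new variant**.
Classification is non-exclusive (a tandem amplification is also a gain),
mirroring how per-kind counts and per-extremity maps are reported at
different granularity.

New variants are tested as **mosaics**: all maximal perfect matches > 50 bp
against the catalog (both orientations) are enumerated; the variant is
mosaic if their union covers it completely (with at least two distinct
donors, or one donor in rearranged order). The reported decomposition is
greedy longest-first, but the mosaic decision uses the exact union cover,
so the greedy choice can never turn a covered sequence into "unexplained".

**Terminal duplications** are screened by comparing the 15 kb upstream of
the X element against the control. On deviation, the divergence point is
located via the centromere-proximal exact match between the survivor and
control frames (no fixed offset is assumed — the two canonical windows
start at different depths of the shared core whenever an event changed the
chromosome length), and the divergent tail is decomposed into a chain of
donor-arm segments. The junction homology is the distance the donor match
extends back into the shared recipient sequence — on error-free genomes
exactly the planted homology cassette length. Nested events fall out of the
same chain as two rows at one extremity. Extremities rewritten by a
terminal duplication (and circularized chromosomes) are excluded from Y′
diffing: their Y′ complement is the donor arm's and would otherwise flood
the tables with spurious losses and gains.

**Circularization** is called when both extremities of a chromosome lack a
terminal telomere tract and both terminal 15 kb segments map to the same
control chromosome; a single missing tract is reported as an anomaly, not
called.

**Statistics.** Group comparisons use two-sided tests without multiplicity
correction: exact Mann–Whitney for per-class alteration frequencies,
Student's t for fractions of altered extremities, Fisher's exact for
survivor-type counts; both rank tests are validated against full
enumeration oracles in the test suite. Degenerate groups yield NA rather
than errors.

## T-circle signatures

Telomere tracts are scanned for perfect tandem arrays with units ≥ 30 bp.
An array is anchored at the left edge of its maximal periodic region
(exactly one report per region and period), must not be extendable by a
full unit on either side, and its unit must be primitive. The production
scanner (run-length encoding of the period-L self-match vector, for every
L) is checked against an independent brute-force enumerator over random
tracts in the test suite.

Units below 50 bp are ignored for circle candidacy — the control's own
telomeres contain occasional short 2-copy repeats, and the generator's
telomerase emitter reproduces that background — and candidates need ≥ 3
copies. Near-identical units (circular-permutation-aware normalized score
> 0.98) merge into one circle represented by the most common unit (largest
total copy support; ties broken by length, then by the lexicographically
smallest rotation) and named `Circle_<unit length>`.

Matching slides a window of the unit length (step 1) across every telomere;
the doubled unit is aligned locally against the window (match 1, mismatch
−1, gap open −1, gap extend −0.9) and the normalized score is the raw score
over the unit length, so a perfect match scores exactly 1 and matches
require > 0.98. Exact rotations are recognized directly; alignments are
only attempted where the window shares a dense set of unit k-mers, because
the degenerate telomere background shares scattered k-mers with everything.
Contiguous matches merge into copy counts; the run phase is anchored on the
best-scoring window of the run because the alignment phase of an imperfect
boundary window can be off by a gap.

A circle found in more than one copy in any *other* assembly is discarded
as non-specific; exactly one copy in the control names the circle's locus
of origin. Containment between circles (the nested-excision signature) is
rotation-aware: the inner unit is scanned against the doubled outer unit.
Per clone we report the fraction of telomeric bp inside perfect arrays and
the extended fraction that adds single or imperfect unit occurrences at the
same 0.98 threshold.

## The synthetic study and its ledger

`build_reference_genome()` emits the control: 16 chromosomes; every
extremity is flank + X + (seed + Y′)* + telomere in the canonical frame.
Defaults are the study conditions: 34 Y′ instances over 20 of 32
extremities with 0–6 copies per end; a 20-variant library built from two
family ancestors via 10 subfamily founders (1.5% divergence, family-band
target lengths) plus one intermediate-size (5981 bp) truncation, with
variants at 0.15% divergence below their founders; interstitial seeds of
50–150 bp (the source strain's seed lengths are not reported; this range is
a calibrated choice); terminal tracts ~N(350, 50) bp from a TG~1–3~ emitter
(extra-G probability 0.5, runs capped at 3). Each variant carries a
deterministic 4-base stamp near its distal end so distinct variants always
differ within the terminal kilobase that read anchors are drawn from —
where variants differ is not otherwise constrained by the biology, only
*that* they differ. Homology cassettes (0.4–1 kb) are planted in selected
subtelomeric flanks as donors/recipients for BIR-like duplications, plus a
mating-type-like cassette on both chromosome III flanks for
circularization; cassette boundaries are forced to differ between the two
sites so the planted junction homology is exact.

`plant_rearrangements()` realizes typed events on a copy of the control and
extends the ledger. Event samplers draw per-clone counts from the observed
rearrangement load (losses ~N(8.3, 3.7), gains ~N(18, 8.9) split among
plain gains, tandem amplifications and new variants; 0–2 terminal
duplications). Samplers enforce non-aliasing: a label lost at an end is not
re-gained there, plain gains introduce labels new to the end, and tandem
amplifications and insertions occupy disjoint extremities. These
constraints are part of the study conditions — composed self-cancelling
edits are invisible in the emitted sequence, so no detector could recover
them and planted-truth recovery would be capped below 1 for reasons that
say nothing about the detector.

Type-II-like survivors keep 5 extremities at control length and elongate
the rest by up to ~9.5 kb, interleaving fresh telomerase-like emission with
rolling-circle arrays (3–9 copies, arbitrary phase) from a circle panel
excised from control telomeres (so origins are traceable), including one
longer unit containing a shorter one (the nested-excision signature). The
per-clone array budget targets ~27% of telomeric bp, inside the observed
13–32% band.

Read simulation places molecules uniformly (they may terminate at either
chromosome end, as real molecules do), draws log-normal lengths (median
15 kb, the scale of length-filtered nanopore runs), flips strands, and
applies substitutions plus ±1 homopolymer-length errors in runs ≥ 5 bp.
Replicate-assembly noise applies only the homopolymer mode — the regime
polished nanopore assemblies actually differ in, and exactly the regime
condensation neutralizes, which is what makes the post-condensation
similarity of homologous elements ≥ 99.98.

### What the generator does not emulate

Real assemblies carry residual consensus errors outside homopolymers,
X elements vary far more in structure (subcores, STR blocks) than the
mutated-ancestor model, Y′ divergence is not uniform along the element, and
intraclonal heterogeneity (different cells with different telomeres) is not
modelled — each extremity has a single underlying truth. Passing
planted-truth tests therefore demonstrates the correctness of the
algorithms under the stated error model, not robustness to every artifact
of real long-read assembly.

## Read-based telomere lengths

A unique ~1 kb anchor per extremity is taken immediately
centromere-proximal to the control tract. A read ending in telomeric
sequence is assigned to the anchor with the highest exactly-recovered base
count (minimum 90% of an 800 bp span); reads tied between anchors are
dropped, but a unique best match wins even when several anchors pass the
threshold — tandem Y′ ends share > 95% of their distal sequence, so a
drop-on-any-multiple-match rule would discard every read from every
Y′-bearing end. Reads whose terminal tract is shorter than 60% of the
extremity's maximum are flagged as molecules sheared inside the telomere
and excluded from summaries (`drop_truncated = TRUE`); this assumes one
underlying length per extremity and should be disabled for clones with
strong intraclonal length heterogeneity.

## Numerical choices and degenerate inputs

* Alignment scoring everywhere: match 1, mismatch −1, first gap base −1,
  further gap bases −0.9; `N` never matches.
* All thresholds live in `telo_config()` and must be strictly positive.
* Tandem arrays: left-anchored per maximal periodic region; primitive units
  only; N-containing units skipped.
* Empty inputs return empty tibbles (never errors) except where the
  operation is undefined: empty sequences in similarity, an empty circle
  unit, fewer than 2 sequences for a matrix, fewer than 3 variants for
  clustering.
* Tie-breaks are deterministic: label ids by smallest member, circle
  representatives by copy support, then length, then smallest rotation;
  silhouette ties to smaller k.
* All stochastic stages derive child seeds from one user seed and restore
  the caller's RNG state.

## Problem sizes

The bundled validation runs at desk scale: the 1.1 Mb, 16-chromosome
synthetic control (30 kb cores, 12 kb subtelomeric flanks), 20-clone
recovery cohorts, 30× read coverage, 200-tract scanner cross-checks and
100 telomerase-only null clones. These sizes were chosen so the whole suite
reruns in minutes while every planted feature class is still exercised at
the study's per-extremity scale.

## A worked example

```{r example, eval = FALSE}
library(telorearr)

ref <- build_reference_genome(seed = 1)
ref$ledger <- make_tcircle_panel(ref$ledger, seed = 1)
survivor <- plant_rearrangements(ref$ledger,
                                 sample_yas_events(ref$ledger, seed = 7),
                                 clone = "c1", seed = 7)

res <- run_pipeline(ref$genome, list(c1 = survivor$genome),
                    ref$ledger$library, ref$ledger$x_ancestor,
                    outdir = "telorearr-demo")
res$summaries
dplyr::count(res$events, kind)

# compare the calls with the planted truth
map <- ledger_label_map(res$control$catalog, ref$ledger)
score_against_ledger(res$clones$c1$calls, survivor$ledger, map)
```

## Known limitations

* Detection libraries must contain the elements being searched for; a Y′
  family absent from the reference library is invisible.
* Terminal-duplication junctions are resolved through exact matches; on
  noisy assemblies the homology length inherits the local error rate.
* The undetermined flag is a proxy for assembly-resolution ambiguity, not a
  re-implementation of manual curation.
* Circle origin tracing requires the origin telomere to be present and
  intact in the control assembly.
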