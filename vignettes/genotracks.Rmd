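---
title: "Methods: allele-origin classification, map tracks and marker anchoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-origin classification, map tracks and marker anchoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genotracks)
```

## The problem

In marker-assisted backcrossing, a donor chromosome segment is moved
into an elite genetic background, and the breeder wants to see — per
individual, per chromosome — which marker alleles came from which
parent. Because recombination is suppressed near centromeres, genetic
distance (cM) and physical distance (bp) disagree badly in exactly the
regions where linkage drag hides. `genotracks` therefore works on both
scales at once: it classifies allele origin per marker, draws the
classification on paired cM/bp tracks, and fills in physical positions
for markers that only have sequence (BLAST) evidence.

## Allele-origin classification

Calls are single symbols: homozygotes `A/C/G/T`, heterozygotes as the
six IUPAC two-base ambiguity codes `M/R/W/S/Y/K`, and one failed state.
Several missing spellings (`NA`, `-`, `f`, `N`, empty) are accepted on
input and unified into that one failed state; keeping three distinct
"unknown" flavours would force every downstream rule to make arbitrary
distinctions the data cannot support. On output the literal `NA` is
written.

`classify_marker()` compares the IOI call against the calls of 1–4
parents and returns a case code `x_y` (`x` = parents needed to detect
the case, `y` = case index), `MONOMORPHIC`, or `UNCLASSIFIED`. The
decision table is only defined on "clean" rows, so a total function
needs an explicit precedence; we use:

1. **failed** — any failed call (IOI or a supplied parent) gives `1_3`.
   A failed parent could alternatively reduce the effective parent
   count, but silently reinterpreting a 3-parent analysis as 2-parent
   per marker makes case codes incomparable across markers.
2. **heterozygous parent** — the lowest-index heterozygous parent gives
   `1_5`/`2_6`/`3_8`/`4_11`. The lowest-index rule mirrors the
   single-heterozygote rows of the taxonomy; when both P1 and P2 are
   heterozygous the result is `1_5` by this tie-break, which is also
   why the P1/P2-swap symmetry (`1_1↔1_2`, `1_5↔2_6`, `3_9↔3_10`,
   all else fixed) holds for all inputs *except* the both-het rows,
   which are fixed points.
3. **heterozygous IOI** — `1_4`.
4. **matching** — with all calls homozygous, let S be the set of parent
   indices carrying the IOI allele. S = all parents (with ≥ 2 parents)
   is `MONOMORPHIC`; S = {P1}, {P2}, {P3}, {P2,P3}, {P1,P3} give
   `1_1`, `1_2`, `3_7`, `3_9`, `3_10`. With a single genotyped parent a
   match is `1_1` and a mismatch is attributed to the ungenotyped
   second parent (`1_2`); monomorphism cannot be established from one
   parent, so `MONOMORPHIC` is unreachable there.

Match sets outside this list — e.g. S = {P1,P2} with three parents, the
pattern a donor-matching marker shows when the two original cross
parents share an allele — are `UNCLASSIFIED` in strict mode (the
default), which keeps the reachable canonical sets at exactly 5, 6, 10
and 11 cases for 1–4 parents:

```{r taxonomy}
vapply(1:4, function(k) length(enumerate_cases(k)), integer(1))
```

Users who need those extra patterns can set `strict = FALSE` and get
deterministic extension labels (`ext_P1P2`, `ext_none`, ...) instead.
Heterozygote identity is by symbol only: `M` in a parent triggers the
parent-heterozygous case regardless of which two bases it encodes,
because SNP-array data are effectively biallelic and the taxonomy
conditions only on heterozygosity, not on its composition.

`discriminate()` applies this per marker and per IOI. Results for
distinct IOIs are independent by construction — a multi-IOI run is
defined as the concatenation of single-IOI runs — and failed (`1_3`)
plus monomorphic markers are flagged `filtered` by default rather than
dropped, so reporting can still count them.

## Input format

The genotype table is tab-delimited with a header and at least nine
columns: chromosome, marker, genetic position (cM), physical position
(bp; alternatively a second genetic map — a per-table flag `col4`
declares which, since the file itself cannot), LOD, parents P1–P4
(roles are positional, columns 6–9; a fully missing column is an
absent parent), then further accessions. Thousands separators in
positions are stripped. Genetic positions are cM floats; physical
positions 1-based bp. Capacity is capped at 500 samples and 50,000
markers at load time. The LOD column is parsed and carried but
consumed by no operation. `write_genotype_table()` inverts the reader
exactly (tested as a record-level round trip).

## Map tracks and layout

`build_tracks()` splits one chromosome's markers into a genetic track
(exactly the markers with a cM position) and a physical track (exactly
those with a bp position); either may be absent. Extent defaults to
the maximum observed position — no external genome table is required —
with an optional chromosome-lengths file as override. `to_canvas()` is
a strictly increasing linear map: cM × zoom, or bp / divisor × zoom.
Parameters, with defaults:

* `zoom` — dimensionless enlargement, capped at 10 in default mode and
  30 in single-chromosome mode (the two display modes differ in how
  much fits on a canvas).
* `physical_divisor` — bp per canvas unit (default 1e6, i.e. 1 Mb per
  unit at zoom 1), so a ~600 Mb chromosome and a ~150 cM map have
  comparable extents.
* `spacing` — canvas distance between the paired tracks (default 60).

Changing the divisor rescales only physical coordinates; genetic
coordinates are bit-identical (tested).

## Interval colouring

Marker-based colouring draws one tick per assignment. Interval-based
colouring colours the span between adjacent markers *only when both
carry the same case code*; between discordant markers the
recombination point is unknown, so the interval stays uncoloured.
Maximal equal-code runs merge into single segments. When two
assignments share one coordinate with different codes (common with
consensus-map positions), no interval passes through that coordinate
and the collision is recorded on the result (plus an R warning) —
filtering to the case of interest is the practical workaround.

Figures are composed as a vector scene (rectangles, lines, text) that
is serialised either to SVG by the package's own writer — fixed number
formatting (`%.2f`), fixed line separator, binary connection — or
rasterised to PNG through the same scene via the cairo PNG device.
Writing the SVG directly is what makes the determinism guarantee
testable: identical inputs produce byte-identical files. The default
palette assigns one fixed colour per status and can be overridden per
code; the legend carries the taxonomy's case descriptions.

## Anchoring markers by BLAST hits

`assign_physical_positions()` consumes precomputed 12-column tabular
BLAST output (running BLAST is out of scope; for regenerating hit
tables the conventional BLASTn defaults are: expectation 10, word size
28, match/mismatch +1/−2, linear gap costs, low-complexity filtering
on). The cascade per marker:

1. no hits → `NO_HIT`;
2. hits on one chromosome → candidate chromosome;
3. hits on several chromosomes → restrict to the consensus-map
   chromosome if it is among them, else `DISCARDED_NO_CONSENSUS`;
4. if two hits on the candidate chromosome lie more than `max_span`
   (default 1,000,000 bp) apart → `DISCARDED_SPAN`; the span screen
   applies to single-chromosome and consensus-resolved markers alike;
5. otherwise anchored at the best hit's smaller subject coordinate,
   best = highest bitscore, then lowest e-value, then lowest subject
   start — a fully deterministic tie-break.

Span is measured between normalised hit start positions (reverse-strand
hits are flipped to min/max at parse time); "more than" is strict, so a
span of exactly `max_span` passes. Raising `max_span` can only move
markers out of `DISCARDED_SPAN`, never into it (tested). The cascade is
verified against an independent brute-force re-implementation on
randomized hit tables (50 markers × ≤10 hits × 20 seeds).

## The simulator

`simulate_cross()` generates the study conditions every other module is
tested under: a configurable crossing scheme (DH/F2 biparental, BCFx
backcross, NIL with donor P1, cross parent P2 and recurrent parent P3),
14 chromosomes × 200 markers by default (a tetraploid wheat-sized
complement at 15K-array marker density), 150 cM / 600 Mb chromosomes,
90 % polymorphic markers, and planted donor blocks (default: a large
target introgression on chromosome 1 and a smaller linkage-drag
fragment on chromosome 3). Genetic positions are a monotone
piecewise-linear function of physical positions with a flattened
centromeric third (relative recombination rates 2 : 0.2 : 2), so
fixtures visibly reproduce the cM-vs-bp distortion the tool exists to
show. Heterozygous and failed IOI calls are injected at configurable
rates (failed takes precedence), and the truth table records the exact
status classification must return — so tests assert equality, not
statistics. The simulator uses one private, explicitly seeded random
stream and leaves the session's RNG untouched.

One deliberate choice: in the NIL scheme the second cross parent P2
carries the recurrent-type allele at polymorphic markers. If P2 shared
the donor allele instead, donor-segment markers would show the
S = {P1,P2} pattern, which the strict taxonomy cannot name; giving P2
the recurrent-type allele keeps planted blocks classifiable as
canonical `1_1` against a `3_9` background.

What the simulator does *not* emulate: real meiosis (blocks are
planted, not sampled from a recombination model, and there is no
interference), genotyping-platform error structure (noise is uniform
across markers), segregation distortion, and multi-allelic markers.
Passing the recovery tests therefore shows the decision table and
interval logic are implemented exactly — not that real NIL data will
be as clean.

`simulate_blast_hits()` plants the five hit patterns the cascade must
distinguish (clean single-chromosome, consensus-resolvable,
consensus-less multi-chromosome, wide-span, no-hit) with the status
each must receive.

## Problem sizes and limits

The test suite works at 14 × 200 markers for recovery checks and
50-marker hit tables over 20 seeds for the anchoring oracle; these
sizes give full coverage of every code path while keeping the suite
fast. Capacity limits (500 samples / 50,000 markers / 10 IOIs per
figure) are enforced, not benchmarked. Known limitations: no
imputation of missing parents, no phasing or probabilistic origin
assignment, no nonlinear (Marey-style) interpolation between the two
maps — connectors are straight per-marker lines — and strict mode
deliberately refuses to name allele patterns outside the canonical
taxonomy.
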