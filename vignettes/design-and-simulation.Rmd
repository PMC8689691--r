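---
title: "Golden Gate design and in silico verification with mocloforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Golden Gate design and in silico verification with mocloforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocloforge)
```

## The problem

Modular cloning (MoClo) builds plasmids hierarchically with type-IIS
restriction enzymes: BsaI and BsmBI cut at a fixed offset *outside* their
recognition motif, so digestion leaves a programmable 4-nt 5′ overhang
("fusion site") and a correctly designed one-pot digestion–ligation
reaction converges on a single product that no longer contains the
enzyme's sites. Two design chores dominate day-to-day use of the yeast
MoClo standard, and both are error-prone by hand:

1. **Part domestication** — turning a raw sequence into a level-0 part
   means adding primer tails that install a BsmBI site plus the
   type-specific fusion sites, while checking for internal recognition
   sites that would break the assembly (BsaI, BsmBI, NotI) or legacy
   standard compatibility (BioBrick, BglBrick).
2. **Multiplexed gRNA arrays** — cloning 2–12 gRNA spacers into a single
   Csy4-separated transcript in one Golden Gate step requires splitting
   every intermediate spacer between two PCR fragments such that all
   junction overhangs are mutually compatible.

`mocloforge` implements both designers and couples them to an in silico
digestion/ligation simulator, so every emitted design is verified by
actually reconstructing the assembled plasmid, base by base.

## The array model

An *N*-spacer array is produced from *N − 1* PCR fragments amplified off
a single template consisting of the constant gRNA scaffold followed by a
separator (by default 28 nt, the length of a Csy4 recognition sequence).
Fragment *k* carries, in its primer tails, the right part of spacer *k*
and the left part of spacer *k + 1*; the first and last spacers travel
whole. After BsmBI digestion the fragment's overhangs are the junction
4-mers, so ligation regenerates every spacer seamlessly and the insert is

```
spacer_1 · (scaffold · separator · spacer_i)  for i = 2..N
```

with zero inserted or deleted bases. `verify_array()` checks exactly this
string identity on the simulated assembly; the tail layout itself is a
means to that end, and the round trip is the contract the tests enforce.

### Junction choice

A junction overhang for intermediate spacer *i* is a 4-nt window
`spacer_i[s, s+4)` with `1 ≤ s ≤ 15` (0-based), so at least one base
remains on each flank. Two overhangs *conflict* when they share at least
3 positionally matching nucleotides in either the forward or the
reverse-complement orientation (`ends_conflict()`); conflicting overhangs
cross-ligate and scramble assembly order. Each overhang must also differ
from its own reverse complement at the same threshold, which rejects
palindromic ends that self-ligate.

`find_junctions()` performs a depth-first greedy search with
chronological backtracking over the intermediate spacers in array order.
Candidates are ordered by `|s − 8|` (ties toward smaller `s`): offset 8
centres the 4-nt window in a 20-nt spacer, making "as close to the middle
as possible" a concrete metric. The worst case is exponential in the
number of spacers, but in practice designs for 12 spacers finish in
milliseconds. Failures are explicit: the error names the first spacer for
which no conflict-free window exists. The search is deterministic — the
same spec always yields the same design.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `conflict_threshold` | 3 | matching nucleotides that define a sticky-end conflict; raising it to 4 weakens the constraint and can only keep designs feasible |
| `spacer_len` | 20 nt | targeting portion of a gRNA; validated strictly |
| array size | 2–12 | tool's supported range, validated at spec construction |
| `flank`, `spacer_base` | `"AA"`, `"A"` | tail bases around the BsmBI recognition site; type-IIS enzymes need flanking bases to cut efficiently, and the single spacer base positions the cut so the overhang is exactly the fusion site/junction |
| `min_binding`, `max_binding` | 18–30 nt | binding-region lengths enumerated for domestication primers |
| `target_tm` | 60 °C | Wallace Tm the candidate ranking aims for |

Melting temperatures use the Wallace rule, `Tm = 2(A+T) + 4(G+C)`,
computed on the binding region only. This is a ranking heuristic, not a
thermodynamic prediction; no nearest-neighbour or salt correction is
applied, deliberately.

## The assembly simulator

`digest()` computes cut positions from recognition-site location, strand
and the enzyme's cut offsets (stored relative to the motif's 3′ end in an
editable registry). Only 5′-overhang cutters can digest; PstI-style
3′-overhang enzymes stay in the registry for scanning. Both physical ends
of a junction are represented by the same top-strand 4-mer, so ligation
matching is string equality and each junction's bases are counted exactly
once — digestion conserves total length.

`golden_gate()` models the one-pot equilibrium structurally rather than
kinetically: fragments still carrying a recognition site oriented to
re-cut a ligated junction are excluded from products (the enzyme would
linearise any assembly using them), candidate products that retain a site
are likewise rejected, and success requires exactly *one* circular
product drawing on at least two input molecules. Re-ligation of a single
input vector is reported as a diagnostic rather than an ambiguity; when
only one molecule is supplied, the unique re-ligation product is returned
with that diagnostic. Product identity is judged after canonicalisation
(`canonical_circular()`: lexicographically least rotation over both
strands), so rotation and strand are never spuriously distinguished.

Degenerate inputs are refused loudly: overlapping cut windows are an
"ambiguous digest", cut windows off the end of a linear molecule are an
error, and more than two sites per Golden Gate input simply surface as
extra fragments for the uniqueness check to adjudicate.

## What the fixtures emulate — and what they do not

All tests run on seeded synthetic sequences; no real plasmid map is
shipped. The generators (`random_spacers()`, `random_part()`,
`make_entry_vector()`, `make_template()`) emulate the *geometry* of the
real materials:

* the entry/destination vector is a motif-free 300-nt backbone plus a
  40-nt placeholder dropout flanked by two inward-facing BsmBI sites
  exposing the chosen fusion sites (the dropout stands in for a GFP or
  toxic screening cassette — only its cloning geometry matters here);
* the template is a 76-nt placeholder scaffold plus a 28-nt placeholder
  separator; the canonical binding parts are the scaffold's first 18 nt
  and the reverse complement of the separator's last 18 nt;
* spacers are 20-nt sequences free of every registry motif; parts are
  free of the blocking motifs (BsaI/BsmBI/NotI) but may contain legacy
  BioBrick/BglBrick sites, as real parts do.

Because the placeholder sequences are random, passing tests demonstrate
that the *design arithmetic and assembly logic* are correct for any
conforming vector/template, not that any particular biological scaffold
or Csy4 site is functional. Real runs should supply their own template
and vector FASTA.

Each generator draws from its own deterministic RNG stream derived from
the config seed and a stream name, so adding a fixture never changes
another fixture's output, and the ambient R RNG state is left untouched.

### Junction guards

One subtlety is handled explicitly: a BsmBI recognition site can arise
*by chance* spanning the boundary between a fixed sequence and free
sequence (e.g. separator end | spacer start) at a rate of roughly a
quarter percent per junction. Such a site is not a bug in the designer —
the simulator correctly reports that the product would be re-cut — but it
would make randomised suites flaky for reasons unrelated to the logic
under test. The generators therefore also reject scaffold prefixes,
separator suffixes, backbone termini and part termini that form a proper
prefix/suffix of a BsmBI motif on either strand, which makes a spanning
site impossible regardless of the neighbouring sequence. The fixed tail
bases (`AA·CGTCTC·A` … `T·GAGACG·TT`) are self-guarding by construction.
User-supplied sequences get no such guarantee; for them, verification
reports the failure honestly.

## Design choices where the design was open

* **Fusion-site table.** Only the type-2/type-3 junction (`TATG`) is
  fixed by the standard's published description here; the remaining
  sites are transcribed from the upstream yeast toolkit standard and
  shipped as an editable data file. The table is validated for junction
  consistency (adjacent types share a site, subtype series span their
  parent) rather than trusted.
* **Warn vs. block.** Internal BsaI/BsmBI/NotI sites warn at primer
  design time (the user may intend to domesticate them away) but hard
  block `simulate_level0()`, where they would guarantee a failed or
  re-cut assembly. Legacy-standard sites never block.
* **No silent edits.** A `TATG`-prefixed part beginning with its own
  `ATG` keeps it and triggers a duplicated-start-codon warning; trimming
  a user's sequence silently is more dangerous than a warning.
* **Candidate deduplication.** Candidates with identical Tm are all
  kept, one per binding length; stable sorting by `|Tm − target|` then
  length makes the ranking deterministic.
* **Positional matching.** "Three matching nucleotides" between 4-mers
  is evaluated position by position, not by best-shift alignment —
  ligation fidelity is positional.
* **Forbidden-site scanning covers both strands**: a site on either
  strand blocks digestion in reality.

## Problem sizes used by the test-suite properties

The randomised suites run at the following scales, chosen to exercise
every code path across the supported input range while staying
comfortably interactive: site-scanning agreement with an independent
Biostrings oracle on 150 random sequences (≤ 500 nt); array round-trip
identity for 100 seeded specs across N = 2…12; exhaustive-oracle
equivalence of the assembly search on 200 instances of ≤ 5 fragments;
digestion base-conservation on 500 random molecules; part-domestication
round trips for 200 random parts (30–2000 nt) across compatible type
pairs.

## Known limitations

* Overhang fidelity is binary (conflict or not); no empirical
  ligation-fidelity rates, kinetics, or concentration effects.
* Exact-match PCR only: primer mispriming and mutations are out of
  scope.
* The designers do not *remove* internal forbidden sites (no automated
  mutagenic domestication); they report them.
* Only Csy4-style separator arrays are modelled, not tRNA or ribozyme
  separation, and spacers are not scored for on/off-target activity.
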