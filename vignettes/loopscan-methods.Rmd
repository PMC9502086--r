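---
title: "Methods: contact occupancy, triplet symmetry and the [DE]G survey"
author: "loopscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact occupancy, triplet symmetry and the [DE]G survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscan)
```

## The scientific problem

The mitochondrial ADP/ATP carrier (AAC, SLC25A4) and its relatives fold as
three homologous ~100-residue domains. Each domain contributes two
transmembrane helices joined by a matrix loop and a short matrix helix, and
each carries the conserved matrix-side MCF signature
`Px[DE]xx[KR]xRxQxQ — (loop, matrix helix) — [DE]Gxxxx[YWF][KR]G`, with
`[YF]xGxxDCxx[RK]` on the matrix helix. Although the fold is three-fold
pseudosymmetric, the *interactions* the three matrix loops make — with their
own domain's motifs and across domain–domain interfaces — are strongly
asymmetric, and that asymmetry (most prominently the choice of D versus E in
the `[DE]G` motif) appears tied to transport function.

`loopscan` implements the analysis layer of that investigation so it can be
run and validated at desk scale: geometric contact occupancies on
trajectories, triplet pseudosymmetry mapping, motif-grammar scanning,
per-residue flexibility and orientation metrics, and the family-wide
`[DE]G` survey. A seeded synthetic-data generator produces trajectories and
sequences with known ground truth, so every stage is testable without
multi-microsecond simulations.

## Contact occupancy

A residue-pair contact is defined purely geometrically: the minimum distance
over a designated atom-set product (donor/acceptor heavy atoms, N and O) is
compared against a cutoff of **0.33 nm, inclusive**. Occupancy is the
percentage of analysed frames in contact. Three conventions matter:

* **Distance-only criterion.** No donor–hydrogen–acceptor angle term is
  applied; the single stated cutoff defines both salt bridges and H-bonds.
  For the same reason cysteine SG is not treated as a polar heavy atom.
* **Analysis window.** Production analyses use the trailing 2,000,000 ps of
  each trajectory. Desk-scale fixtures are far shorter, so
  `default_window()` degrades to the trailing 2/3 of frames and logs the
  substitution. `occupancy()` itself takes any `trailing_window()`.
* **Retention threshold.** Interactions are retained when their average
  occupancy across parallel trajectories is *strictly* above 25%
  ("higher than 25%"); a record at exactly 25% is dropped. Averages are
  arithmetic means over trajectories; tables print them rounded half-up to
  integers while full precision is kept internally.

One published occupancy row is arithmetically inconsistent in its source
(per-trajectory values 21/30/13 printed with average 12, though the mean is
21.3); the package does not attempt to reproduce that cell.

Candidate pairs are enumerated over the screened regions — within one matrix
loop, between a loop and its own domain's matrix helix, and across the three
domain–domain interfaces — with a whole-trajectory minimum heavy-atom
distance prefilter (default 0.6 nm). Per residue pair, one spec is emitted
per donor/acceptor context combination: backbone carbonyl `(O)`, backbone
amide `(NH)` (absent for proline), and the side-chain polar set. Sequence
neighbours (|i−j| ≤ 1) contribute no backbone–backbone specs. Salt bridges
are the Arg {NE, NH1, NH2} / Lys {NZ} versus Asp {OD1, OD2} / Glu
{OE1, OE2} set pairs; histidine is not treated as a salt-bridge partner.
Labels follow the published convention, e.g. `V37(O):A40(NH)`,
`R30:A141(O)`, `R236:E264`.

Classification is a total, deterministic partition: same loop →
`intra-loop`; loop + same-domain matrix helix → `loop-helix`; different
domains → `inter-domain` (`1-2`, `2-3`, `3-1`); anything else — including
residues outside the element map, with a warning — `other`.

## Triplet mapping

A *triplet* is the set of residues occupying one column of the three-domain
alignment, indexed by the residue number of the domain-1 member (triplet 38
= Q38/D143/Q240). `build_triplet_map()` consumes a three-row aligned FASTA
(numbering from `name/start-end` headers or `domain_starts`).
Columns where domain 1 is gapped cannot carry a triplet number; they are
labelled `"between t and t+1"` and excluded from symmetry summaries, since
triplets are defined strictly by domain-1 numbering.

The alignment is an input, not hard-coded. Five landmark triplets act as
validation anchors (`validate_triplet_anchors()`): 30 → (30, 139, 236) (the
capping arginines), 37 → (37, 142, 239) (the hydrophobic plug), 38 →
(38, 143, 240), 50 → (50, 153, 250) (the `[YF]xG` aromatics) and 65 →
(65, 168, 265) (the G of `[DE]G`). The introduction of the source study
once lists the third capping arginine as R264, against R236 everywhere
else; the package follows R236, which is the reading consistent with
triplet 30. The packaged alignment
(`loopscan_example("aac1_domains_synthetic.afa")`) is a **synthetic**
stand-in: the published alignment figure is not machine-readable, so the
fixture honours every published residue identity and the numbering/gap
structure, and fills unpinned positions with invented residues.

## Motif grammar and annotation

Patterns are compiled from literals, the wildcard `x`, residue classes
`[..]`, and the small-residue symbol `π`. The literature defines π only as
"a small residue"; the package defaults to {G, A, S, C, T}, configurable in
`compile_pattern()`. `scan_motif()` is a pure primitive: exhaustive
position-by-position matching, all overlapping matches reported.

`annotate_mcf()` picks one instance of each motif per domain as the hit
nearest its expected triplet anchor (P-motif near 27, `[YF]xG` near 50,
`DCxx[RK]` near 55, `[DE]G` near 64, `[YWF][KR]G` near 70); ties are
reported, never silently resolved. Real carrier domains frequently deviate
from the full `Px[DE]xx[KR]xRxQxQ` consensus after the capping arginine
(in AAC, domain 2 has A141/D143 and domain 3 has M238 where the consensus
expects glutamines), so a domain without a full hit is re-scanned with the
`Px[DE]xx[KR]xR` prefix and flagged `partial`.

`derive_elements()` turns anchors into ranges: per domain the matrix loop
runs from the residue after the triplet-37 hydrophobic-plug position
(= position 11 of the P-motif) to the residue before the `[YF]xG`
aromatic, and the matrix helix from that aromatic to the G of `[DE]G`.
When a domain only has a partial P-motif hit, the loop start is carried
through the triplet map from a domain that has one.

## Geometry metrics

* **Angle series** — per frame, the angle at a vertex atom between two rays
  (degrees, [0, 180]); the default `angle_spec()` is the side-chain
  orientation of the domain-3 capping arginine (R236-Cζ, R236-Cα vertex,
  T232-Cα).
* **RMSF** — each frame is least-squares superposed (Kabsch, via
  `bio3d::fit.xyz`) onto a reference before computing
  `sqrt(mean ||x_i(t) − x̄_i||²)` per Cα. The reference is the first frame
  by default (configurable to the time mean), and the fitting group is all
  Cα by default — the source analysis states neither, so both are exposed
  as arguments. Fitting on a perfectly collinear atom set leaves the
  rotation undetermined; validation scaffolds are therefore non-collinear.
* **Minimum-distance series** — per-frame minimum over all heavy atoms or
  side-chain heavy atoms of two residues.

## The [DE]G family survey

For each carrier, each domain's matrix-helix window is scanned for a G
preceded by a charged residue; the candidate nearest the helix C-end is
taken and the call is the preceding residue — D, E, or `other` for an
unexpected K/R/H. Survey exclusions follow the standard lists: carriers
outside the inner mitochondrial membrane (MTCH1, MTCH2, SLC25A46, PM34) and
carriers with a charged residue in the motif's second position (SLC25A47,
SLC25A51, SLC25A52); of the 53 human carriers this retains 46. Exclusion is
by name; an entry on both lists is excluded once with both flags. Because
the per-member domain assignments of all 53 human carriers are not
published as data, survey windows are an input (a config table, or the
derived element map for AAC-like sequences). Position-frequency matrices
report per-column counts over the 20 residues plus gap, and information
content `IC = log2(20) − H` with gaps excluded from the frequency
normalisation; no small-sample correction is applied by default.

## The synthetic generator

The generator *defines* the package's validation conditions:

* **Contacts** follow a two-state Markov (telegraph) process per pair with
  stationary bound probability `p` and lag-1 autocorrelation `phi`
  (`phi = 0` is i.i.d.); the effective sample size of an `n`-frame window
  is `n(1−phi)/(1+phi)`. The telegraph model was chosen over i.i.d. frames
  precisely so window/threshold behaviour under temporal correlation is
  testable. Defaults: bound distance 0.25 nm, unbound 0.45 nm, positional
  noise sigma = 0.01 nm per axis — the scenario constructor enforces
  `bound + 3σ < cutoff < unbound − 3σ` so state and measured contact
  almost surely agree — and 10 ps frame spacing, the conventional save
  interval. Atoms are real amino-acid templates (Arg/Glu by default, so
  salt-bridge sets are exercised); pairs sit 10 nm apart.
* **Sequences** are three planted domains of 100 residues (the approximate
  repeat length) with the full motif set at fixed offsets and filler drawn
  from {L, I, V, A, T, S, M}, an alphabet that cannot spawn spurious motif
  hits; `[DE]G` letters default to (D, D, E), the wild-type carrier
  arrangement. Optional indels insert filler into one domain with gap
  columns elsewhere, exercising the gapped-triplet logic.
* **Families** draw each member's per-domain `[DE]G letter
  Bernoulli(E) = p_e[d]`, with names optionally overlapping the exclusion
  lists; the default size is 53.

Everything is reproducible from a mandatory integer seed
(`withr::with_seed`; no environment-dependent parallelism). What the
generator does *not* emulate: physically realistic dynamics, solvent and
lipids, periodic boundary imaging, correlated multi-pair motions, and
sequence evolution (members are i.i.d., real families are phylogenetically
correlated). Passing tests therefore demonstrate the correctness of the
measurement and bookkeeping machinery under controlled statistics — not
that any biological conclusion re-emerges from new simulations.

## Validation problem sizes

The packaged checks run the occupancy estimator over
`p ∈ {0.1, 0.25, 0.5, 0.67, 0.9} × phi ∈ {0, 0.5, 0.9}`, 20 seeds × 10,000
frames per cell, asserting per-cell mean |error| within the 3σ binomial
bound at the autocorrelation-corrected effective sample size plus exact
agreement with a frame-counting oracle; the motif scanner against a PCRE
lookahead oracle on 1,000 random 200-mers for every motif; RMSF recovery of
`σ√3` within 2% at 10,000 frames; and byte-identical pipeline manifests on
repeated runs. These sizes were chosen once as the smallest that make the
statistical envelopes tight; they are not tuned to outcomes.

## Known limitations

* Multi-model PDB is the only trajectory format; binary formats (XTC/DCD)
  would need an external conversion step.
* The H-bond criterion is distance-only by design; analyses requiring
  angular criteria or water-mediated bridges are out of scope, as are
  energetic scoring and aromatic-stacking detection.
* Survey windows for non-AAC carriers must be supplied by the user.
* Occupancies at the retention boundary are sensitive to the strictness
  convention; this package treats the threshold as strict and the distance
  cutoff as inclusive, and states both in every output manifest.
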