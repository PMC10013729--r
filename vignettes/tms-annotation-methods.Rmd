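---
title: "Curating transmembrane segments from predicted structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating transmembrane segments from predicted structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aftm)
```

## The problem

Membrane-positioning programs (PPM3 and its relatives) were built for
experimental structures. Applied to predicted models they inherit the
models' pathologies: disordered tails and flexible linkers are placed
arbitrarily and drag the membrane optimization off target; helices broken or
kinked in the model are reported as two embedded segments; marginal
crossings are missed entirely; and genuinely membrane-embedded but
non-crossing (re-entrant) segments are indistinguishable from crossings in
the raw segment list. This package post-processes such raw placements into
curated transmembrane segment (TMS) calls, and provides the bookkeeping
around them: domain partitioning of the model, transfer of reference
annotations between near-identical sequences, and multi-source comparison.

Everything operates on 1-based closed residue intervals (the UniProt
TRANSMEM convention), and residue numbering is *never* rewritten: trimming
and domain extraction leave gaps rather than renumbering, so segment
coordinates from any processing track are directly comparable.

## Domain partitioning from pair errors

Structure predictors export, next to the coordinates, an L×L matrix of
predicted aligned errors (PAE, in Å): the expected error in residue j's
position when the model is aligned on residue i. Residue pairs within one
rigid, well-packed domain have low PAE; pairs spanning two mobile domains,
or touching disordered regions, have high PAE.

A segment is scored for splitting at site *s* (the last residue of the left
part) by the ratio `D_intra / D_inter`, where `D_intra` is the fraction of
low-PAE pairs (< 12 Å) pooled over all within-left plus within-right pairs
(i < j) and `D_inter` the same fraction over left×right pairs. Recursion
splits any segment longer than 500 residues at its best site when the ratio
reaches 10 (length > 1000) or 20 (length 501–1000), depth-first and
left-first, until no segment qualifies.

Choices that the ratio definition leaves open, and how this package fixes
them:

* **Pooling.** `D_intra` pools the two candidate segments (one count over
  the union of within-segment pairs) rather than, say, taking the minimum of
  two per-segment densities. Pooling is the simplest single-number reading
  and keeps the statistic monotone under segment swap.
* **Asymmetry.** Exported PAE matrices are asymmetric; a pair counts as low
  when the *minimum* of its two directions is below threshold, since either
  direction being confident indicates a rigid relative arrangement.
* **No exclusion band.** All pairs i < j are counted, including
  near-diagonal pairs. Sequence-adjacent pairs are low-PAE in any model, so
  they dilute both densities slightly and cancel in the ratio for the sites
  that matter.
* **Degenerate splits.** Unconstrained search admits 1-residue fragments
  whose intra density is undefined. The smallest admissible fragment is
  `min_fragment_len = 30` residues — roughly the smallest folded domain —
  and configurable.
* **Edge cases of the ratio.** `D_inter = 0` with `D_intra > 0` gives +∞
  (a perfect split, passes any threshold); 0/0 is defined as 0 and never
  justifies a split. Ties between sites break to the smallest index, making
  the whole recursion deterministic.

The implementation scans all admissible sites of a segment in O(L²) via
two-dimensional prefix sums; the test suite checks it against a brute-force
per-site evaluation on seeded block matrices, and checks the recursion
against an independently re-derived recursion plus tiling/threshold
invariants on 200 instances.

## Model preparation

Three trimming operations precede placement, all numbering-preserving:
caller-supplied peptide annotations (signal and transit peptides) are
stripped; residues with pLDDT below 50 are removed (the trimmed model may be
fragmented — it is kept as one model with numbering gaps, because the
placement step consumes whole models); and per-domain sub-models are
extracted for the domain track. Stripping and trimming commute, so their
order is immaterial. Confidence is held on the 0–100 scale internally;
files carrying pLDDT on the 0–1 scale (both conventions circulate) are
detected by `max(B-factor) <= 1` and rescaled on read.

## From raw placement to TMS calls

The raw placement supplies the two boundary surfaces — parallel planes
`n·x = o1, o2` or concentric spheres of radii `r1 < r2` — and an ordered
list of embedded segments with orientations (entry side, exit side). Side
labels are abstract (`side1`/`side2`); no placement convention names them.

1. **Classification.** Each raw segment, extended by `tms_extension = 10`
   residues on each side (clipped to residues that exist), is measured by
   the minimum distance of its main-chain atoms (N, CA, C, O) to each
   boundary. Both minima `< boundary_dist_max = 10` Å ⇒ the region reaches
   both boundaries and is a crossing (TMS); otherwise it is re-entrant and
   excluded from the TMS track (reported separately). The 10-residue
   extension makes the test robust to placement tools that trim segment
   ends conservatively.
2. **Merging.** Adjacent TMSs with identical (entry, exit) orientation
   separated by fewer than `merge_gap_max = 10` residues are one broken
   helix: they merge to their union span, repeated to fixpoint (the
   operation is idempotent).
3. **Recovery.** Two same-orientation TMSs imply an even number of
   crossings between them. When they are separated by
   `missing_gap_min = 15` or more residues, exactly one missed crossing is
   reconstructed: the gap residue with the smallest |d1 − d2| (minimum
   main-chain distances to the two boundaries; ties to the smaller residue
   number) is the center, extended by `missing_halfwidth = 5` residues on
   each side and clipped against the flanks, so an inserted segment never
   overlaps an existing one and spans at most 11 residues. "A window around
   the center" is read as symmetric-per-side; a total-width reading would
   halve the segment, and the parameter is exposed for users who prefer it.
   The inserted orientation is the reverse of the flanks' — topologically
   forced when exactly one crossing is inserted between two same-orientation
   neighbors. Gaps whose residues lack coordinates are skipped with a
   warning rather than interpolated.
4. **Ordering of the rules.** Re-entrant segments are set aside *before*
   merging and recovery. A re-entrant region between two same-orientation
   TMSs would otherwise block a legitimate recovery or, worse, be merged
   into a crossing. The re-entrant track is retained in the output.

TMSs are called on the trimmed full-length model and on each domain
sub-model, then combined: the union of both tracks, except that a
domain-derived segment overlapping a full-model segment by at least
`match_overlap_min = 10` residues is the same crossing seen twice and the
full-model boundaries win (the full-model placement sees the complete
membrane context, so its boundaries are preferred when both tracks agree).
Any residually overlapping survivors merge to their union span. No
combination rule is canonical here; this union-prefer-full rule is this
package's documented choice, and every output segment carries its
provenance (raw / merged / recovered) and track (full / domain) into the
structured log.

## Reference mapping and consensus

Reference TMSs (from databases of experimentally positioned or curated
membrane proteins) transfer to targets through tabular alignment hits. Hits
are kept only above 95% identity (strict), so projections are near-trivial:
by default a plain offset projection (requiring a length-matched hit), or a
gap-aware per-column walk when aligned sequence strings are present.
Projections partially outside the aligned span are clipped, not discarded,
as long as one residue survives — at this identity level a clipped
projection still marks the right region. Per target, projected ranges are
clustered by single-linkage with links at overlap ≥ 10 residues (any chain
of pairwise overlaps joins a cluster), and each cluster yields one consensus
TMS at the floored median of starts and of ends; for even counts the
midpoint average is floored, so the consensus of starts {10, 13} is 11.

## Comparison semantics

Two TMSs match at overlap ≥ 10 residues. Consistency between two sources on
one protein demands a one-to-one pairing covering *both* lists (greedy by
descending overlap, ties to the earlier start), which implies equal TMS
counts. The looser "mutual coverage" reading would let one wide segment
match two narrow ones and make per-source counts incomparable; bijection is
the stricter reading and the one adopted. Two empty lists are vacuously
consistent; empty versus non-empty is not. Three-source categories follow:
all three pairs consistent ⇒ `AUH`; exactly one pair ⇒ that pair's label;
none ⇒ `A\U\H`. Pairwise bijective consistency is not transitive (a wide
segment in one source can pair with disjoint narrow segments in the two
others), so exactly-two-pairs cases exist: they are assigned the
lexicographically first consistent-pair label with a warning, and the tests
exercise the case explicitly.

## The fixture generators, and what they do not show

`make_helix_bundle()` builds ideal membrane bundles: straight helices with a
1.5 Å per-residue rise along the membrane normal crossing a planar slab
alternately, loops outside the slab, optional Gaussian coordinate jitter,
and a truth table of crossings with orientations. Main-chain atoms sit on a
helical curve near the backbone position — sufficient for every distance
computation in the package, with no dihedral-level realism.
`make_hairpin()` plants a re-entrant region penetrating to a chosen depth.
`wrap_spherical()` swaps the planar boundaries for concentric spheres of
large radius (curvature error ~x²/2R) to exercise the spherical branch
without regenerating coordinates. `make_pae_blocks()` emulates rigid
domains as low-PAE diagonal blocks with a seeded fraction of entries flipped
across the 12 Å line; `make_placement()` derives raw placements from truth
with planted misses and splits; `make_annotation_sets()` plants per-source
shift/drop/add perturbations whose comparison outcome is computable in
closed form. All generators are bit-reproducible given a seed.

What passing tests on these fixtures shows: the corrections implement their
definitions exactly — classification thresholds, fixpoint merging, center
selection, clipping, clustering, medians, category logic — and the
end-to-end run is deterministic. What they do not show: performance on real
predicted models, whose error modes (gradual confidence decay, compact
misfolded tails, tilted or curved helices, amphipathic surface helices) are
not statistically emulated, and the quality of the upstream membrane
placement itself, which this package consumes but does not compute.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `pae_low_threshold` | 12 | Å | low-PAE cutoff for pair densities |
| `split_min_len` | 500 | residues | segments at most this long never split |
| `split_big_len` | 1000 | residues | boundary between the two ratio thresholds |
| `ratio_small` / `ratio_big` | 20 / 10 | — | minimal split ratio (501–1000 / >1000 residues) |
| `plddt_min` | 50 | 0–100 score | trimming threshold before placement |
| `tms_extension` | 10 | residues | per-side extension before classification |
| `boundary_dist_max` | 10 | Å | both-boundary proximity bound for a crossing |
| `merge_gap_max` | 10 | residues | merge gap bound (exclusive, `< 10`) |
| `missing_gap_min` | 15 | residues | recovery gap bound (inclusive, `≥ 15`) |
| `missing_halfwidth` | 5 | residues | per-side extent of a recovered TMS |
| `match_overlap_min` | 10 | residues | match/clustering overlap bound |
| `identity_min` | 95 | % | hit filter (strict, `> 95`) |
| `min_fragment_len` | 30 | residues | smallest fragment a split may produce |

The comparison directions (strict vs inclusive) follow the rules they
implement and are asserted in the tests (`gap 14` does not recover, `gap 15`
does; identity exactly 95 is dropped; overlap 9 does not match).

## Numerical choices and problem sizes

Geometric predicates use plain double arithmetic; rigid-transform invariance
of boundary distances and classification is tested to 1e-6 Å over random
rotations and ±50 Å translations. Membrane normals are normalized on
construction (offsets rescaled so the planes are unchanged). All tie-breaks
(split sites, recovery centers, matching) resolve to the smallest index, so
every pipeline output is a deterministic function of inputs and
configuration. Degenerate inputs are first-class: empty raw segment lists
yield a non-TMP call, fully trimmed models are valid and yield zero TMSs,
empty annotation lists compare as described above.

The test suite validates the split search against a brute-force per-site
oracle on 100 seeded block matrices (lengths mostly 60–300 with a tail to
1200, where the O(L³) oracle dominates run time), the recursion invariants
on 200 matrices, merging against a fixpoint oracle on 200 random segment
lists, recovery on 50 delete-one bundle simulations, clustering against a
transitive-closure oracle on 200 random range lists, the comparison
statistics against closed-form planted values on 20-protein fixtures, and
end-to-end determinism byte-for-byte. These sizes were chosen as the point
where the properties stabilize while the whole suite stays fast enough to
run on every change.

## Known limitations

* The package curates placements; it cannot rescue a protein the upstream
  tool failed to embed at all (zero raw segments stays a non-TMP call), and
  single-pass proteins whose lone helix is low-confidence are trimmed away
  before placement ever sees them.
* Recovery inserts at most one crossing per qualifying gap; a gap hiding
  three crossings (same-orientation flanks again) gains only one.
* Offset projection assumes near-ungapped alignments, which >95% identity
  hits almost always are; supply aligned strings in the hit table otherwise.
* The re-entrant/crossing dichotomy is purely geometric; interfacial
  amphipathic helices that skim one boundary within 10 Å of both planes in
  a thin membrane would be called crossings.
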