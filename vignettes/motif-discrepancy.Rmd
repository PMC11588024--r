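---
title: "Comparing RNA 3D motif instances: the model behind motifcorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing RNA 3D motif instances: the model behind motifcorr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifcorr)
```

## The problem

RNA molecules are solved again and again: hundreds of ribosome
structures from one organism, and structures of the same RNA family
from many organisms. A recurring question is whether a small motif — a
hairpin, an internal loop, a handful of functionally important
nucleotides such as the A1492/A1493 pair of the ribosomal decoding
loop — adopts the same geometry in all of those structures, or switches
between conformational states that correlate with ligands, functional
state, or sequence changes.

`motifcorr` answers this at the level of *motif instances*: ordered
sets of nucleotides (intended for up to around 30) taken from one chain
of one structure. Starting from a query instance, the package

1. retrieves the corresponding nucleotides across a user-supplied scope
   of structures,
2. compares all retrieved instances with a geometric discrepancy
   metric,
3. orders the instances so similar conformations are adjacent,
4. annotates within-motif interactions and nearby chains, and
5. writes a table, an ordered heatmap matrix, and superposed
   coordinates.

Everything runs offline on local mmCIF/PDB files; no database or
network access is involved.

## Base reference frames

Each nucleotide is reduced to a *base reference frame*: a center
$c_i \in \mathbb{R}^3$ and a proper rotation $R_i \in SO(3)$ describing
where the base sits and how it is oriented. The frame is obtained by
least-squares fitting an embedded standard planar base geometry onto
the observed base ring atoms (purines: N9 C8 N7 C5 C6 N1 C2 N3 C4;
pyrimidines: N1 C2 N3 C4 C5 C6). The center is the unweighted mean of
the observed ring atoms; the rotation is the proper rotation of the
fit, so identical bases in identical poses get identical frames, and
rigidly moving a base by $(Q, t)$ moves its frame to $(Q R_i,
Q c_i + t)$ exactly (this equivariance is property-tested).

The embedded standard geometries are *synthetic idealized* coordinates
built in code (`R/base-frames.R`) from regular polygons with a uniform
1.38 Å ring bond length, with exocyclic O/N substituents placed
radially in plane. Because frames only ever enter the analysis through
*differences between frames of the same base type*, any internally
consistent standard geometry gives the same discrepancy values; using
an idealized one keeps the package free of external coordinate tables.
A frame needs at least 3 ring atoms; nucleotides below that are dropped
at parse time with a warning, since no orientation can be defined for
them.

Modified nucleotides (pseudouridine, methylated bases, ...) are mapped
to a parent letter by a built-in table so that sequences align across
structures with scattered modifications; unmapped hetero residues are
excluded from chains (their atoms remain available for neighbor
detection). When alternate conformers are present, the
highest-occupancy altloc wins, ties broken by altloc letter ascending —
an arbitrary but deterministic rule.

## The geometric discrepancy

Two instances $A$ and $B$ with $n$ nucleotides each are compared by
first superposing the $n$ base centers of $B$ onto those of $A$ with
the least-squares rigid fit $T^*$ (Kabsch, proper rotation enforced),
then combining the residual center distances
$d_i = \lVert c_i^A - T^*(c_i^B)\rVert$ with the base reorientation
angles $\theta_i$ between $R_i^A$ and $T^*_{\mathrm{rot}} R_i^B$:

$$
D(A, B) \;=\; \frac{1}{n}\sqrt{\textstyle\sum_i d_i^2 \;+\;
  \sum_i (k\,\theta_i)^2},
\qquad k = 1\ \text{Å/rad by default.}
$$

Properties that follow directly and are enforced by tests:

* $D(A, A) = 0$, and $D$ is invariant under any rigid motion applied to
  either instance (checked to below $10^{-8}$ over random motions).
* Rotating one base in place by an angle $\varphi$ (center fixed)
  changes $D$ by exactly $\varphi / n$ — a closed form used as an exact
  oracle in the tests and by the fixture generator's manifest.
* Only base centers enter the superposition, so $D$ is independent of
  sugar/backbone completeness.

Two choices here are conventions rather than mathematical necessities,
and both are exposed as parameters. The angle weight `kAngle` (Å per
radian) balances positional against orientational variation; 1 Å/rad
follows the established discrepancy measures in the RNA 3D comparison
literature. The $1/n$ normalization makes values comparable across
motif sizes. The angle itself is the geodesic angle
$\arccos((\mathrm{tr}(R_1^{\top}R_2) - 1)/2)$, evaluated as
`atan2(sin, cos)` with the sine taken from the skew part of
$R_1^{\top}R_2$: mathematically identical, but accurate to machine
precision near zero angle, where the plain arccos loses half the
available precision — without this the self-discrepancy of a rigidly
moved copy would only reach about $10^{-8}$ instead of $10^{-15}$.

## Correspondence across structures

The scope of a query is a set of (file, chain, model) members, in one
of two modes.

**Chain sets** model the within-organism case: chains of the same
molecule from the same organism are nearly identical in sequence, so
each member is aligned to the query chain with a global (end-gap
penalized) pairwise alignment (match +2, mismatch −1, gap open −5, gap
extend −1, a gap run of length $L$ costing $-5 - L$). A full multiple
alignment would add nothing at this near-identity level. The aligner is
`Biostrings::pairwiseAlignment`; its optimality is cross-checked
against an exhaustive enumeration oracle on short sequences. One
caveat is inherent to alignment, not to the implementation: a deletion
inside a homopolymer run (e.g. one G of "GG") has several co-optimal
placements, and the reported mapping picks one of them.

**Stockholm mode** models the cross-family case: a precomputed multiple
sequence alignment (typically from a covariance model of the family)
is *consumed*, never computed, and its rows are mapped to members.
Correspondence then goes through shared alignment columns. Each row
must spell its chain's observed sequence up to modified-residue
mapping, case, and unresolved residues; a genuine mismatch drops the
member with a logged reason, because a wrong row-to-chain assignment
would silently produce nonsense correspondences.

An instance is retained only if **every** query position maps to an
observed nucleotide with a defined frame. Partial instances are
dropped (with the first failing position logged) rather than padded:
the discrepancy is only defined between complete, equal-length
instances, and padding would quietly change what is being compared.
Consequently `|instances| + |dropped|` always equals the number of
members after filtering, which is asserted in tests.

Resolution and method filters run before any alignment work. The
resolution ceiling is *inclusive* (a member at 3.0 Å passes a 3.0 Å
ceiling), matching how resolution thresholds are conventionally quoted;
members with unknown resolution are dropped only when a ceiling is
actually set. A sidecar metadata table overrides file headers, for
files with incomplete metadata.

## Ordering, annotation, neighbors, outputs

**Seriation.** Instances are ordered by average-linkage hierarchical
clustering of the discrepancy matrix followed by *optimal leaf
ordering*: among all $2^{n-1}$ leaf orders consistent with the
dendrogram, dynamic programming finds the one minimizing the summed
discrepancy between adjacent instances. Conformational clusters then
appear as contiguous dark blocks on the heatmap diagonal. No published
reference algorithm exists for this step in the motif-comparison
setting, so the choice is this package's own; `--ordering greedy-path`
(nearest-neighbor path) and `none` are available for comparison. All
tie-breaks are first-index-wins, making the order — like every other
output — byte-reproducible. The DP is quartic in the worst case but
instant for the tens-of-instances scopes the tool targets.

**Interaction annotation** is an explicit *heuristic*, not a
Leontis–Westhof classification: a base pair of the instance is labeled
`stack` when base centers are closer than 5.5 Å, base normals within
30° of (anti)parallel, and the vertical offset (projection of the
inter-center vector on the mean normal) lies in 2.5–5.5 Å; `pair` when
centers are 4.5–12 Å apart, normals within 65° of (anti)parallel, and
at least two N/O atom pairs across the bases sit within 3.4 Å. Stack
wins when both fire; all thresholds live in `interactionConfig()`. The
purpose of the column is to make presence/absence shifts of
interactions across clusters visible in the instance table; assigning
the twelve geometric basepair families is a separate project and is
deliberately out of scope.

**Neighboring chains.** A chain is a neighbor of an instance when any
of its heavy atoms is within 10 Å (configurable) of any instance heavy
atom, hydrogens ignored since they are usually absent from experimental
structures. The instance's own nucleotides are excluded but its host
chain may qualify through flanking residues. The implementation is
plain all-pairs (blocked per chain) and is tested for exact agreement
with an independent brute force. Whether neighborhoods should use all
atoms or base atoms only is a genuinely open convention; all heavy
atoms was chosen because binding partners contact backbone as often as
bases.

**Outputs.** The driver writes the instance table (seriation order,
with per-position letters+numbers, interactions, neighbors), the
ordered discrepancy matrix as CSV, the full matrix as JSON, a grayscale
heatmap (darker = more similar; CSV/JSON are the contract, image
failure only warns), superposed coordinates as a multi-model mmCIF (one
model per instance, fitted on base centers onto the query, optionally
carrying neighborhood residues), the drop log, and a machine-readable
`query.json` sufficient to re-run the query. An optional
`maxDiscrepancy` trims only the table/CSV display, never the
computation. A worked example is in the README.

## The synthetic fixture generator

Real motif scopes live in large structure files with uncontrolled
provenance, so the package ships a generator
(`fixtureSpec()` / `makeScope()`) that writes fully-controlled scopes
as minimal-but-valid mmCIF (atom_site plus entry/exptl/refine/entity
records, so metadata filters are covered). Bases are placed along an
ideal helical path (defaults: rise 3.4 Å, twist 32°, radius 2.5 Å —
chosen so consecutive bases satisfy the stacking criterion and
non-consecutive ones do not, with an 11-nt default length echoing the
decoding loop). Per member it can apply, with ground truth recorded in
a JSON manifest:

* global rigid motions — must leave $D$ at numerical zero;
* isotropic Gaussian coordinate noise — raises $D$ monotonically in
  expectation;
* in-place per-base rotations — shift $D$ by the closed form
  $\varphi/n$ and plant conformational clusters;
* indels — shift author numbering and exercise the aligner;
* missing ring atoms — force frame-undefined drops;
* modified-residue codes, a peptide chain, and one-atom neighbor
  chains planted at an exact minimum distance (via the support point of
  the motif in a fixed direction).

What passing tests on these fixtures *do* show: the metric's
invariances and closed forms, the correspondence bookkeeping, seriation
cluster recovery, and exact neighbor distances, under fully known
ground truth. What they *cannot* show: behavior on real experimental
artifacts — correlated (non-isotropic) coordinate error, chain breaks,
heterogeneous numbering conventions, genuinely ambiguous family
alignments. The fixtures have idealized backbone-free bases and
near-identical sequences by construction; conclusions about real
structures still require real structures.

Problem sizes used by the shipped checks (chosen to exercise every
code path at interactive speed): motifs of 2–34 nt, scopes of 1–10
members, 100-replicate invariance sweeps, 200 random aligner pairs
against exhaustive search, rotation grids at 9° spacing, and 1000
random permutations as the seriation baseline.

## Known limitations

* The interaction annotator is heuristic (above); its labels are
  coarse by design.
* Instances of unequal length are never compared; there is no elastic
  or partial-motif alignment.
* No symmetry-mate expansion: neighbors are detected within the
  deposited asymmetric unit / biological assembly as given in the file.
* mmCIF reading covers the atom_site loop and common metadata; exotic
  constructs (multi-line values inside loops) are rejected with a
  clear error rather than guessed at.
* Loop identifiers from motif databases are not resolved; selections
  are ranges or explicit unit IDs.
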