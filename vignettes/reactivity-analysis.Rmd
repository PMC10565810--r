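---
title: "Mining reaction events from catalyst exploration trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining reaction events from catalyst exploration trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactraj)
```

## The problem and the model

Automated exploration engines (metadynamics-driven conformer searches,
reactive MD) emit multi-frame XYZ trajectories in which a starting
organometallic complex visits alternative bonding patterns: ligand arms
detach, adducts migrate, new bonds form. `reactraj` treats each frame as
a *labeled molecular graph* and defines all downstream chemistry in graph
terms:

* **Nodes** are atoms, labeled by element. Atom identity is positional:
  all frames of one trajectory share one atom ordering, so atom *i* in
  frame 40 is the same nucleus as atom *i* in frame 0. This is what the
  generating engines guarantee, and it makes bond diffs exact set algebra
  rather than a graph-matching problem.
* **Edges** carry one of three bond classes. A pair of non-metal atoms is
  covalently bonded when its distance is at most `covalent_scale` times
  the sum of covalent radii; a metal--ligand pair is coordination-bonded
  up to `metal_scale` times the radius sum; and a metal--hydrogen pair
  that fails the coordination test but sits inside a fixed distance
  window is recorded as a *weak* (agostic-type) contact.
* A **conformer** is an equivalence class of frames under labeled graph
  isomorphism (elements and bond classes both preserved). Frame 0 is the
  reference conformer C1.
* A **reaction event** is the positional diff of a conformer's graph
  against the reference: formed bonds are rendered `+El-El`, broken bonds
  `-El-El` (metal element first, otherwise alphabetical; ASCII hyphens
  throughout so labels survive every file format). On top of the
  elemental labels, annotation-aware labels mark side-arm decoordination
  (`-side arm`, `-side arm(2)` for two arms), repeated identical changes
  (`-Mn-N(2)`), and complete adduct detachment (`-adduct`).

The workflow makes no assumption about where the energies come from: the
comment-line energy of each frame is taken as-is (hartree by default,
converted to kcal/mol for reporting), so semiempirical and DFT
trajectories are handled identically.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `covalent_scale` | 1.20 | — | covalent cutoff as a multiple of the radius sum; the common perception rule |
| `metal_scale` | 1.30 | — | coordination cutoff; metal--ligand bonds run systematically longer than covalent ones |
| `weak_h_metal_min/max` | 1.6 / 2.3 | Å | agostic M···H window; a geometric modeling choice, not a printed literature criterion, and therefore exposed |
| `clash_floor` | 0.75 | Å | minimum interatomic distance tolerated when a substituent is attached |
| `energy_window` | [−40, +25] | kcal/mol | credibility window for database classification; closed on both ends |
| `de_binwidth` | 5 | kcal/mol | bin width when ΔE is used as a histogram feature |
| `k`, `n_init` | 10 / 10 | — | k-modes cluster count and restart count; the seed is mandatory |

Covalent radii are a standard single-bond table (H–Rn), with low-spin
values for the mid-3d metals appropriate to carbonyl-stabilized
complexes. Unknown element symbols are a hard error: a typo must never
silently change perception.

Two perception details deserve emphasis. First, hydrogen atoms keep only
their single nearest strong-bond partner when several candidates pass the
distance test; this suppresses artifact H–H and H–C edges in crowded
alkyl groups at the cost of forbidding genuinely bridging hydrides, which
are outside this package's scope. Second, bond classes are part of graph
identity: a weak agostic contact is never interchangeable with a covalent
or coordination bond, so conformers that differ only by an agostic
contact are distinct. Callers who consider that over-splitting can set
`weak_in_identity = FALSE`, which removes weak edges from the isomorphism
test while keeping them in the diffs.

## Conformer identification: order, ties, and the prescreen

Frames are scanned in trajectory order. Each frame's graph is compared
against the conformers discovered so far, in discovery order, and joins
the **first** match — a deterministic, order-stable rule. Comparison is a
two-stage test: an iterated label-refinement fingerprint (three rounds of
Weisfeiler–Lehman-style neighborhood hashing over element and bond-class
labels) prescreens candidates, and surviving pairs are certified with a
color-aware exact VF2 matching from `igraph`. The fingerprint is sound in
one direction only — different fingerprints prove non-isomorphism, equal
fingerprints prove nothing — which is exactly the direction a prescreen
needs; the test suite checks the sequential identifier against a
brute-force all-pairs clustering oracle (200 random trajectories of up to
50 frames and 30 atoms) and the exact matcher against a factorial
permutation oracle on small graphs.

Energy bookkeeping follows the representative-minimum convention: each
conformer records the minimum and maximum energy over its member frames,
its representative energy is the minimum, and ΔE is that minimum minus
the reference conformer's minimum. The reference ΔE is therefore exactly
zero, which the tests assert. Frames without a parseable energy propagate
as `NA` with a warning; energy-dependent operations (window filtering,
hemilability detection) refuse `NA` rather than guessing.

The evolution graph is a star: one vertex per conformer, the reference at
the hub, one edge to every other conformer, each vertex annotated with
member frames and energies. Whether temporally adjacent conformers should
also be linked is genuinely ambiguous from the source material; the star
is the literal reading, and `sequential_edges = TRUE` adds the temporal
edges for users who want the alternative without changing the default.

## Hemilability

Side-arm decoordination is only chemically interesting as *hemilability*
when the decoordinated structure is more stable than the reference.
`detect_hemilability()` flags conformers with at least one broken
metal--donor bond **and** ΔE < 0. Uphill arm loss and adduct loss are
deliberately not flagged.

## The combinatorial library

`enumerate_combinations()` is the exact Cartesian product backbone × R¹ ×
R² × X in lexicographic order; with the four pincer backbones, six R
groups at each position and four adducts this is 4 × 6 × 6 × 4 = 576
complexes. Functionalization is symmetric: one R¹ choice applies to every
R¹ site of a scaffold.

Geometry construction replaces a placeholder atom (a dummy H named in the
scaffold annotation) by a rigid substituent fragment. The bond axis is
fixed by the anchor→placeholder direction and the new bond length
defaults to the covalent-radius sum. The torsion angle about the bond
axis is chosen by a deterministic scan: 36 equally spaced angles are
evaluated and the one maximizing the smallest fragment–scaffold contact
distance wins, ties going to the smallest angle. An earlier fixed-angle
rule (align to a canonical perpendicular) proved needlessly
clash-prone for bulky groups; the scan is equally reproducible — identical
inputs give coordinate-identical outputs — and leaves only genuine steric
conflicts, which are collected per entry in a rejection report so that
`entries + rejections` always equals the enumeration size. No force-field
relaxation is applied: downstream analysis needs topologically correct,
clash-free geometries, not refined ones.

## k-modes clustering

Reaction-label sets are encoded as a binary matrix (one column per
distinct label in the database, sorted). The k-modes implementation is
written in the package rather than delegated, because every tie-break
must be pinned down for bit-reproducibility:

* assignment: minimum simple-matching dissimilarity, ties to the lowest
  cluster id;
* update: per-column mode of the members, ties resolved toward the
  largest ("present") value;
* empty clusters keep their previous center;
* iteration stops at a joint fixed point of assignments and centers;
* `n_init` seeded restarts, restart *r* seeded with `seed + r − 1`, best
  cost wins.

The recorded per-iteration cost is provably non-increasing (each
half-step only improves the objective for the other half fixed), and the
suite verifies monotonicity on random instances, exact recovery of two
disjoint planted label blocks at k = 2 for any seed, and the analytic
k = 1 case (center = column-wise mode).

## What the synthetic fixtures do and do not show

The fixture module builds schematic octahedral pincer complexes — metal
at the origin, trans side-arm donors, a central amine completing the
tridentate ligand through two- or three-carbon bridges, two carbonyls,
and an adduct placeholder. Bridge carbons are placed by a deterministic
penalized least-squares solve that enforces bond lengths while keeping
every backbone atom clear of the metal's perception sphere; the short
carbene and amine arms need three-carbon bridges for such a clearance to
exist at all, a purely geometric fact discovered during design. Every
preset is validated at construction: the perceived graph must equal the
designed bonding pattern exactly.

Scripted events are realized as rigid group motions — translation along a
bond axis, a swing about a pivot atom (which preserves the group's bond
to the pivot; the natural decoordination motion), or a hinge rotation
about an axis through two atoms — with the final distance solved by root
finding. Gaussian coordinate jitter (default 0.02 Å, reduced to 0.005 Å
for fixtures whose target distances sit near a perception threshold)
exercises threshold robustness. The generator then re-perceives every
emitted frame and demands that its edge set equal the scripted edge set
for its segment, so an unrealizable script fails loudly at generation
time rather than silently producing a fixture that tests nothing.
Segment energies are piecewise constant, making all ΔE assertions
analytic.

What passing these fixtures shows: the pipeline recovers known bond
events, conformer partitions and energies exactly under realistic
geometric noise. What it does not show: anything about the *physics* of
real trajectories — fixture energies are arbitrary bookkeeping values,
the dynamics are teleported rather than continuous, and real
metadynamics frames contain strained geometries, transition regions and
borderline contacts that no scripted corpus reproduces. Conclusions
about real catalysts still require real exploration data.

The corpus covers single and double side-arm decoordination, central
donor loss, adduct loss, agostic contact formation, CF₃ migration from a
donor to the metal (scripted as adduct loss followed by migration into
the vacated site, since a distance-based perception finds no room for a
seventh contact at a saturated metal), and nucleophilic attack of a
hydroxide adduct on a carbonyl carbon. The central-donor fixture is
omitted for the CNC backbone — its folded arms leave the central N no
clean exit under rigid motions — and replaced there by a compound
side-arm-plus-agostic fixture; central decoordination remains covered by
the other three backbones.

## Numerical choices and degenerate inputs

* XYZ energies: first parseable float token of the comment line
  (`Energy=` prefixes and bare numbers both work); a strict flag accepts
  only a lone bare number. Round trips preserve coordinates to 1e-6 Å and
  energies to 1e-8.
* 1 hartree = 627.509 kcal/mol, overridable where more digits matter.
* One-frame trajectories are valid: one conformer, empty diff, a
  single-vertex evolution graph.
* Window endpoints are closed on both sides, read literally from the
  bracket notation.
* Records without usable energies stay in the database flagged
  `no_energy`; energy-based operations reject them explicitly.
* Test problem sizes — 200 random trajectories for the partition oracle,
  27 scripted fixtures, 100 rigid motions, 50 random k-modes instances —
  were chosen so the full suite completes in a few minutes on one CPU
  while still exercising each property over a meaningful sample.

## Known limitations

* Bond perception is purely geometric; no bond orders, no charges, no
  electronic structure. Borderline distances flip edges, which is why
  thresholds are exposed and fixtures test robustness margins.
* Positional atom identity restricts analysis to trajectories that
  preserve atom order (the standard case for exploration engines); it
  cannot align trajectories with permuted atoms.
* The agostic window is a modeling choice, not a fitted criterion, and
  only metal–H weak contacts are modeled; other weak interaction types
  (π contacts, hydrogen bonds) are out of scope.
* Library geometries are unrelaxed; rejection of a clashing combination
  is a statement about rigid fragments, not about the real molecule.
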