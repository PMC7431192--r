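---
title: "Methods: structural alignment and pore assessment of channel TM domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural alignment and pore assessment of channel TM domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`channelstruct` compares tetrameric ion-channel transmembrane (TM) domains by
geometry rather than sequence. This vignette documents the models and
procedures, the parameters that matter, the numerical conventions, and the
limits of what the synthetic test bed can show.

## Inputs and preprocessing

The unit of analysis is a `StructureModel`: a flat atom table in author
numbering with hetero flags, the reported resolution, and an annotation block
consumed from membrane-positioning output — the membrane normal, the
extracellular side, TM-segment ranges, and three domain boundaries (TM =
pre-S1 start to TRP-box end; pore = S5 start to S6 end; S1S4 = S1 start to S4
end). Membrane orientation is *never computed here*; it is an input.

Preprocessing mirrors standard practice for this analysis family:

* structures with reported resolution poorer than 5 Å are excluded (the
  boundary is inclusive, 5.0 Å passes);
* HETATM records are removed before alignment and profiling;
* any loop between two TM segments longer than 100 residues is reduced to
  the 10 residues adjacent to each flanking segment (loops of exactly 100
  are untouched);
* alternate locations resolve to the highest-occupancy conformer, ties to
  altloc `A`; only the first model of multi-model files is read;
* TM and pore domains keep all four chains, the S1-S4 domain keeps a single
  protomer;
* before alignment, chains are ordered counterclockwise as seen from the
  extracellular side, by the azimuth of each chain centroid in the membrane
  plane. Convention: the cycle starts at the chain nearest azimuth 0 in the
  plane basis built from the membrane normal (ties by chain id); azimuths
  within 1e-9 of a full turn snap to 0. Any fixed convention suffices
  because the downstream alignment is purely geometric; the choice is
  documented because other implementations may anchor the cycle elsewhere.
  Merging preserves author chain ids and residue numbers (keys stay
  authoritative); the merged order is recorded rather than renumbered.

## Pairwise alignment and the TM-score

The aligner is fragment-seeded and TM-score-optimizing. Stationary length
`L_ref` fixes the distance scale `d0 = max(0.5, 1.24 (L_ref − 15)^{1/3} −
1.8)` (the 0.5 Å floor covers `L_ref ≤ 15`). Candidate superpositions come
from gapless Kabsch fits of all fragment pairs (length `fragment_len = 8`,
stride `stride = 4`) plus one pass pairing CA-geometry helix segments. Each
seed is scored by a single score-matrix + dynamic-programming round; the 20
best seeds (`top_k`) then iterate to a fixed point: TM-optimal superposition
of the current mapping (iterative close-pair subset refinement over window
seeds of decreasing length), score matrix `1/(1+(d_ij/d0)^2)`, global DP with
gap penalty `gap = 0.6` in score units and free end gaps, until the mapping
stops changing (`max_iter = 20`). DP ties break diagonal, then up, then left,
which makes the whole procedure deterministic. The returned TM-score is the
stationary-normalized sum over mapped pairs; self-alignments score exactly 1.

The settings `F = 8, S = 4, g = 0.6` are the standard fragment-alignment
family values and are exposed as arguments. On toys of ≤ 30 residues the
aligner is checked against an exhaustive-seed oracle (every fragment pair at
stride 1, iterated to convergence in plain R); at scale, the pruning to
`top_k` seeds is a speed/optimality trade-off that the oracle test bounds.

Because `L_ref` differs with direction, every pair is aligned twice with
mobile and stationary exchanged; matrices are reported with mobile rows and
stationary columns.

## Structural MSA

One structure anchors the MSA; its residues are the columns. Each other row
is filled from that structure's pairwise alignment with the reference: a
mobile residue mapped to reference position *j* lands in column *j*; mobile
residues without a reference partner (insertions) are omitted; unmatched
reference positions are gaps. Width therefore always equals the reference
length and the reference row has no gaps. This is a star-shaped construction,
not a progressive MSA: rows are mutually consistent only through the
reference. If a reference column is hit twice (possible only at merged-chain
junctions), the first occurrence wins and a warning is logged. Nonstandard
residues render as `X` but keep their provenance.

## Clustering

Scores convert to distances by `TM-distance = 1 − TM-score`. Items are the
stationary structures: item *j*'s feature vector is column *j* of the
distance matrix (distances of all mobiles to *j*), dissimilarity is the
Euclidean distance between columns, and agglomeration is single linkage
(nearest point), matching the clustered-heatmap practice this package
follows. Leaf order and dendrogram reflections follow `stats::hclust`'s
deterministic conventions; rows are displayed in the same leaf order for
square all-vs-all matrices.

## Pore profiling

For each plane along the pore axis the profiler maximizes the clearance
`f(p) = min_i (|p − x_i| − r_i)` over in-plane points `p`, where `x_i` ranges
over heavy protein atoms and `r_i` are van der Waals radii (defaults C 1.85,
N 1.75, O 1.65, S 2.00, P 2.10 Å; unknown elements 2.0 Å; hydrogens are
ignored). The search is a deterministic multi-start: the previous plane's
center plus a ring of eight 1 Å offsets, each polished by Nelder-Mead and a
shrinking pattern search (final step 5 × 10⁻³ Å). Marching proceeds in 0.25 Å
steps both ways from a start point in the lumen (default: heavy-atom
centroid, which lies on the pore axis for a C4 tetramer) until the radius
exceeds the 10 Å bulk cutoff or the planes leave the atom extent; a blocked
plane is skipped with the march continuing. A `seed` argument reserves
optional random restarts; the default search is seed-independent.

An atom lines the pore at a plane when its distance to the plane's center
equals its van der Waals radius plus the local pore radius within `tol = 0.1`
Å; a residue's minimum radius is the smallest profile radius over planes any
of its atoms touches. Constriction radii are labelled against hydration
limits — below 1.0 Å nothing passes, 1.0–3.3 Å dehydrated ions only,
3.3–4.1 Å hydrated Na⁺, ≥ 4.1 Å hydrated Ca²⁺ — with inclusive lower bounds.
The gate tally counts a structure as multiply constricted when its profile
has at least two maximal sub-1.0 Å runs separated by more than 1.5 Å along z
(about one helical rise); this operationalizes "multiple constriction
regions", which is otherwise a judgement call.

On analytic fixtures the profiler recovers the closed-form radius to well
within 0.05 Å. Against published values for real structures, the main source
of Å-level discrepancy is conventions the original tools do not print (radius
set, step, endpoint criteria); ±0.2 Å is a realistic agreement band.

## Secondary structure

Hydrogen bonds use the Kabsch–Sander electrostatic energy `E = 0.084 ·
332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with a bond at
`E < −0.5`; the amide H is rebuilt 1.0 Å from N opposite the preceding C=O
(the standard reconstruction when hydrogens are absent). n-turns at offsets
3/4/5 with two consecutive turns start 3₁₀/α/π helices (codes G/H/I);
precedence is H > G > I as in DSSP 3.x; residues in turns but no helix are T;
chain breaks (CA–CA > 4.5 Å) act as termini. Strand (E/B) and bend (S) codes
are deliberately not assigned: the TM regions surveyed are helical, and
would-be strands render as `-`. A consequence of the two-turn minimum is that
π-run lengths are always 0 or ≥ 5, which the survey statistics rely on.
π statistics are taken strictly within the annotated S6 window (no spillover
into the S4–S5 linker); the window is an argument if the looser behavior is
wanted.

## Motifs

A ligand-binding pocket is every residue with at least one side-chain heavy
atom within 4.0 Å (inclusive) of any ligand heavy atom; side chain means
heavy atoms excluding backbone N/CA/C/O, so glycine never qualifies. With one
ligand copy per subunit the union over copies is reported. Selectivity-filter
motifs come from annotated residue ranges of the reference (filter boundaries
are a curation decision, not computed). Comparisons across the MSA report
`identity% = 100 · n_identical / n_ref` and `similarity% = 100 · n_similar /
n_ref` with `n_ref` the motif length; similar means a positive BLOSUM62
score (identities included, so identity ≤ similarity always); target gaps and
`X` count as neither. The denominator stays fixed at `n_ref` even when the
target has gaps — the alternative (excluding gaps from the denominator) is a
flag away but not the default.

## Synthetic test bed

`make_ideal_helix` builds N/CA/C/O(/CB) backbones from canonical per-class
dihedrals (α −57.8/−47, 3₁₀ −49/−26, π −55/−70) with standard bond geometry,
so the hydrogen-bond pattern genuinely encodes the helix class.
`make_tetramer_pore` places carbon pseudo-atoms on rings with exact C4
symmetry and a prescribed wall-radius profile; the analytic pore radius
(wall − vdw) ships as a ground-truth sidecar. `make_synthetic_channel`
assembles an annotated C4 tetramer of six α-helices per protomer with an open
S5/S6 lumen; `perturb_copy` applies a seeded rigid motion plus Gaussian
coordinate noise (and rotates the annotated membrane normal with the model);
`make_random_fold` chains randomly oriented α-helical CA segments with short
linkers inside a sphere of radius `3.0 · n^{1/3}` — protein-like packing and
secondary-structure content, which is what makes its random-pair TM-score
baseline land near the documented ~0.3 value for unrelated proteins.

What the fixtures do **not** emulate: real side-chain rotamers and packing,
sequence-structure correlation, strand content, experimental noise models, or
genuine evolutionary divergence. Passing tests demonstrate algorithmic
correctness against analytic/enumerated ground truth, not field performance
on deposited structures; for real coordinate files the preprocessing
conventions above (chain-cycle anchor, radius set) are the knobs most likely
to shift results at the margin.

Problem sizes used by the test suite and acceptance script — 26–150-residue
folds, 6-structure families, ~4000-atom pore fixtures, 50 alignment pairs for
the baseline — were chosen as the smallest sizes at which each statistic is
stable (e.g. the random baseline's sampling spread is ≈0.03 at n = 50).

## Known limitations

* Pruned seeding (`top_k`) can in principle miss the global TM optimum on
  adversarial inputs; the exhaustive oracle bounds this only at small sizes.
* The MSA is reference-anchored; columns are undefined where the reference
  has no structural counterpart (e.g. a subfamily-specific pre-S1 element
  stays reference-only, other rows show gaps there).
* The profiler's plane-wise maximization assumes a roughly axis-aligned,
  singly connected lumen; severely tilted or branched pathways would need a
  curved-axis search.
* Constriction-site naming, membrane positioning, conductance estimation and
  figure rendering are out of scope.
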