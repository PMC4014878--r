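---
title: "Tree-guided game scoring and crowd-style MSA refinement: methods"
author: "phyloPuzzle authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-guided game scoring and crowd-style MSA refinement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloPuzzle)
```

`phyloPuzzle` implements the scoring and bookkeeping machinery of a
crowd-computing approach to multiple sequence alignment (MSA)
refinement: a fast, tree-aware objective that can be recomputed after
every edit, a protocol for cutting a parent MSA into puzzle-sized
blocks, and the admission/ranking/reinsertion logic that turns many
candidate block realignments into one improved parent alignment. This
vignette explains the model, the parameters that matter, the numerical
conventions, and the limits of what the test suite shows.

## The scoring model

An instance is a rectangular alignment over `{A,C,G,T,-}` together with
a rooted binary tree whose leaves map one-to-one onto the alignment
rows. Scoring proceeds in two stages.

**Ancestral reconstruction.** Each internal node receives a full-width
sequence by the two-pass Fitch parsimony algorithm applied independently
per column, with the gap treated as a fifth character state. Bottom-up,
a node's candidate set is the intersection of its children's sets, or
their union when the intersection is empty; each union event is one
substitution, and the per-column count of union events attains the
parsimony minimum over all internal assignments (the test suite checks
this against exhaustive enumeration on small instances). Top-down, ties
are broken deterministically: states are ordered `A < C < G < T < '-'`,
the root takes the smallest state in its set, and every other node keeps
its parent's state when possible, otherwise the smallest state in its
own set. Any Fitch-minimal labeling is an equally valid reconstruction;
the fixed order exists purely so that identical inputs always give
identical scores.

**Edge-sum affine scoring.** For every tree edge, the parent and child
sequences are projected to their induced pairwise alignment (columns
gapped in both are removed — a gap aligned to a gap is asserted never to
reach the scorer), and scored with integer game scores: match `+1`,
mismatch `-1`, gap opening `-4`, gap extension `-1`, values chosen to
approximate the BLASTZ costs while staying intuitive. A maximal gap run
of length $k$ costs $-4-(k-1)$ under the default convention that the
opening charge covers the first gap column; `ScoringParams(openCoversFirst
= FALSE)` switches to the alternative $-4-k$ reading. Gap runs touching
either end of a pairwise alignment are free and their columns contribute
nothing; this terminal-gap exemption removes the degenerate strategy of
pushing whole sequences sideways. The total is the sum over edges, and
`ScoreBreakdown` retains the per-edge decomposition (`total` always
equals the sum, by construction and by validity check).

**Ancestor editing.** Because columns are scored independently during
reconstruction, Fitch cannot see the affine coupling between neighbouring
columns and may fragment gap runs that a better labeling would merge.
`scoreWithAncestors()` therefore accepts an arbitrary user labeling —
the expert game's ancestor-editing feature. A minimal demonstration
ships as a fixture:

```{r fixture}
fx <- suboptimalAncestorFixture()
alnStrings(fx$aln)
totalScore(gameScore(fx$aln, fx$tree))                       # Fitch
totalScore(scoreWithAncestors(fx$aln, fx$tree, fx$edited))   # merged gap
```

Fitch propagates the root's `C` into the tied last column of the
`(a,b)` ancestor, stranding a non-terminal one-column gap that costs an
opening on the root edge; relabeling that ancestor `AA--` merges the gap
into a free terminal run and gains two points. The gain is computed by
the code at run time, not asserted as a constant.

### Invariants, and one that needed narrowing

Three exact invariants are enforced by tests: inserting an all-gap
column anywhere never changes the total; consistently renaming leaves
and rows never changes the total; and appending a column carrying the
same nucleotide in every row adds exactly `match × (2n−2)` on an
*n*-leaf binary tree. The last invariant holds **only when the final
column of the original alignment is gap-free**: otherwise the appended
column turns a free terminal gap run into a charged internal one and the
total moves by less. The tests state and use that precondition; it is a
genuine property of the terminal-gap exemption, not an implementation
artifact.

## Puzzle extraction

Casual levels are found by panning a reading frame of `frameWidth`
columns (default 20; the legal range is 10–20, read as the permissible
widths of a fixed-width scan rather than a per-frame search) from left
to right. For each frame the per-row ungapped nucleotide counts give a
mean and standard deviation, and the match ratio is the number of row
pairs per column sharing an identical nucleotide, summed over the frame,
divided by all `choose(n,2) × width` comparisons — pairs involving a gap
count as comparisons that failed to match, which is the natural reading
of "matches over all possible pairwise comparisons". A frame is accepted
iff `sd > 1` (strict) and the ratio lies in the inclusive window
`[0.32, 0.38]`; acceptance makes the frame jump past its columns, so
emitted blocks are disjoint, and rejection shifts it one column right.
The standard deviation is the population form (divide by `n`), with a
`sdType = "sample"` switch; the choice is documented rather than
principled, as either reading is defensible. Accepted blocks keep
exactly the non-empty rows (at least one nucleotide) of their region,
and are scored on the tree pruned to those rows.

Expert levels are 300-column windows (on a 400-column playing grid) cut
at starts 1, 151, 301, … — the stride defaults to half the width so
neighbouring blocks overlap, a choice this package fixes since only the
existence of overlap is documented for the deployed system — plus a
final right-aligned window so every column is covered.

Coordinates throughout are 1-based inclusive column ranges, the
R/Bioconductor convention.

## Admission, ranking, reinsertion

A candidate realignment of a block is admitted iff (i) every row's
ungapped sequence equals the snapshot's — players slide bricks, never
create or destroy nucleotides; violations are errors, not rejections —
(ii) its width fits the grid, and (iii) its game score on the pruned
tree is `>=` the initial block's score. Admitted solutions are ranked by
score with ties broken toward earlier submissions, and `topFraction()`
keeps the first `ceiling(0.4 × n)` — the observation behind the default
being that the best reinsertions concentrate among the top-ranked
solutions, so evaluating the rest wastes objective-function calls.
Ceiling (rather than floor) and 1-based ranks are this package's
conventions.

Reinsertion first deletes columns that are all-gap across the solution's
rows (so the padding of excluded rows is well defined), then splices the
solution into the block's column range, padding non-block rows with a
gap run of the solution's width. The result's width is
`ncols − blockWidth + solutionWidth`; per-row ungapped sequences are
invariant, and reinserting the unmodified snapshot is bit-exact the
identity. `evaluateCandidates()` scores each reinsertion with a
pluggable full-MSA objective (`function(PhyloMSA) -> numeric`, higher
better; the default is the game score on the full tree — external
objectives like consistency or likelihood scorers are deliberately not
bundled) and keeps the argmax per block; scorer failures are recorded
per candidate and never abort the batch. `prioritize()` implements the
task-routing rule: fewest plays first, stable.

## The simulator and the robot player

`randomTree()`/`evolveAlignment()` generate seeded instances: a uniform
random rooted binary tree, an i.i.d. uniform `ACGT` root sequence of
`rootLength` columns, per-edge per-site substitution with probability
`subProb` (resampling uniformly over all four nucleotides, so the
expected pairwise identity under saturation is 0.25), and at most one
indel event per edge with probability `indelProb` (deletion or insertion
with equal odds, geometric length with mean `indelMean`, uniform
position). True homology is preserved via a global site registry, so
gaps land exactly where lineages lost or never had a site; columns
gapped in every leaf are not emitted. The pipeline defaults — 12
leaves, 600 root columns, `subProb = 0.1`, `indelProb = 0.5`,
`indelMean = 3` — mimic one promoter-scale study alignment of a dozen
mammals at moderate divergence.

The simulated truth is, unsurprisingly, a local optimum of the game
score, so refining it verbatim honestly yields nothing. Real inputs to
a crowd system are *computed* alignments, which carry local
inaccuracies; `perturbAlignment()` therefore applies a fixed number of
random legal brick slides (default 40 for the 600-column pipeline run)
to emulate aligner error while conserving content. What the generator
does **not** emulate: realistic promoter base composition,
context-dependent substitution, rate variation across sites or
lineages, and multi-event indel histories per edge. Passing tests
therefore show the machinery is correct and the pipeline can recover
planted or perturbation-induced misalignments — they do not certify
improvement rates on real genomic data, which depend on the crowd and
the external objective.

The robot player (`hillClimb()`) performs first-improvement hill
climbing: each iteration enumerates the legal moves — slide one maximal
nucleotide run one column into an adjacent gap, or add a gap column at
either grid edge — shuffles them with the seeded RNG, and applies the
first strict improvement, recording every visited state scoring at
least the initial block as an admissible solution. First-improvement
with shuffled order was chosen over steepest ascent to emulate diverse
player trajectories cheaply; restarts add diversity for the ranking
tests, and `seedFrom = "best_known"` reproduces collaborative seeding
from the best submitted solution. The solver never edits ancestors;
ancestor editing is exercised through `scoreWithAncestors()` directly.

## Numerical and degenerate-input conventions

- Input sequences are uppercased; `.`, `*` and (by default) IUPAC
  ambiguity codes are rejected. With `allowN = TRUE`, `N` becomes a
  gap-free wildcard that mismatches everything (including `N`) and
  contributes `{A,C,G,T}` as its Fitch set — strictness keeps the
  scoring semantics unambiguous.
- Trees must be rooted and binary; multifurcations are rejected rather
  than silently resolved, because the edge sum is defined on a fixed
  edge set. Branch lengths are parsed and ignored: the score uses unit
  edges.
- Empty induced pairs (possible when two rows share no non-gap column)
  score 0. All-gap alignment rows are legal and survive round-trips.
- All randomness (simulation, perturbation, solver) flows from explicit
  integer seeds through a private RNG stream that restores the caller's
  `.Random.seed`.

## Problem sizes used by the validation suite

The acceptance-style tests run at sizes chosen to make exhaustive
oracles feasible: 200 random instances with at most 6 leaves and 12
columns against full enumeration of internal assignments; 1,000 random
induced pairs of length at most 50 against an independently written
two-state scanner; 50 random alignments against a brute-force reference
scan; 500 admitted solutions for reinsertion conservation; and one
end-to-end 12-leaf, 600-column pipeline run. `scripts/acceptance.R`
re-runs the pipeline and writes its computed headline quantities as
JSON.

## Known limitations

- Per-column Fitch reconstruction is knowingly sub-optimal under the
  affine model (that is precisely what ancestor editing is for); no
  exact affine-aware reconstruction is attempted.
- The casual filter's thresholds are the deployed constants, not tuned
  quantities; nothing in the package calibrates them.
- External objective functions are a plug-in contract, not bundled
  programs; the default full-MSA objective is the game score itself.
- The move set formalizes brick-sliding as single-run, single-column
  slides plus grid widening; multi-brick drags of the real interface
  are compositions of these but are not generated as single moves.
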