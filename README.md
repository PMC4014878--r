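# phyloPuzzle

Crowd-computing platforms turn small multiple sequence alignment (MSA)
problems into puzzles: short sub-alignments are cut from a parent MSA,
handed out as game levels, and the best player solutions are spliced back
to refine the parent alignment. `phyloPuzzle` implements the computational
core of such a system in R, with a robot player standing in for the human
crowd:

- **Game scoring.** An alignment with a rooted binary tree is scored by
  reconstructing one ancestral sequence per internal node with a
  per-column Fitch parsimony variant that treats the gap `-` as a fifth
  character, then summing, over every tree edge, the affine-gap score of
  the induced pairwise alignment of parent and child (both-gap columns
  dropped). With the default integer scores — match `+1`, mismatch `-1`,
  gap opening `-4`, gap extension `-1` — a maximal internal gap run of
  length *k* costs `-4 - (k-1)`, while gap runs touching either end of a
  pairwise alignment are free, so the total is
  `S = Σ_(u,v)∈E(T) s_affine(π(x_u, x_v))`.
- **Puzzle extraction.** Casual levels: a 10–20 column reading frame pans
  the MSA and is accepted when the standard deviation of per-row ungapped
  nucleotide counts exceeds 1 and the column-wise pairwise match ratio
  lies in [0.32, 0.38]; accepted frames jump past their columns so blocks
  never overlap. Expert levels: 300-column blocks on a 400-column grid,
  cut every 150 columns. Manual selection is also supported.
- **Crowd machinery.** Candidate realignments are admitted only when they
  preserve every row's nucleotides and score at least the initial block;
  admitted solutions are ranked by score, the top 40% are reinserted into
  the parent, and each block keeps the reinsertion that maximizes the
  full-MSA objective (game score by default; any `alignment -> score`
  function can be plugged in). Task routing favours least-played blocks.
- **Robot player and simulator.** A seeded first-improvement hill climber
  over the legal game moves (slide a nucleotide run into an adjacent gap,
  or widen the grid) stands in for gamers, and a seeded tree/alignment
  simulator with substitutions, indels, and content-preserving
  perturbation generates improvable study instances, so the whole
  pipeline runs without external data.

Expert-mode ancestor editing is exposed through `scoreWithAncestors()`:
because Fitch is applied per column, it cannot see the affine coupling
between neighbouring columns, and `suboptimalAncestorFixture()` ships a
minimal instance where a hand-merged gap run strictly beats the Fitch
labeling.

## Worked example

```r
library(phyloPuzzle)

aln  <- PhyloMSA(c(human = "ACGTAC--GTAC", chimp = "ACGTAC--GTAC",
                   mouse = "ACGTA-C-GTAC", rat   = "ACGTAC--GTAC"))
tree <- readTree("((human,chimp),(mouse,rat));")
gameScore(aln, tree)
#> ScoreBreakdown: total 51 over 6 edges
#>   matches 59, mismatches 0, gap openings 2, extensions 0
```

The mouse row carries a misplaced `C`. The ancestors are all
`ACGTAC--GTAC`, so the mouse edge pays two gap openings (its induced pair
is `ACGTA-C-GTAC` / `ACGTAC--GTAC`, score `1` instead of `10`). Sliding
that `C` one column left — a single legal game move — repairs the edge:

```r
fixed <- alnMatrix(aln); fixed["mouse", ] <- fixed["human", ]
totalScore(gameScore(PhyloMSA(fixed), tree))
#> [1] 60
```

which is exactly what the robot player finds. The end-to-end pipeline on
a simulated 12-species instance:

```r
res <- runPipeline(runConfig(seed = 2), quiet = FALSE)
#> simulated alignment 12 x 617 (seed 2, 40 perturbing slides)
#> extracted 9 casual blocks
#> solver produced 77 solutions
#> initial score 8645, best 8709
```

Here 7 of the 9 extracted blocks were improved by the robot crowd, and
the best single reinsertion raised the full-MSA game score by 64.

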