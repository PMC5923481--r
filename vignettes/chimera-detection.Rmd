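---
title: "Detecting chimeric two-domain replication proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chimeric two-domain replication proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repchimera)
```

## The problem

The replication-associated proteins (Reps) of circular Rep-encoding
single-stranded (CRESS) DNA viruses are built from two domains with
separable evolutionary histories: an N-terminal HUH endonuclease (conserved
motifs I–III) that nicks the replication origin, and a C-terminal
superfamily 3 helicase (Walker A, Walker B, motif C, arginine finger) that
unwinds the double-stranded intermediate. Intragenic recombination can pair
a nuclease from one lineage with a helicase from another. Such chimeric
Reps scramble phylogenies built from the full-length protein: a tree over
mixed-history sequences supports no consistent set of families. Before
proposing higher-level groups, chimeras have to be found and removed.

Nucleotide-level recombination detectors are of little use here: CRESS DNA
viruses routinely exceed the sequence divergence at which sliding-window
methods are reliable. `repchimera` therefore works entirely in protein
space, with two complementary detectors, and ships a synthetic-data
generator so that every stage is testable without any external dataset.

## The procedure

Given an aligned set of full-length Rep amino-acid sequences:

1. **Anchor and split.** The column-wise majority consensus is scanned for
   the Walker A P-loop pattern `[GA]-x(4)-G-K-[ST]`, restricted to the
   C-terminal half of the consensus (the helicase is C-terminal; the
   restriction avoids N-terminal P-loop lookalikes). The alignment is split
   at the first residue of the match: columns left of it form the nuclease
   block, the match onward forms the helicase block.
2. **Connectedness score.** For each protein, both domain sequences are
   compared against all other proteins' corresponding domains
   (local alignment, BLOSUM62, affine gaps, open 11 / extend 1). For each
   domain the top `max(1, floor(0.2 * H))` non-self hits are kept, where
   `H` is the number of non-self hits. The connectedness score is

   `score = |top_nuclease ∩ top_helicase| / k`,

   with `k` the top-set size. It estimates the probability that the best
   20% of hits found with either domain are the same proteins: near 1 when
   the domains co-evolved, near 0 when the helicase finds a different
   neighborhood than the nuclease. Scores below 0.2 flag likely
   recombinants.
3. **Tree displacement.** Per-domain trees are built from the trimmed
   domain blocks (see below), branches with bootstrap support below 70%
   are collapsed into polytomies, and the two trees are compared leaf by
   leaf: a leaf's neighborhood in a tree is the smallest clade (on the tree
   rooted at the leaf's farthest point) containing at least 5 other leaves,
   and its displacement is one minus the Jaccard similarity of its two
   neighborhoods. Displacement above 0.8 flags a leaf whose helicase sits
   among different relatives than its nuclease — the reproducible
   counterpart of spotting a taxon that changes position between the two
   sides of a tanglegram.
4. **Tiered calls.** Flagged by both detectors ⇒ `chimera`; by exactly one
   ⇒ `review`; by neither ⇒ `clean`. The two detectors have different
   reaches — hit-set overlap is most sensitive to recent swaps among close
   relatives, tree displacement to older transfers across clades — so
   disagreement is informative and is never silently auto-resolved. The
   `review` tier is the package's stand-in for case-by-case expert
   assessment; `--strict` mode treats it as `chimera`.
5. **Purge and regroup.** Called chimeras are removed (the `chimera` tier
   by default; strict mode also drops `review`), the full-length tree is
   rebuilt from the purged, trimmed alignment, and well-supported
   monophyletic groups are extracted (below). Because the default purge
   keeps review-tier sequences, groups recovered from a default-purged
   tree can still contain a sequence whose two domains disagree; when the
   goal is clean candidate families rather than a minimal removal list,
   the strict purge is the conservative choice — in simulation it yields
   groups whose members all share one (nuclease, helicase) clade pair.

## Trees without ML

Published analyses of this kind typically use maximum-likelihood inference
with model selection. This package deliberately substitutes
distance-based inference — saturation-corrected p-distances and neighbor
joining with a column-resampling bootstrap — to keep the core desk-scale
and dependency-free. Externally computed trees (for example PhyML output
with aBayes supports) can be supplied as Newick via `read_newick()`, which
rescales 0–1 posterior supports to the 0–100 scale used throughout, so the
ML route remains open as a plug-in.

The distance is the equal-input correction
`d = -p_max * ln(1 - p / p_max)` with `p_max = 0.95`, where `p` is the
mismatch fraction over columns in which both sequences are non-gap. The
0.95 ceiling is the equilibrium mismatch probability for 20 equally likely
residues and matches the generator's substitution model exactly. Pairs
sharing fewer than 20 columns give distances too noisy to use; they are set
to the matrix maximum with a warning, and a pair with no shared columns is
an error.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `top_fraction` | 0.2 | fraction of non-self hits | top-set size for the connectedness score |
| `score_threshold` | 0.2 | score units (0–1) | flag below this connectedness |
| `gap_keep_fraction` | 0.2 | fraction of sequences | keep columns with at least this non-gap fraction |
| `support_collapse` | 70 | percent | collapse branches below this support |
| `bootstrap_reps` | 100 | replicates | column-resampling bootstrap depth |
| `displacement_threshold` | 0.8 | Jaccard distance (0–1) | flag above this displacement |
| `neighborhood_min` | 5 | leaves | minimum neighborhood size for displacement |
| `seed` | 1 | — | governs all randomness downstream |

The first four are the field's conventional values for this analysis; the
displacement threshold and neighborhood size are this package's own
plumbing, calibrated on simulation (see below) and exposed because the
right neighborhood scale depends on clade sizes: `neighborhood_min` should
stay below the typical clade size, and `displacement_threshold` trades
sensitivity for specificity in the obvious direction.

Trimming is applied after splitting, and the Walker A anchor is located on
the untrimmed alignment: trimming first could delete motif columns and
shift the anchor. Connectedness is computed on the full (degapped) domain
sequences rather than the trimmed blocks, since pairwise local alignment
needs no column filtering; trimming matters for the distance matrices,
where gappy columns add noise.

## The synthetic-data generator

`simulate_rep_family()` emulates the statistical structure the detectors
assume, with ground truth:

* a guide tree of `n_clades` monophyletic clades (default 4) of
  `taxa_per_clade` taxa (default 12), scaled so taxa of the same clade
  diverge by about 0.2 substitutions/site and taxa of different clades by
  about 1.0 — within-family versus between-family distances typical of
  highly diverse ssDNA virus Reps;
* two domains evolved independently along that tree under an equal-input
  model (each site substitutes with probability `1 - exp(-t)` per branch,
  replacement drawn uniformly from the 20 amino acids), with the conserved
  motifs — HUH motifs I–III in the 160-residue nuclease, Walker A
  (`GPPGTGKT`, at helicase offset 0, so the domain split is exactly at the
  motif), Walker B, motif C and the arginine finger in the 120-residue
  helicase — frozen at fixed offsets;
* planted chimeras: for `floor(chimera_fraction * n)` randomly chosen taxa
  (default fraction 0.3), the helicase is replaced by that of a random
  taxon from a different clade, and the truth table records both clades.

What it does **not** emulate: insertions and deletions (sequences are
generated pre-aligned, isolating the detectors from aligner behaviour),
among-site rate variation, compositional bias, within-clade recombination,
and alignment error. Passing tests on simulated data therefore demonstrate
that the statistics behave as designed when their assumptions hold; on real
data, alignment quality and very short domains remain the user's
responsibility, and neither detector can resolve recombination between
near-identical genomes.

## Numerical choices

* **Determinism.** All randomness flows from the seed; hit rankings break
  score ties by subject id in C-locale byte order; NJ uses the standard
  deterministic agglomeration. Two runs with equal inputs and config
  produce byte-identical report bundles.
* **Top-set clamp.** `k = max(1, floor(fraction * H))`, so small databases
  still yield a defined score.
* **Tanglegram ordering.** Crossing minimization is NP-hard in general.
  For small binary problems (at most 16 internal nodes in both trees
  combined) the package enumerates all rotation states and is provably
  optimal; beyond that it alternates barycenter passes with greedy
  single-node flips until no improvement, and never returns a layout worse
  than the input order.
* **Group extraction.** An unrooted tree has no clades, so the purged tree
  is midpoint-rooted first — the midpoint falls on the long path between
  divergent groups, never inside a tight one. Edges below the support
  threshold are collapsed, and the tree is then decomposed from the basal
  node: a supported clade with at least `min_size` (default 5) leaves is
  reported whole unless it decomposes into two or more such groups — or
  into one group plus at least `min_size` unassigned leaves, which keeps a
  large unplaced block from being absorbed into a neighbouring group — in
  which case the subgroups are reported instead. The alternative "largest clade
  with all edges supported" rule is not used: chance-correlated signal in
  finite alignments regularly lends high bootstrap support to unions of
  clearly distinct families, and the maximal rule would merge them, while
  requiring support for every pre-collapse edge would reject almost
  everything, because shallow within-family edges are legitimately weak.
  The decomposition rule recovers exactly the planted families in
  simulation and degrades gracefully — a family with one supported
  subfamily stays whole.
* **Degenerate inputs.** All-gap logo columns report zero information and
  a flag; unknown branch supports are retained (never treated as 0) and
  warned about; a Walker A miss aborts with the consensus sequence in the
  error message.

## A worked example

A small family, one planted swap per ~4 taxa, and the whole pipeline:

```{r example}
sim <- simulate_rep_family(sim_spec(n_clades = 3, taxa_per_clade = 4,
                                    nuclease_len = 80, helicase_len = 60,
                                    chimera_fraction = 0.25, seed = 6))
res <- run_pipeline(sim$sequences, rep_config(seed = 6, bootstrap_reps = 50))
res
glance(res)
```

The per-protein view joins cleanly against the simulator's truth table:

```{r truth}
dplyr::inner_join(tidy(res), sim$truth, by = "id") |>
  dplyr::count(tier, is_chimera)
```

`autoplot(res)` draws the two detector statistics against each other with
the decision thresholds; `plot_tanglegram(res$tanglegram)` and
`plot_logo(res$logo_walker_a)` show the ordered tanglegram and the Walker A
logo.

## Problem sizes

The package's own test suite and acceptance script run the full pipeline on
families of 48 taxa (4 clades × 12), domains of 160 + 120 residues and 100
bootstrap replicates — the scale at which the default thresholds were
calibrated — plus many smaller constructed instances with exhaustive or
closed-form oracles. These desk-scale sizes are a deliberate design point:
they are large enough for the bootstrap and the hit-set statistics to be
informative and small enough to re-run everywhere.

## Known limitations

* Distance-based trees are a pragmatic substitute, not a replacement, for
  ML inference on hard datasets; use the Newick import for serious
  phylogenies.
* The displacement statistic depends on the collapse threshold: on poorly
  supported trees most structure collapses and displacement loses power
  (it can only compare what the trees resolve).
* Connectedness assumes the database contains several relatives of each
  query in both domains; for a lone representative of its family the score
  is dominated by distant noise hits.
* Neither detector resolves recombination between closely related genomes,
  and breakpoints inside a domain are out of scope by construction.
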