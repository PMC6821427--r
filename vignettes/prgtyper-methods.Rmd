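---
title: "Projection-based graph alignment and HLA-style genotyping: models and design"
author: "prgtyper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-based graph alignment and HLA-style genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prgtyper)
```

# The problem

Hyperpolymorphic loci such as the classical HLA genes defeat alignment
against a single linear reference: reads from a diverged allele accumulate
mismatches and misplaced gaps, and genotypes inferred from such alignments
are unreliable. A population reference graph (PRG) — a sequence graph built
from a multiple sequence alignment (MSA) of many known haplotypes and
alleles — gives every known variant a path to align against. Full
sequence-to-graph alignment is expensive, however. This package implements a
hybrid: reads are first aligned *linearly* against one of the haplotypes the
graph was built from (standard mappers do this well), that linear alignment
is *projected* onto the graph, and only the parts of the projection that
look wrong are re-optimized by graph dynamic programming.

# The column-structured graph

`buildPrg()` turns an aligned panel (an `MsaPanel`) into a `PrgGraph` with
one *level* per MSA column. Each level carries one edge per distinct symbol
observed in that column (`A,C,G,T,N` or the gap symbol `-`), annotated with
the set of sequences exhibiting it; a full path traverses exactly one edge
per level, and `-` edges spell nothing.

Nodes sit at column boundaries and control which recombinant traversals
exist. The MSA does not dictate a unique node-merging rule, so one had to be
chosen. We merge two sequences at a boundary whenever they can be linked by
a chain of shared symbols in either adjacent column (the transitive closure
of "same symbol in the left column or same symbol in the right column").
Consequences we rely on:

* every (level, label) pair is exactly one edge, so the graph's size is
  bounded by the number of distinct symbols per column;
* re-convergence is maximal: wherever two haplotypes agree in a column they
  can exchange, which gives the polishing step the freedom it needs;
* the rule is deterministic, so rebuilding from the same panel is
  bit-identical (tested).

Exon-only allele sequences are carried as *partial rows*: outside their
covered blocks they hold the absent marker `*`, contribute no edges, and
have `NA` entries in their haplotype paths. Within a block they behave like
any row (including genuine `-` gap columns).

# Projection and the three-stage optimization

`projectAlignment()` maps a SAM-style linear alignment (CIGAR against one
full-length haplotype) onto the graph: each aligned base lands on the
haplotype's edge at the level of its reference residue, deletions advance
levels as read-gap cells, and gap columns of the haplotype are traversed
transparently (zero score, gap runs not interrupted). Inserted read bases
are placed onto the haplotype's *gap columns* at the insertion site when
such columns exist, by a small graph DP over the gap-column run anchored at
the flanking reference nodes; only bases the run cannot accommodate become
"floating" insertions attached to the preceding level. This placement
matters: an insertion relative to one haplotype is usually an MSA column
where that haplotype is gapped, so an exact, connectivity-aware placement
lets the fixed-level polishing step repair MSA-consistent insertions
without any later re-alignment (a label-based heuristic is not enough:
several columns of the run may carry the right symbol, but only one of
them connects). Leading insertions use the gap-column run immediately to
the left of the first aligned residue.

Three stages follow.

**Inspection** (`inspectAlignment()`) excises regions whose *local gap
structure* suggests level misassignment: every run of insertion/deletion
cells totalling at least `gapTriggerLen` (default 2) is removed together
with `flankW` (default 5) aligned bases on each side, into
`removed` intervals. In long-read mode inspection is the identity — indels
are expected there and carry no positional signal.

**Polishing** (`polishAlignment()`) holds every read base's level fixed and
re-chooses the edge at each level by dynamic programming over boundary
nodes (Rcpp kernel), with transitions restricted to graph edges and the
affine gap state carried through. Contiguous level segments are polished
independently. The DP provably contains the original choice, so the score
never decreases; a brute-force enumeration oracle
(`polishEnumerationScore()`, which scores every edge-choice path with the
same scorer) agrees on 500/500 random instances in the acceptance suite.

**Extension** (`extendAlignment()`) re-aligns everything not yet
represented — inspection removals, floating end insertions, and soft-clipped
read ends — by full graph DP anchored at the flanking retained cells. Mid
intervals run banded (half-width `2·len + 10` around the anchor diagonal)
with an unbanded retry; if the graph's node structure admits no connection
at all, the whole read falls back to one exhaustive `fullGraphAlign()` call,
the same escape hatch used for haplotype-switching reads. Read ends may
remain soft-clipped only where they fall outside the graph's level range.
Reads that projected cleanly skip this stage entirely; the skip fraction is
reported per sample and equals 1.0 in the error-free study condition.

After the three stages, one global check remains: a short-mode read whose
score is still below the perfect-match score for its length may have
switched between divergent haplotypes in a way the local gap-structure
heuristics cannot see (a multi-column insertion site can admit several
locally clean placements of which only one is globally consistent). Such
reads switch into full graph alignment mode and keep the better result.
Reads that project cleanly — the overwhelming majority at realistic error
rates, and all reads in the error-free condition — never reach this check,
which is what makes the hybrid cheap; at a 0.3% substitution error rate
roughly a quarter of 100 bp reads carry at least one error and pay for one
exhaustive alignment.

`fullGraphAlign()` itself is an exhaustive affine-gap semi-global DP over
all level paths (free leading/trailing level skips, end clips free only at
the graph boundaries). It doubles as the oracle: the hybrid pipeline's
score can never exceed it, and equals it whenever the read is an exact
substring of a spelled path (both tested at scale).

## Scoring

One scorer (`scoreGraphAlignment()`, shared C++ code with all DPs) defines
the objective: match `+1`, mismatch `-4`, gap open `-6`, gap extend `-1`, a
run of k gap cells costing `open + (k-1)·extend`; `N` scores 0 against
anything; a read gap meeting a gap edge is transparent (scores 0 and does
not interrupt a gap run, so deleting across a column the haplotype also
lacks costs nothing). The numbers are mapper-like defaults and fully
configurable through `scoringScheme()`; all internal coordinates are
0-based half-open, converted from SAM's 1-based convention at the I/O
boundary.

# Genotyping

For each locus the diploid genotype is the unordered allele pair maximizing
the read-set likelihood. Per read r and allele a,
`readAlleleLogLik()` walks the read's graph alignment against the allele's
column row: matches contribute `log(1-s)`, mismatches `log(s/3)`, indel
runs `log(open) + (k-1)·log(extend)`. Short-mode defaults are
`s = 0.003`, indel open `1e-4`, extend `0.1`; long mode raises them to
`s = 0.01`, open `0.03`, extend `0.3`, reflecting the indel-dominated error
profile of nanopore/PacBio reads. Columns an exon-only allele does not
cover are skipped and not counted as evaluated.

The pair score is `Σ_r log(½ P(r|a1) + ½ P(r|a2))`, computed in log space.
Mixing happens on the whole-read scale: per-read values are rescaled to the
read's maximum evaluated-column count, which is exactly the raw whole-read
log-likelihood when the database is all-genomic and keeps exon-only and
genomic alleles on one scale otherwise. (Mixing per-column-averaged
likelihoods instead collapses the heterozygote/homozygote contrast to a few
hundredths of a log unit per read and makes calls unstable — we measured
this directly, which is why the whole-read scale is used.) A uniform prior
over unordered pairs turns the scores into a posterior; the best pair is
reported with `Q` = its posterior and flagged `called` when `Q ≥ 0.7`
(configurable; the threshold trades call rate against accuracy). Ties break
lexicographically. One known limitation: when an exon-only allele explains
all exon-overlapping reads as well as the genomic truth does, the
normalized comparison cannot separate them — the familiar ambiguity of
exon-only typing.

# Assembly typing

Contigs are typed without reads. Candidate (contig, haplotype) pairs share
an exact anchor of ≥ 20 bp (`identifyOverlappingContigs()`); for each pair,
gap-free exact-match *diagonals* (maximal exact matches, k-mer located, k =
15 by default; `findDiagonals()`) are chained by DP
(`chainSemiglobal()`) into the highest-scoring strictly monotone traversal
of the alignment matrix: diagonals score `length·match`, horizontal
(reference-skip) and vertical (contig-skip) jumps pay an affine penalty
(open `-6`, extend `-0.5`), and leading/trailing reference skips are free
(semi-global: global in the contig). Overlapping diagonals are reconciled
by minimally trimming the downstream start — one can show any split of the
trim between the two diagonals scores identically, so this loses no
optima — and with exhaustive single-cell anchors the chain score equals a
full-matrix semi-global DP under the same gap model
(`semiglobalDpScore()`, tested 200/200).

The best-scoring haplotype's annotations are projected through the chain's
base-level coordinate map (`projectAnnotations()`); jump interiors are
re-aligned globally (equal-length jumps map diagonally as substitution
runs; unequal ones through `Biostrings::pairwiseAlignment`, capped at 2 kb)
so feature boundaries stay base-accurate. Features inside reference skips
are flagged unprojectable; partial overlaps are truncated and flagged. Gene
sequences extracted from the projected coordinates are matched against the
allele database by global Levenshtein distance (`utils::adist`), genomic
gene sequences against genomic alleles or concatenated exons against
exon-only alleles; each gene yields at most one call per contig, resolved
by lowest edit distance then longest span.

# The simulator and what passing tests mean

`simulatePanel()` generates, per locus, an ancestral sequence and derives
haplotypes and alleles by per-base substitution (and optional geometric
indels), with the MSA induced by tracked coordinates — no heuristic
realignment, so truth alignments are exact. A gene spanning the central 80%
of the locus with two exon blocks is annotated on every haplotype.
`simulateReads()` draws reads uniformly from the two truth alleles, applies
substitution/indel errors, and emits the true CIGAR against the allele's
nearest haplotype, composed through the MSA; with probability
`misprojectionProb` a record instead targets a random other haplotype with
a naive all-M CIGAR — the wrong-level/wrong-edge inputs the optimizer must
repair. `simulateContigs()` splices an allele's gene region into a
haplotype background and applies point edits. Everything is reproducible
from one seed.

The reference study conditions (the generator defaults) are: one 1 kb
locus, 5 haplotypes, 20 alleles at 1% substitution divergence, 30× coverage
of 100 bp reads with 0.3% substitution error and 5% misprojection; the
long-read condition uses a 2 kb locus covered by full-length reads at 10×
with 1% substitution + 5% indel error; panels for the alignment-oracle
checks use 8% divergence with 2% indel events, chosen once as
representative of diverged haplotype panels. Panel indels default to zero:
the substitution-only panel is what makes the error-free extension-skip
statistic exactly 1.0, and it matches the stated conditions of the recovery
checks. The simulator emulates neither coverage bias, quality-score
miscalibration, chimeric reads nor platform-specific error motifs, so
passing recovery tests demonstrates the correctness of the machinery under
its model, not field accuracy on real sequencing data.

Problem sizes used by the acceptance suite: 500 polish-oracle instances
(≤ 8 haplotypes, ≤ 30 levels), 500 hybrid-vs-oracle instances plus 200
substring reads, 50 short-read and 25 long-read diploid replicates, 200
chaining pairs (≤ 120 bp), and 2 × 50 contigs — sizes at which the
exhaustive oracles are still exact and the full suite runs in minutes on
one core.

## Stage-score accounting

Each stage reports the score of its own alignment (removed intervals and
clips contribute zero). Projection–polishing–extension is monotone in score
whenever inspection removes nothing — the polishing DP contains the
original edge choice, and extension only runs DPs anchored to retained
cells — which covers every read of the substitution-only study conditions.
When inspection does excise a region whose flanking matches outweighed its
indel penalty, the interim score dips and recovers at extension; the
invariant that always holds is that the final alignment never scores below
the initial projection, and that every read base sits in exactly one of
cells, removed intervals or clips after every stage. The acceptance suite
asserts exactly these two forms.

# Numerical and degenerate-input choices

* All DP tie-breaks prefer the lexicographically smaller edge label, then
  the lower node index; chain ties prefer the leftmost chain. Everything is
  single-threaded and deterministic.
* Likelihood computations stay in log space; pair mixtures use the
  max-trick; posteriors normalize to 1 within 1e-9 (asserted per call).
* Empty inputs degrade explicitly: an empty cell list scores 0, a locus
  with no retained reads is returned uncalled with a reason, a contig with
  no anchors produces no calls, and an empty diagonal set yields a
  zero-score alignment flagged unalignable.
* A read whose record starts beyond its reference's length is discarded
  and counted.

# Session info

```{r}
sessionInfo()
```
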