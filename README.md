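# prgtyper

HLA-style genotyping of hyperpolymorphic loci from linearly projected graph
alignments, in R.

At loci like the classical HLA genes, alignment against one linear
reference sequence breaks down: reads from diverged alleles pick up
mismatches and misplaced gaps, and genotypes inferred from them are
unreliable. `prgtyper` aligns reads against a **population reference graph
(PRG)** — an acyclic sequence graph built from a multiple sequence
alignment of known haplotypes and allele sequences, with one *level* per
alignment column — but avoids paying for full sequence-to-graph dynamic
programming on every read. Instead, an existing linear alignment of the
read against one of the graph's own haplotypes is **projected** onto the
graph and repaired in three stages:

1. **inspection** — excise bases near long indel runs, whose level
   assignment is suspect (skipped for long reads, where indels are
   expected);
2. **polishing** — re-choose the best edge at every fixed level by dynamic
   programming over the graph's boundary nodes;
3. **extension** — re-align the excised bases and clipped read ends by
   (banded) full graph DP anchored at the retained cells; most reads never
   need this step.

Diploid genotypes per locus maximize the read-set mixture likelihood over
unordered allele pairs (a₁,a₂),

&nbsp;&nbsp;&nbsp;&nbsp;argmax over (a₁,a₂) of Σᵣ log(½ P(r|a₁) + ½ P(r|a₂)),

with per-read allele likelihoods from a substitution/affine-indel error
model evaluated along the graph alignment (separate short-read and
long-read rates), and a posterior-based call quality Q. Assembled contigs
are typed separately: exact-match *diagonals* against each reference
haplotype are chained into a semi-global alignment by DP, the best
haplotype's gene/exon annotations are projected onto the contig, and the
extracted gene sequence is matched to the allele database by minimum edit
distance, once per gene per contig.

A self-contained simulator generates haplotype panels, allele databases,
diploid truth genotypes, error-bearing short/long reads with SAM records,
and contigs, so the entire pipeline is testable end to end without any
external data.

## Worked example

A three-row panel shows the graph's column structure — one edge per symbol
per column, with a gap edge where a row is deleted:

```r
library(prgtyper)
panel <- msaPanel(c(H1 = "ACGT", H2 = "ACAT", H3 = "AC-T"))
g <- buildPrg(panel)
g
#> PrgGraph 'locus1': 4 levels, 6 edges, 5 nodes, 3 sequences
subset(prgEdges(g), level == 2)[, c("level", "from", "to", "label")]
#>   level from to label
#> 3     2    3  4     -
#> 4     2    3  4     A
#> 5     2    3  4     G
```

One simulated diploid replicate under the default study conditions (1 kb
locus, 20 alleles at 1% divergence, 30x coverage of 100 bp reads with 0.3%
substitution error and 5% of records deliberately misprojected onto the
wrong haplotype), typed end to end:

```r
res <- simulateAndType(simConfig(seed = 42))
res$calls$locus1
#> GenotypeCall locus1: (locus1_A01, locus1_A16) Q=1.000 called [300 reads]
res$truth@truth$locus1
#> [1] "locus1_A01" "locus1_A16"
unlist(res$summary[c("callRate", "extensionSkipFraction", "discardedReads")])
#>              callRate extensionSkipFraction        discardedReads
#>             1.0000000             0.8066667             0.0000000
```

The call matches the simulated truth pair with posterior Q = 1. The
extension-skip fraction records that ~81% of reads were resolved by
projection + polishing alone, never paying for a full graph alignment —
the mechanism that makes the hybrid approach cheap; with error-free reads
the fraction is exactly 1.

A command-line entry point with `build`, `type`, `type-assembly` and
`simulate` subcommands is installed at `inst/scripts/prgtyper`:

```sh
Rscript inst/scripts/prgtyper simulate --seed 5 --out simdir
Rscript inst/scripts/prgtyper build --msa simdir/locus1_panel.fasta \
    --locus locus1 --out graph.jsonl
Rscript inst/scripts/prgtyper type --graph graph.jsonl \
    --sam simdir/reads.sam --annotations simdir/annotations.tsv \
    --out calls.tsv
```

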