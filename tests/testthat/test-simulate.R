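test_that("zero divergence gives identical alleles and a linear graph", {
  truth <- simulatePanel(simConfig(seed = 1, divergence = 0,
                                   nAllelesPerLocus = 4L, locusLen = 80L))
  seqs <- truth@dbs$locus1@seqs
  expect_true(all(seqs == seqs[1L]))
  prg <- buildPrg(truth@panels$locus1)
  expect_equal(nrow(prgEdges(prg)), prg@levelCount)
})

test_that("simulation is byte-reproducible under a fixed seed", {
  cfg <- simConfig(seed = 77, indelProb = 0.01, locusLen = 150L)
  t1 <- simulatePanel(cfg); t2 <- simulatePanel(cfg)
  expect_identical(t1@panels$locus1@rows, t2@panels$locus1@rows)
  expect_identical(t1@truth, t2@truth)
  r1 <- simulateReads(t1, cfg); r2 <- simulateReads(t2, cfg)
  expect_identical(r1$sam, r2$sam)
  c1 <- simulateContigs(t1, 3L, 2L); c2 <- simulateContigs(t2, 3L, 2L)
  expect_identical(c1$contigs, c2$contigs)
})

test_that("pairwise allele divergence matches the closed-form expectation", {
  len <- 2000L; div <- 0.02
  truth <- simulatePanel(simConfig(seed = 13, divergence = div,
                                   nAllelesPerLocus = 8L, locusLen = len))
  seqs <- truth@dbs$locus1@seqs
  pairs <- combn(length(seqs), 2L)
  obs <- mean(apply(pairs, 2L, function(p)
    sum(strsplit(seqs[p[1L]], "")[[1L]] != strsplit(seqs[p[2L]], "")[[1L]])))
  ## two independent mutants differ at a site unless neither mutated or
  ## both hit the same target base
  expected <- (2 * div * (1 - div) + (2 / 3) * div^2) * len
  sd3 <- 3 * sqrt(expected)
  expect_lt(abs(obs - expected), sd3 + 0.05 * expected)
})

test_that("read count follows coverage arithmetic", {
  cfg <- simConfig(seed = 2, coverage = 30, locusLen = 1000L,
                   readLen = 100L, misprojectionProb = 0)
  truth <- simulatePanel(cfg)
  reads <- simulateReads(truth, cfg)
  expect_equal(nrow(reads$sam), 300L)
  expect_true(all(reads$provenance$allele %in% truth@truth$locus1))
})

test_that("error-free, misprojection-free reads align at perfect score", {
  ## the allele's own path is in the graph, so after polishing the
  ## (substitution-only) differences to the nearest haplotype vanish
  cfg <- simConfig(seed = 3, readSubRate = 0, misprojectionProb = 0,
                   locusLen = 300L)
  truth <- simulatePanel(cfg)
  prg <- buildPrg(truth@panels$locus1)
  reads <- simulateReads(truth, cfg)
  for (i in sample(nrow(reads$sam), 20L)) {
    ga <- alignRead(
      linearAlignment(reads$sam$qname[i], reads$sam$seq[i],
                      reads$sam$rname[i], reads$sam$pos[i] - 1L,
                      reads$sam$cigar[i]), prg)
    expect_equal(ga@score, nchar(reads$sam$seq[i]) * 1)
    expect_false(ga@meta$extensionRan)
  }
})

test_that("long-mode CIGAR indel rate sits within binomial bounds", {
  cfg <- simConfig(seed = 5, locusLen = 2000L, readLen = 500L,
                   coverage = 10, mode = "long", readSubRate = 0.01,
                   readIndelRate = 0.05, misprojectionProb = 0)
  truth <- simulatePanel(cfg)
  reads <- simulateReads(truth, cfg)
  ops <- GenomicAlignments::explodeCigarOps(reads$sam$cigar)
  nIndelEvents <- sum(vapply(ops, function(o) sum(o %in% c("I", "D")), 0L))
  nBases <- sum(nchar(reads$sam$seq))
  p <- cfg@readIndelRate
  expect_lt(abs(nIndelEvents / nBases - p), 3 * sqrt(p * (1 - p) / nBases))
})

test_that("misprojected records carry naive CIGARs on other haplotypes", {
  cfg <- simConfig(seed = 6, misprojectionProb = 1, locusLen = 300L)
  truth <- simulatePanel(cfg)
  reads <- simulateReads(truth, cfg)
  expect_true(all(reads$provenance$misprojected))
  expect_true(all(grepl("^[0-9]+M$", reads$sam$cigar)))
})

test_that("contig truth labels allow distance-zero recovery", {
  truth <- simulatePanel(simConfig(seed = 9, locusLen = 400L))
  sim <- simulateContigs(truth, nContigs = 4L, nEdits = 0L)
  for (i in seq_len(4L)) {
    a <- sim$truthLabels$allele[i]
    geneSeq <- truth@dbs$locus1@geneSeqs[match(a, truth@dbs$locus1@ids)]
    expect_true(grepl(geneSeq, sim$contigs[[i]], fixed = TRUE))
  }
})
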