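test_that("diagonals: identical sequences, split at substitutions", {
  s <- randomSeq(100)
  d <- findDiagonals(s, s, k = 15L, minLen = 20L)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$cs, d$ce, d$rs, d$re), c(0L, 100L, 0L, 100L))
  s2 <- paste0(substr(s, 1, 50),
               setdiff(c("A", "C", "G", "T"), substr(s, 51, 51))[1L],
               substr(s, 52, 100))
  d2 <- findDiagonals(s2, s, k = 15L, minLen = 20L)
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$ce[1L], 50L)
  expect_equal(d2$cs[2L], 51L)
})

test_that("k-mer diagonals equal the quadratic maximal-exact-match scan", {
  set.seed(200)
  for (i in 1:10) {
    a <- randomSeq(150)
    b <- mutateSeq(a, 0.05)
    dk <- findDiagonals(b, a, k = 8L, minLen = 8L)
    de <- exhaustiveDiagonals(b, a)
    de <- de[de$len >= 8L, ]
    key <- function(d) sort(do.call(paste, d[, c("cs", "ce", "rs", "re")]))
    expect_equal(key(dk), key(de))
  }
})

test_that("chaining: single diagonal, contig insertion, empty input", {
  d1 <- data.frame(cs = 0L, ce = 100L, rs = 0L, re = 100L, len = 100L)
  ch <- chainSemiglobal(d1, 100L, 100L)
  expect_equal(nrow(ch@diagonals), 1L)
  expect_equal(ch@score, 100)
  expect_equal(nrow(ch@jumps), 0L)

  ## two co-linear diagonals separated by a 10-base contig insertion
  sc <- chainScoring()
  d2 <- data.frame(cs = c(0L, 60L), ce = c(50L, 110L),
                   rs = c(0L, 50L), re = c(50L, 100L), len = c(50L, 50L))
  ch2 <- chainSemiglobal(d2, 110L, 100L)
  expect_equal(nrow(ch2@diagonals), 2L)
  expect_equal(ch2@jumps$v, 10L)
  expect_equal(ch2@score,
               100 + sc$jumpOpen + 9 * sc$jumpExtend)

  ch0 <- chainSemiglobal(d1[0, ], 50L, 50L)
  expect_true(ch0@unalignable)
  expect_equal(ch0@score, 0)
})

test_that("chain score equals full semi-global DP with exhaustive anchors", {
  set.seed(300)
  for (i in 1:30) {
    n <- sample(40:120, 1L)
    a <- randomSeq(n)
    b <- mutateSeq(a, runif(1, 0, 0.1))
    d <- exhaustiveDiagonals(b, a)
    ch <- chainSemiglobal(d, nchar(b), nchar(a))
    expect_equal(ch@score, semiglobalDpScore(b, a))
    ## chain validity: strictly monotone, score recomputes from parts
    if (nrow(ch@diagonals) > 1L) {
      expect_true(all(diff(ch@diagonals$cs) > 0))
      expect_true(all(diff(ch@diagonals$rs) > 0))
    }
    sc <- chainScoring()
    aff <- function(g) if (g > 0) sc$jumpOpen + (g - 1) * sc$jumpExtend else 0
    recomputed <- sum(ch@diagonals$len) * sc$match +
      sum(vapply(ch@jumps$h, aff, 0)) + sum(vapply(ch@jumps$v, aff, 0)) +
      aff(ch@diagonals$cs[1L]) +
      aff(ch@contigLen - ch@diagonals$ce[nrow(ch@diagonals)])
    expect_equal(ch@score, recomputed)
  }
})

test_that("candidate identification by shared anchors", {
  set.seed(310)
  haps <- c(h1 = randomSeq(300), h2 = randomSeq(300))
  contigs <- c(c1 = haps[["h1"]],
               c2 = randomSeq(250),
               c3 = paste0(substr(haps[["h1"]], 1, 100),
                           substr(haps[["h2"]], 101, 200)))
  cand <- identifyOverlappingContigs(contigs, haps)
  expect_true(any(cand$contig == "c1" & cand$haplotype == "h1"))
  expect_false("c2" %in% cand$contig)
  expect_setequal(cand$haplotype[cand$contig == "c3"], c("h1", "h2"))
})

test_that("best haplotype selection and lexicographic ties", {
  set.seed(320)
  h2 <- randomSeq(300)
  haps <- c(hapA = mutateSeq(h2, 0.05), hapB = h2, hapC = mutateSeq(h2, 0.08))
  ch <- bestHaplotype(h2, "c", haps, k = 12L, minLen = 12L)
  expect_equal(ch@haplotypeId, "hapB")
  ## exact tie between duplicated haplotypes resolves to the first id
  ch2 <- bestHaplotype(h2, "c", c(zzz = h2, aaa = h2), k = 12L,
                       minLen = 12L)
  expect_equal(ch2@haplotypeId, "aaa")
})

test_that("annotation projection: identity, shifts, unprojectable", {
  hap <- randomSeq(200)
  ann <- annotationsToGRanges(data.frame(
    haplotype_id = "h", locus = "locus1", feature_kind = "gene",
    exon_index = NA, start = 50L, end = 150L))
  d <- exhaustiveDiagonals(hap, hap)
  ch <- chainSemiglobal(d, 200L, 200L, contigId = "c", haplotypeId = "h")
  f <- projectAnnotations(ch, ann)
  expect_equal(c(f$contig_start, f$contig_end), c(50L, 150L))
  expect_equal(f$status, "projected")

  ## 10-base contig insertion before the gene shifts it by +10
  contig <- paste0(substr(hap, 1, 20), randomSeq(10), substr(hap, 21, 200))
  ch2 <- chainSemiglobal(exhaustiveDiagonals(contig, hap), 210L, 200L,
                         contigId = "c", haplotypeId = "h",
                         contigSeq = contig, refSeq = hap)
  f2 <- projectAnnotations(ch2, ann)
  expect_equal(c(f2$contig_start, f2$contig_end), c(60L, 160L))

  ## feature entirely inside a reference skip is unprojectable
  contig3 <- paste0(substr(hap, 1, 40), substr(hap, 161, 200))
  ch3 <- chainSemiglobal(exhaustiveDiagonals(contig3, hap), 80L, 200L,
                         contigId = "c", haplotypeId = "h")
  f3 <- projectAnnotations(ch3, ann)
  expect_equal(f3$status, "unprojectable")
})

test_that("database matching: exact, tie-break, triangle bound", {
  db <- new("AlleleDatabase", locus = "L", ids = c("ACAT", "AGGT"),
            seqs = c("ACAT", "AGGT"), rows = c("ACAT", "AGGT"),
            coverage = c("genomic", "genomic"),
            geneSeqs = c("ACAT", "AGGT"), exonSeqs = c("", ""))
  m <- matchDatabase("ACAT", db)
  expect_equal(m$alleleId, "ACAT")
  expect_equal(m$editDistance, 0L)
  m2 <- matchDatabase("ACGT", db)   # distance 1 to both
  expect_equal(m2$editDistance, 1L)
  expect_equal(m2$alleleId, "ACAT") # lexicographic winner
  expect_error(matchDatabase("", db), "empty")
  set.seed(9)
  for (i in 1:10) {
    s <- randomSeq(60)
    edited <- mutateSeq(s, 3 / 60)
    db2 <- new("AlleleDatabase", locus = "L", ids = "x", seqs = s,
               rows = s, coverage = "genomic", geneSeqs = s, exonSeqs = "")
    expect_lte(matchDatabase(edited, db2)$editDistance, adist(s, edited))
  }
})

test_that("contig typing recovers the spliced allele end to end", {
  truth <- simulatePanel(simConfig(seed = 21, locusLen = 600L))
  haps <- vapply(truth@haplotypeIds$locus1, function(h)
    ungappedSequence(truth@panels$locus1, h), "")
  sim <- simulateContigs(truth, nContigs = 6L, nEdits = 0L)
  calls <- typeAssembly(sim$contigs, haps, truth@annotations, truth@dbs)
  m <- merge(calls, sim$truthLabels, by = "contig")
  expect_equal(nrow(m), 6L)
  expect_true(all(m$allele.x == m$allele.y))
  expect_true(all(m$edit_distance == 0L))
  ## with 3 edits: reported distance bounded by the edit count
  sim3 <- simulateContigs(truth, nContigs = 6L, nEdits = 3L)
  calls3 <- typeAssembly(sim3$contigs, haps, truth@annotations, truth@dbs)
  expect_true(all(calls3$edit_distance <= 3L))
})

test_that("a duplicated gene region yields a single call per contig", {
  truth <- simulatePanel(simConfig(seed = 23, locusLen = 500L))
  haps <- vapply(truth@haplotypeIds$locus1, function(h)
    ungappedSequence(truth@panels$locus1, h), "")
  dup <- paste0(haps[[1L]], haps[[1L]])
  calls <- typeAssembly(c(dup1 = dup), haps, truth@annotations, truth@dbs)
  expect_equal(sum(calls$contig == "dup1" & calls$locus == "locus1"), 1L)
  ## contig with no anchor match yields no calls
  none <- typeAssembly(c(x = randomSeq(400)), haps, truth@annotations,
                       truth@dbs)
  expect_equal(nrow(none), 0L)
})
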