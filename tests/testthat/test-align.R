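scheme <- scoringScheme()   # match 1, mismatch -4, open -6, extend -1

test_that("projection follows the CIGAR on the example graph", {
  g <- buildPrg(threeRowPanel())
  ga <- projectAlignment(linearAlignment("r", "ACGT", "H1", 0, "4M"), g,
                         scheme)
  expect_equal(ga@score, 4 * scheme@match)
  expect_equal(ga@cells$edge, unname(haplotypePath(g, "H1")))

  ga2 <- projectAlignment(linearAlignment("r", "ACAT", "H1", 0, "4M"), g,
                          scheme)
  expect_equal(ga2@score, 3 * scheme@match + scheme@mismatch)

  ga3 <- projectAlignment(linearAlignment("r", "ACT", "H1", 0, "2M1D1M"),
                          g, scheme)
  expect_equal(ga3@score, 3 * scheme@match + scheme@gapOpen)
  expect_equal(ga3@cells$base[3L], "-")
})

test_that("projection errors on unknown or partial references", {
  g <- buildPrg(msaPanel(c(H1 = "ACGT", A1 = "AC*T"), partial = "A1"))
  expect_error(projectAlignment(
    linearAlignment("r", "AC", "H9", 0, "2M"), g), "not a sequence")
  expect_error(projectAlignment(
    linearAlignment("r", "AC", "A1", 0, "2M"), g), "full-length")
  expect_error(projectAlignment(
    linearAlignment("r", "ACGTA", "H1", 2, "5M"), g), "exceeds")
})

test_that("affine scoring: runs, transparency, clips", {
  g <- buildPrg(threeRowPanel())
  ga <- projectAlignment(linearAlignment("r", "ACGT", "H1", 0, "4M"), g)
  expect_equal(scoreGraphAlignment(ga@cells[0, ], scheme), 0)
  ## run of k read-gaps costs open + (k-1) extend
  rows <- c(H1 = "ACGTACGT", H2 = "ACGTACGT")
  g2 <- buildPrg(msaPanel(rows))
  for (k in 1:3) {
    cig <- sprintf("2M%dD%dM", k, 6L - k)
    read <- paste0(substr("ACGTACGT", 1, 2), substr("ACGTACGT", 2 + k + 1, 8))
    ga <- projectAlignment(linearAlignment("r", read, "H1", 0, cig), g2)
    expect_equal(ga@score,
                 (8 - k) * scheme@match + scheme@gapOpen +
                   (k - 1) * scheme@gapExtend)
  }
})

test_that("inspection excises indel runs with flanks; counts match rule", {
  rows <- c(H1 = strrep("ACGT", 8), H2 = strrep("ACGT", 8))
  g <- buildPrg(msaPanel(rows))
  ## read with a 6-base floating insertion in the middle
  read <- paste0(substr(rows[1], 1, 12), "TTTTTT", substr(rows[1], 13, 32))
  lin <- linearAlignment("r", read, "H1", 0, "12M6I20M")
  ga <- projectAlignment(lin, g, scheme)
  ins <- inspectAlignment(ga, inspectionParams(gapTriggerLen = 3L,
                                               flankW = 2L), scheme)
  expect_equal(nrow(ins@removed), 1L)
  expect_equal(unname(ins@removed[1L, 2L] - ins@removed[1L, 1L]), 10L)

  ## gap-free alignment unchanged
  clean <- projectAlignment(linearAlignment("r", rows[[1]], "H1", 0, "32M"),
                            g, scheme)
  expect_identical(inspectAlignment(clean)@removed, clean@removed)

  ## long-read mode is the identity
  gaL <- projectAlignment(lin, g, scheme, mode = "long")
  expect_identical(inspectAlignment(gaL, inspectionParams(3L, 2L))@cells,
                   gaL@cells)
})

test_that("placed indel runs below the trigger length are kept", {
  rows <- c(H1 = strrep("ACGT", 8), H2 = strrep("ACGT", 8))
  g <- buildPrg(msaPanel(rows))
  ## a single deletion stays below the g = 2 trigger
  read <- paste0(substr(rows[1], 1, 12), substr(rows[1], 14, 32))
  ga <- projectAlignment(linearAlignment("r", read, "H1", 0, "12M1D19M"),
                         g, scheme)
  ins <- inspectAlignment(ga, inspectionParams(gapTriggerLen = 2L), scheme)
  expect_equal(nrow(ins@removed), 0L)
  ## a floating (unplaceable) insertion is excised whatever its length
  readI <- paste0(substr(rows[1], 1, 12), "T", substr(rows[1], 13, 32))
  gaI <- projectAlignment(linearAlignment("r", readI, "H1", 0, "12M1I20M"),
                          g, scheme)
  insI <- inspectAlignment(gaI, inspectionParams(gapTriggerLen = 2L),
                           scheme)
  expect_equal(nrow(insI@removed), 1L)
})

test_that("polish recovers the optimum at fixed levels (examples)", {
  g <- buildPrg(threeRowPanel())
  ga <- projectAlignment(linearAlignment("r", "ACAT", "H1", 0, "4M"), g,
                         scheme)
  p <- polishAlignment(ga, g, scheme)
  expect_equal(p@score, 4 * scheme@match)
  ## already-optimal alignment unchanged
  ga2 <- projectAlignment(linearAlignment("r", "ACGT", "H1", 0, "4M"), g,
                          scheme)
  expect_equal(polishAlignment(ga2, g, scheme)@score, ga2@score)
})

test_that("polish equals exhaustive enumeration on random instances", {
  set.seed(404)
  for (i in 1:40) {
    inst <- switchReadInstance(1000 + i, readLen = 12L)
    ga <- projectAlignment(inst$lin, inst$prg, scheme)
    pol <- polishAlignment(ga, inst$prg, scheme)
    expect_equal(pol@score, polishEnumerationScore(ga, inst$prg, scheme))
    expect_gte(pol@score, ga@score)
  }
})

test_that("full graph alignment matches hand enumeration", {
  g <- buildPrg(threeRowPanel())
  expect_equal(fullGraphAlign("ACT", g, scheme)@score, 3 * scheme@match)
  expect_equal(fullGraphAlign("ACGT", g, scheme)@score, 4 * scheme@match)
  expect_error(fullGraphAlign("", g, scheme), "empty read")
})

test_that("extension re-integrates removals and places clipped ends", {
  rows <- c(H1 = "ACGTACGTACGTACGTACGTACGT",
            H2 = "ACGTACGT----ACGTACGTACGT",
            H3 = "ACGTACGTACTTACGTACGTACGT")
  g <- buildPrg(msaPanel(rows))
  read <- gsub("-", "", rows[["H1"]])
  ## read from H1 projected onto H2 across the indel: the anchored
  ## insertion placement repairs this during projection itself
  ga <- alignRead(linearAlignment("r", read, "H2", 0, "8M4I12M"), g, scheme)
  expect_equal(ga@score, nchar(read) * scheme@match)
  expect_conserved(ga, nchar(read))
  ## read from H2 projected onto H1 across the same indel: the deletion run
  ## is excised by inspection and re-integrated by extension
  readD <- gsub("-", "", rows[["H2"]])
  gaD <- alignRead(linearAlignment("r", readD, "H1", 0, "8M4D12M"), g,
                   scheme)
  expect_equal(gaD@score, nchar(readD) * scheme@match)
  expect_true(gaD@meta$extensionRan)
  expect_conserved(gaD, nchar(readD))
  ## soft-clipped suffix matching the next columns gets placed
  ga2 <- alignRead(linearAlignment("r", substr(read, 1, 15), "H1", 0,
                                   "10M5S"), g, scheme)
  expect_equal(ga2@score, 15 * scheme@match)
  ## clean read skips extension entirely
  ga3 <- alignRead(linearAlignment("r", read, "H1", 0, "24M"), g, scheme)
  expect_false(ga3@meta$extensionRan)
})

test_that("hybrid pipeline never beats the exhaustive aligner, and matches
           it on spelled-path substrings", {
  set.seed(77)
  for (i in 1:40) {
    inst <- switchReadInstance(2000 + i)
    ga <- alignRead(inst$lin, inst$prg, scheme)
    f <- fullGraphAlign(inst$lin@readSeq, inst$prg, scheme)
    expect_lte(ga@score, f@score + 1e-9)
    expect_equal(ga@score, f@score)   # read is a substring of a spelled path
    expect_conserved(ga, nchar(inst$lin@readSeq))
  }
})

test_that("stage scores improve monotonically", {
  set.seed(5150)
  for (i in 1:25) {
    inst <- switchReadInstance(3000 + i)
    ga <- alignRead(inst$lin, inst$prg, scheme)
    expect_lte(ga@meta$projectedScore, ga@meta$polishedScore + 1e-9)
    expect_lte(ga@meta$polishedScore, ga@meta$finalScore + 1e-9)
  }
})

test_that("long mode aligns reads with indel errors without removal", {
  cfg <- simConfig(seed = 31, locusLen = 300L, readLen = 300L, coverage = 3,
                   mode = "long", readSubRate = 0.01, readIndelRate = 0.05,
                   misprojectionProb = 0)
  truth <- simulatePanel(cfg)
  prg <- buildPrg(truth@panels$locus1)
  reads <- simulateReads(truth, cfg)
  for (i in seq_len(nrow(reads$sam))) {
    lin <- linearAlignment(reads$sam$qname[i], reads$sam$seq[i],
                           reads$sam$rname[i], reads$sam$pos[i] - 1L,
                           reads$sam$cigar[i])
    ga <- projectAlignment(lin, prg, scheme, mode = "long")
    expect_identical(inspectAlignment(ga)@cells, ga@cells)
    final <- alignRead(lin, prg, scheme, mode = "long")
    expect_conserved(final, nchar(lin@readSeq))
  }
})
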