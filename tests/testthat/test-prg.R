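test_that("column structure of the three-row example graph", {
  g <- buildPrg(threeRowPanel())
  e <- prgEdges(g)
  expect_equal(g@levelCount, 4L)
  expect_equal(unname(table(e$level)[c("0", "1", "3")]),
               rep(1L, 3L), ignore_attr = TRUE)
  lvl2 <- e[e$level == 2L, ]
  expect_setequal(lvl2$label, c("A", "G", "-"))
  origin <- setNames(lvl2$origins, lvl2$label)
  expect_equal(origin[["G"]], "H1")
  expect_equal(origin[["A"]], "H2")
  expect_equal(origin[["-"]], "H3")
})

test_that("single-row panel builds a linear graph", {
  g <- buildPrg(msaPanel(c(H1 = "ACGT")))
  expect_equal(g@levelCount, 4L)
  expect_equal(nrow(prgEdges(g)), 4L)
  expect_equal(spellPath(g, haplotypePath(g, "H1")), "ACGT")
})

test_that("haplotype paths spell their rows on random panels", {
  for (seed in 1:6) {
    truth <- tinyTruth(seed, len = 30L)
    panel <- truth@panels$locus1
    prg <- buildPrg(panel)
    for (id in names(panel@rows))
      expect_equal(spellPath(prg, haplotypePath(prg, id)),
                   ungappedSequence(panel, id))
  }
})

test_that("path enumeration of the example covers the stored spellings", {
  g <- buildPrg(threeRowPanel())
  spelled <- vapply(enumerateLevelPaths(g), function(p) spellPath(g, p), "")
  expect_true(all(c("ACGT", "ACAT", "ACT") %in% spelled))
  ## recombinants, if any, traverse only observed edges
  expect_true(all(nchar(spelled) %in% 3:4))
})

test_that("coordinate maps skip gap columns and round-trip", {
  g <- buildPrg(threeRowPanel())
  cm <- coordinateMap(g, "H3")
  expect_equal(cm$res2lvl, c(0L, 1L, 3L))
  expect_equal(coordinateMap(g, "H1")$res2lvl, 0:3)
  for (seed in 1:4) {
    truth <- tinyTruth(seed)
    prg <- buildPrg(truth@panels$locus1)
    for (id in names(prg@cmap)) {
      cm <- prg@cmap[[id]]
      expect_equal(cm$lvl2res[cm$res2lvl + 1L],
                   seq_along(cm$res2lvl) - 1L)
    }
  }
})

test_that("graph construction is deterministic", {
  panel <- tinyTruth(3)@panels$locus1
  g1 <- buildPrg(panel)
  g2 <- buildPrg(panel)
  expect_identical(g1@edges, g2@edges)
  expect_identical(g1@nodeBoundary, g2@nodeBoundary)
  expect_identical(g1@paths, g2@paths)
})

test_that("edge origins are nonempty and match column content", {
  truth <- tinyTruth(7)
  panel <- truth@panels$locus1
  prg <- buildPrg(panel)
  e <- prgEdges(prg)
  expect_true(all(lengths(e$origins) > 0L))
  m <- do.call(rbind, strsplit(panel@rows, ""))
  rownames(m) <- names(panel@rows)
  for (i in sample(nrow(e), 20L))
    expect_true(all(m[e$origins[[i]], e$level[i] + 1L] == e$label[i]))
})

test_that("malformed panels are rejected with diagnostics", {
  expect_error(msaPanel(character(0)), "empty panel")
  expect_error(msaPanel(c(H1 = "ACGT", H2 = "ACG")), "unequal length")
  expect_error(msaPanel(c(A1 = "AC*T"), partial = "A1"), "full-length")
  expect_error(spellPath(buildPrg(threeRowPanel()), c(1L, 4L)),
               "not a connected")
  expect_error(coordinateMap(buildPrg(threeRowPanel()), "nope"), "unknown")
})

test_that("partial rows contribute edges only inside covered blocks", {
  panel <- msaPanel(c(H1 = "ACGTACGT", A1 = "**GTAC**"),
                    partial = "A1")
  g <- buildPrg(panel)
  p <- haplotypePath(g, "A1")
  expect_true(all(is.na(p[c(1, 2, 7, 8)])))
  expect_true(all(!is.na(p[3:6])))
  expect_equal(spellPath(g, p), "GTAC")
})

test_that("graph serialization round-trips exactly", {
  truth <- tinyTruth(5, nAll = 4L)
  panel <- truth@panels$locus1
  ## add an exon-only row to exercise partial serialization
  prg <- buildPrg(panel)
  f <- tempfile(fileext = ".jsonl")
  writePrgJson(prg, f)
  prg2 <- readPrgJson(f)
  expect_identical(prg@edges, prg2@edges)
  expect_identical(prg@nodeBoundary, prg2@nodeBoundary)
  expect_identical(prg@levelCount, prg2@levelCount)
  expect_identical(sort(names(prg@paths)), sort(names(prg2@paths)))
})
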