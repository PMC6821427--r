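## A fixed small locus: 3 alleles over a 60-base ancestor, no haplotype
## divergence so reads project perfectly; likelihoods are then closed-form.
fixedLocus <- function() {
  truth <- simulatePanel(simConfig(seed = 8, nHaplotypes = 2L,
                                   nAllelesPerLocus = 3L, locusLen = 60L,
                                   divergence = 0.05, readLen = 30L))
  list(truth = truth, prg = buildPrg(truth@panels$locus1),
       db = truth@dbs$locus1)
}

test_that("read-vs-allele log-likelihood has its closed forms", {
  fx <- fixedLocus()
  model <- errorModel("short")
  a <- fx$db@ids[1L]
  seqA <- fx$db@seqs[1L]
  hap <- fx$truth@haplotypeIds$locus1[1L]
  ## error-free read drawn from allele a, evaluated against a
  lin <- msaInducedAlignment(fx$truth@panels$locus1, a, hap, 5L, 20L)
  ga <- alignRead(lin, fx$prg)
  ll <- readAlleleLogLik(ga, a, fx$db, fx$prg, model)
  expect_equal(as.numeric(ll), attr(ll, "neval") * log(1 - model@sub))
  expect_equal(attr(ll, "neval"), 20)
  ## against an allele differing at d covered columns:
  ## (n-d) log(1-sub) + d log(sub/3)
  b <- fx$db@ids[2L]
  rowA <- strsplit(fx$db@rows[1L], "")[[1L]]
  rowB <- strsplit(fx$db@rows[2L], "")[[1L]]
  cols <- which(rowA %in% c("A", "C", "G", "T"))
  win <- cols[6:25]
  d <- sum(rowA[win] != rowB[win])
  llB <- readAlleleLogLik(ga, b, fx$db, fx$prg, model)
  expect_equal(as.numeric(llB),
               (20 - d) * log(1 - model@sub) + d * log(model@sub / 3))
  expect_error(readAlleleLogLik(ga, "nope", fx$db, fx$prg, model),
               "absent")
})

test_that("likelihood agrees with an independent column-walk oracle", {
  fx <- fixedLocus()
  model <- errorModel("short")
  logp <- c(m = log(1 - model@sub), x = log(model@sub / 3),
            io = log(model@insOpen), ie = log(model@insExtend),
            do = log(model@delOpen), de = log(model@delExtend))
  set.seed(12)
  for (rep in 1:10) {
    a <- sample(fx$db@ids, 1L)
    hap <- fx$truth@haplotypeIds$locus1[1L]
    st <- sample(0:30, 1L)
    lin <- msaInducedAlignment(fx$truth@panels$locus1, a, hap, st, 25L)
    ga <- alignRead(lin, fx$prg)
    b <- sample(fx$db@ids, 1L)
    rowB <- strsplit(fx$db@rows[match(b, fx$db@ids)], "")[[1L]]
    ## oracle: walk cells, classify against the allele row, affine runs
    ll <- 0; state <- "none"
    for (i in seq_len(nrow(ga@cells))) {
      lvl <- ga@cells$level[i] + 1L
      base <- ga@cells$base[i]
      lab <- if (is.na(ga@cells$edge[i])) "ins" else rowB[lvl]
      if (identical(lab, "*")) { state <- "none"; next }
      if (base != "-" && (identical(lab, "ins") || identical(lab, "-"))) {
        ll <- ll + if (state == "ins") logp[["ie"]] else logp[["io"]]
        state <- "ins"
      } else if (base != "-") {
        ll <- ll + if (base == lab) logp[["m"]] else logp[["x"]]
        state <- "none"
      } else if (lab != "-") {
        ll <- ll + if (state == "del") logp[["de"]] else logp[["do"]]
        state <- "del"
      }
    }
    got <- readAlleleLogLik(ga, b, fx$db, fx$prg, model)
    expect_equal(as.numeric(got), ll)
  }
})

test_that("pair likelihood is a symmetric log-space mixture", {
  fx <- fixedLocus()
  truth <- fx$truth
  reads <- simulateReads(truth)
  lins <- lapply(seq_len(nrow(reads$sam)), function(i)
    linearAlignment(reads$sam$qname[i], reads$sam$seq[i],
                    reads$sam$rname[i], reads$sam$pos[i] - 1L,
                    reads$sam$cigar[i]))
  gas <- lapply(lins, function(l) alignRead(l, fx$prg))
  tab <- likelihoodTable(gas, fx$db, fx$prg)
  a <- fx$db@ids[1L]; b <- fx$db@ids[2L]
  ## collapse when a1 == a2
  expect_equal(pairLogLik(tab, a, a), sum(tab$mat[, a]))
  ## symmetry, exactly
  expect_identical(pairLogLik(tab, a, b), pairLogLik(tab, b, a))
  ## direct summation oracle over all pairs
  for (x in fx$db@ids) for (y in fx$db@ids)
    expect_equal(pairLogLik(tab, x, y),
                 sum(log(0.5 * exp(tab$mat[, x]) + 0.5 * exp(tab$mat[, y]))))
  ## mixture dominance
  for (x in fx$db@ids) for (y in fx$db@ids)
    expect_gte(pairLogLik(tab, x, y) + 1e-9,
               min(pairLogLik(tab, x, x), pairLogLik(tab, y, y)))
})

test_that("genotype calling recovers constructed diploids", {
  fx <- fixedLocus()
  hap <- fx$truth@haplotypeIds$locus1[1L]
  a1 <- fx$db@ids[1L]; a2 <- fx$db@ids[2L]
  mk <- function(allele, i)
    alignRead(msaInducedAlignment(fx$truth@panels$locus1, allele, hap,
                                  (3L * i) %% 20L, 30L,
                                  readId = sprintf("%s_%d", allele, i)),
              fx$prg)
  gas <- c(lapply(1:10, function(i) mk(a1, i)),
           lapply(1:10, function(i) mk(a2, i)))
  tab <- likelihoodTable(gas, fx$db, fx$prg)
  call <- callGenotype(tab)
  expect_equal(sort(c(call@a1, call@a2)), sort(c(a1, a2)))
  ## posterior normalizes
  expect_equal(sum(call@posterior$posterior), 1, tolerance = 1e-9)
  ## single-allele database: homozygous call with Q = 1
  db1 <- alleleDatabaseFromPanel(fx$truth@panels$locus1, a1)
  tab1 <- likelihoodTable(lapply(1:10, function(i) mk(a1, i)), db1, fx$prg)
  call1 <- callGenotype(tab1)
  expect_equal(c(call1@a1, call1@a2), c(a1, a1))
  expect_equal(call1@q, 1)
})

test_that("zero retained reads yield an uncalled result with a reason", {
  fx <- fixedLocus()
  tab <- likelihoodTable(list(), fx$db, fx$prg)
  call <- callGenotype(tab)
  expect_false(call@called)
  expect_match(call@reason, "zero retained")
})

test_that("threshold semantics drive the call flag", {
  r <- simulateAndType(simConfig(seed = 41, locusLen = 300L, coverage = 10),
                       threshold = 0)
  expect_true(all(vapply(r$calls, function(x) x@called, TRUE)))
  expect_equal(attr(r$calls, "summary")$callRate, 1)
})

test_that("two-locus samples are typed per locus", {
  r <- simulateAndType(simConfig(seed = 42, nLoci = 2L, locusLen = 400L))
  expect_equal(length(r$calls), 2L)
  for (loc in names(r$calls)) {
    expect_equal(sort(c(r$calls[[loc]]@a1, r$calls[[loc]]@a2)),
                 sort(r$truth@truth[[loc]]))
    expect_equal(sum(r$calls[[loc]]@posterior$posterior), 1,
                 tolerance = 1e-9)
  }
  ## empty alignment set: all loci uncalled
  truth <- simulatePanel(simConfig(seed = 42, nLoci = 2L, locusLen = 400L))
  prgs <- lapply(truth@panels, buildPrg)
  calls <- typeSample(list(), prgs, truth@dbs)
  expect_true(all(!vapply(calls, function(x) x@called, TRUE)))
})

test_that("exon-only alleles are evaluated only over exon columns", {
  truth <- simulatePanel(simConfig(seed = 51, locusLen = 200L,
                                   nAllelesPerLocus = 6L,
                                   fractionExonOnly = 0.5))
  prg <- buildPrg(truth@panels$locus1)
  db <- truth@dbs$locus1
  exonIdx <- which(db@coverage == "exon_only")[1L]
  exonAllele <- db@ids[exonIdx]
  hap <- truth@haplotypeIds$locus1[1L]
  genomicAllele <- db@ids[db@coverage == "genomic"][1L]
  ## a read spanning the whole locus: only exon columns count
  lin <- msaInducedAlignment(truth@panels$locus1, genomicAllele, hap,
                             0L, nchar(db@seqs[1L]))
  ga <- alignRead(lin, prg)
  ll <- readAlleleLogLik(ga, exonAllele, db, prg)
  exonLen <- nchar(db@exonSeqs[exonIdx])
  expect_lte(attr(ll, "neval"), exonLen + 5L)  # small slack for indel cells
  expect_gt(attr(ll, "neval"), 0)
})

test_that("long-mode model scores indel-bearing reads higher than the
           short-mode model for the true allele", {
  cfg <- simConfig(seed = 61, locusLen = 500L, readLen = 500L,
                   coverage = 8, mode = "long", readSubRate = 0.01,
                   readIndelRate = 0.05, misprojectionProb = 0)
  truth <- simulatePanel(cfg)
  prg <- buildPrg(truth@panels$locus1)
  reads <- simulateReads(truth, cfg)
  diffs <- vapply(seq_len(nrow(reads$sam)), function(i) {
    lin <- linearAlignment(reads$sam$qname[i], reads$sam$seq[i],
                           reads$sam$rname[i], reads$sam$pos[i] - 1L,
                           reads$sam$cigar[i])
    ga <- alignRead(lin, prg, mode = "long")
    a <- reads$provenance$allele[i]
    as.numeric(readAlleleLogLik(ga, a, truth@dbs$locus1, prg,
                                errorModel("long"))) -
      as.numeric(readAlleleLogLik(ga, a, truth@dbs$locus1, prg,
                                  errorModel("short")))
  }, 0)
  expect_gt(median(diffs), 0)
})
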