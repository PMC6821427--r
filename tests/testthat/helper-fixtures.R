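## Shared fixtures, all generated in code.

## The three-row panel used throughout: one polymorphic column with a gap.
threeRowPanel <- function() {
  msaPanel(c(H1 = "ACGT", H2 = "ACAT", H3 = "AC-T"))
}

## Small divergent panel with indels for randomized alignment checks.
tinyTruth <- function(seed, nHap = 5L, nAll = 3L, len = 40L,
                      div = 0.08, indel = 0.02) {
  simulatePanel(simConfig(seed = seed, nHaplotypes = nHap,
                          nAllelesPerLocus = nAll, locusLen = len,
                          divergence = div, indelProb = indel))
}

## A read that is an exact substring of one full-length row, projected (via
## the panel-induced CIGAR) onto another row.
switchReadInstance <- function(seed, readLen = 20L) {
  truth <- tinyTruth(seed)
  panel <- truth@panels$locus1
  prg <- buildPrg(panel)
  full <- names(panel@rows)[!panel@partial]
  src <- sample(full, 1L)
  ref <- sample(full, 1L)
  ulen <- nchar(ungappedSequence(panel, src))
  rl <- min(readLen, ulen)
  st <- sample.int(ulen - rl + 1L, 1L) - 1L
  list(prg = prg, panel = panel,
       lin = msaInducedAlignment(panel, src, ref, st, rl),
       src = src, ref = ref)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

mutateSeq <- function(s, p) {
  ch <- strsplit(s, "")[[1L]]
  i <- which(runif(length(ch)) < p)
  for (j in i) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
  paste(ch, collapse = "")
}

## Conservation invariant: every read base in exactly one of cells /
## removed intervals / clips.
expect_conserved <- function(ga, readLen) {
  slots <- rep(0L, readLen)
  rp <- ga@cells$readPos
  rp <- rp[!is.na(rp)]
  slots[rp + 1L] <- slots[rp + 1L] + 1L
  if (nrow(ga@removed))
    for (i in seq_len(nrow(ga@removed))) {
      iv <- ga@removed[i, ]
      if (iv[2L] > iv[1L])
        slots[(iv[1L] + 1L):iv[2L]] <- slots[(iv[1L] + 1L):iv[2L]] + 1L
    }
  if (ga@clipPrefix > 0L)
    slots[seq_len(ga@clipPrefix)] <- slots[seq_len(ga@clipPrefix)] + 1L
  if (ga@clipSuffix > 0L)
    slots[(readLen - ga@clipSuffix + 1L):readLen] <-
      slots[(readLen - ga@clipSuffix + 1L):readLen] + 1L
  expect_true(all(slots == 1L),
              label = sprintf("read base conservation (%s)",
                              paste(which(slots != 1L), collapse = ",")))
}
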