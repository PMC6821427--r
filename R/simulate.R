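#' Simulation configuration
#'
#' Defaults describe the package's reference study conditions: one 1 kb
#' locus, 5 genomic haplotypes, 20 alleles diverged by 1% substitutions,
#' 30x coverage with 100 bp substitution-dominated short reads (0.3% error)
#' and 5% of reads deliberately misprojected onto the wrong haplotype.
#' Panel indels, read indels (long-read mode) and exon-only alleles are off
#' by default and enabled by the corresponding rates.
#'
#' @param seed RNG seed; every output is reproducible from it.
#' @param nLoci,nHaplotypes,nAllelesPerLocus,locusLen panel dimensions.
#' @param divergence per-base substitution probability from the locus
#'   ancestor, per sequence.
#' @param indelProb per-base probability of starting an indel when deriving
#'   a panel sequence; \code{indelGeomP} sets the geometric length tail.
#' @param coverage,readLen read simulation depth and length.
#' @param mode \code{"short"} or \code{"long"} (affects downstream defaults
#'   only; error rates here are explicit).
#' @param readSubRate,readIndelRate per-base read error rates.
#' @param fractionExonOnly fraction of alleles truncated to their two exon
#'   blocks.
#' @param misprojectionProb probability a read's SAM record targets a wrong
#'   haplotype with a naively recomputed CIGAR.
#' @export
simConfig <- function(seed = 1L, nLoci = 1L, nHaplotypes = 5L,
                      nAllelesPerLocus = 20L, locusLen = 1000L,
                      divergence = 0.01, indelProb = 0,
                      indelGeomP = 0.5, coverage = 30, readLen = 100L,
                      mode = "short", readSubRate = 0.003,
                      readIndelRate = 0, fractionExonOnly = 0,
                      misprojectionProb = 0.05) {
  new("SimConfig", seed = as.integer(seed), nLoci = as.integer(nLoci),
      nHaplotypes = as.integer(nHaplotypes),
      nAllelesPerLocus = as.integer(nAllelesPerLocus),
      locusLen = as.integer(locusLen), divergence = divergence,
      indelProb = indelProb, indelGeomP = indelGeomP, coverage = coverage,
      readLen = as.integer(readLen), mode = mode,
      readSubRate = readSubRate, readIndelRate = readIndelRate,
      fractionExonOnly = fractionExonOnly,
      misprojectionProb = misprojectionProb)
}

BASES <- c("A", "C", "G", "T")

mutateBase <- function(b) {
  vapply(b, function(x) sample(setdiff(BASES, x), 1L), "")
}

## Derive one sequence from the ancestor: substitutions plus indel events.
## Returns list(chars at ancestor positions ('-' = deleted),
##              insAfter = list(position -> inserted chars)).
deriveSequence <- function(anc, cfg) {
  len <- length(anc)
  chars <- anc
  subs <- which(runif(len) < cfg@divergence)
  if (length(subs)) chars[subs] <- mutateBase(chars[subs])
  insAfter <- list()
  if (cfg@indelProb > 0) {
    ev <- which(runif(len) < cfg@indelProb)
    for (p in ev) {
      k <- 1L + rgeom(1L, cfg@indelGeomP)
      if (runif(1) < 0.5) {
        chars[p:min(len, p + k - 1L)] <- "-"                 # deletion
      } else {
        insAfter[[as.character(p)]] <- sample(BASES, k, replace = TRUE)
      }
    }
  }
  list(chars = chars, insAfter = insAfter)
}

#' Simulate a haplotype panel, allele database and diploid truth
#'
#' Per locus: an ancestral sequence; haplotypes and alleles derived by
#' substitution and (optionally) indel mutation, with the alignment induced
#' by the tracked coordinates (no heuristic realignment). A gene spanning
#' the central 80% of the ancestor with two exon blocks is annotated on
#' every haplotype. A configured fraction of alleles is truncated to the
#' exon blocks (exon-only rows). The diploid truth genotype per locus is
#' drawn uniformly (with replacement) from the genomic alleles.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return A \linkS4class{TruthSet}.
#' @export
simulatePanel <- function(cfg) {
  set.seed(cfg@seed)
  panels <- list(); dbs <- list(); truth <- list()
  hapIds <- list(); alleleIds <- list(); features <- list()
  annRows <- list()
  for (li in seq_len(cfg@nLoci)) {
    locus <- sprintf("locus%d", li)
    anc <- sample(BASES, cfg@locusLen, replace = TRUE)
    hids <- sprintf("%s_H%d", locus, seq_len(cfg@nHaplotypes))
    aids <- sprintf("%s_A%02d", locus, seq_len(cfg@nAllelesPerLocus))
    ids <- c(hids, aids)
    der <- lapply(ids, function(i) deriveSequence(anc, cfg))
    names(der) <- ids
    ## MSA columns: insertion slots (per row, in row order) then the
    ## ancestor column, for each ancestor position
    insLens <- vapply(seq_along(anc), function(p)
      sum(vapply(der, function(d) {
        x <- d$insAfter[[as.character(p)]]
        if (is.null(x)) 0L else length(x)
      }, 0L)), 0L)
    ## (insertions after position p precede the column of position p+1)
    L <- cfg@locusLen + sum(insLens)
    ancCol <- integer(cfg@locusLen)   # MSA column (1-based) of each anc pos
    rows <- matrix("-", nrow = length(ids), ncol = L,
                   dimnames = list(ids, NULL))
    col <- 0L
    for (p in seq_along(anc)) {
      col <- col + 1L
      ancCol[p] <- col
      for (i in seq_along(ids))
        rows[i, col] <- der[[i]]$chars[p]
      for (i in seq_along(ids)) {
        x <- der[[i]]$insAfter[[as.character(p)]]
        if (!is.null(x)) {
          rows[i, (col + 1L):(col + length(x))] <- x
          col <- col + length(x)
        }
      }
    }
    ## gene and exon blocks in ancestor coordinates -> MSA columns
    gs <- floor(0.1 * cfg@locusLen) + 1L; ge <- floor(0.9 * cfg@locusLen)
    ex <- rbind(c(floor(0.15 * cfg@locusLen) + 1L, floor(0.35 * cfg@locusLen)),
                c(floor(0.55 * cfg@locusLen) + 1L, floor(0.75 * cfg@locusLen)))
    geneCols <- matrix(c(ancCol[gs] - 1L, ancCol[ge]), 1L)
    exonCols <- rbind(c(ancCol[ex[1L, 1L]] - 1L, ancCol[ex[1L, 2L]]),
                      c(ancCol[ex[2L, 1L]] - 1L, ancCol[ex[2L, 2L]]))
    ## exon-only alleles: absent outside exon columns
    nExon <- round(cfg@fractionExonOnly * cfg@nAllelesPerLocus)
    exonOnly <- if (nExon > 0L) tail(aids, nExon) else character(0)
    for (id in exonOnly) {
      keep <- rep(FALSE, L)
      for (e in seq_len(nrow(exonCols)))
        keep[(exonCols[e, 1L] + 1L):exonCols[e, 2L]] <- TRUE
      rows[id, !keep] <- ABSENT_CHAR
    }
    rowStrs <- apply(rows, 1L, paste, collapse = "")
    panel <- msaPanel(setNames(rowStrs, ids), partial = exonOnly,
                      locus = locus)
    ## per-haplotype feature annotations in ungapped haplotype coordinates
    for (h in hids) {
      ch <- rows[h, ]
      isRes <- ch %in% BASES | ch == "N"
      cum <- cumsum(isRes)
      resBefore <- function(col0) if (col0 == 0L) 0L else cum[col0]
      annRows[[length(annRows) + 1L]] <- data.frame(
        haplotype_id = h, locus = locus,
        feature_kind = c("gene", "exon", "exon"),
        exon_index = c(NA, 1L, 2L),
        start = c(resBefore(geneCols[1L, 1L]),
                  resBefore(exonCols[1L, 1L]), resBefore(exonCols[2L, 1L])),
        end = c(resBefore(geneCols[1L, 2L]),
                resBefore(exonCols[1L, 2L]), resBefore(exonCols[2L, 2L])))
    }
    db <- alleleDatabaseFromPanel(panel, aids, geneCols, exonCols)
    genomic <- aids[!aids %in% exonOnly]
    panels[[locus]] <- panel
    dbs[[locus]] <- db
    truth[[locus]] <- sort(sample(genomic, 2L, replace = TRUE))
    hapIds[[locus]] <- hids
    alleleIds[[locus]] <- aids
    features[[locus]] <- list(geneCols = geneCols, exonCols = exonCols)
  }
  ann <- annotationsToGRanges(do.call(rbind, annRows))
  new("TruthSet", panels = panels, annotations = ann, dbs = dbs,
      truth = truth, haplotypeIds = hapIds, alleleIds = alleleIds,
      features = features, config = cfg)
}

#' @export
setMethod("show", "TruthSet", function(object) {
  cat(sprintf("TruthSet: %d loci, %d haplotypes + %d alleles each\n",
              length(object@panels), object@config@nHaplotypes,
              object@config@nAllelesPerLocus))
})

## Alignment of one panel row against another over a column window:
## returns CIGAR ops per column ('M','I','D' or '' for double gaps).
rowPairOps <- function(srcChars, refChars) {
  sBase <- srcChars %in% c(BASES, "N")
  rBase <- refChars %in% c(BASES, "N")
  ifelse(sBase & rBase, "M", ifelse(sBase, "I", ifelse(rBase, "D", "")))
}

## Apply read errors to a perfect read; returns read chars plus per-source-
## base op list used for CIGAR composition.
applyReadErrors <- function(chars, cfg) {
  n <- length(chars)
  keep <- rep(TRUE, n)                       # FALSE = deleted source base
  insAfter <- vector("list", n + 1L)         # insertions before pos i+1
  subs <- which(runif(n) < cfg@readSubRate)
  if (length(subs)) chars[subs] <- mutateBase(chars[subs])
  if (cfg@readIndelRate > 0) {
    ev <- which(runif(n) < cfg@readIndelRate)
    for (p in ev) {
      k <- 1L + rgeom(1L, cfg@indelGeomP)
      if (runif(1) < 0.5) keep[p:min(n, p + k - 1L)] <- FALSE
      else insAfter[[p + 1L]] <- sample(BASES, k, replace = TRUE)
    }
  }
  list(chars = chars, keep = keep, insAfter = insAfter)
}

#' Linear alignment of one panel row's substring against another row
#'
#' Composes the alignment induced by the panel's columns: the substring of
#' \code{srcId}'s ungapped sequence starting at \code{srcStart} is aligned
#' against \code{refId}, with columns where only one row has a base becoming
#' insertions/deletions. Useful for constructing reads with exactly known
#' optimal graph alignments (the read spells \code{srcId}'s path).
#'
#' @param panel an \linkS4class{MsaPanel}.
#' @param srcId,refId source and target rows (target must be full-length).
#' @param srcStart 0-based start in the source's ungapped coordinates.
#' @param srcLen number of source residues.
#' @param readId read name.
#' @return A \linkS4class{LinearAlignment}.
#' @export
msaInducedAlignment <- function(panel, srcId, refId, srcStart, srcLen,
                                readId = "read") {
  sChars <- strsplit(panel@rows[[srcId]], "")[[1L]]
  rChars <- strsplit(panel@rows[[refId]], "")[[1L]]
  isBase <- function(x) x %in% c(BASES, "N")
  srcCols <- which(isBase(sChars))
  stopifnot(srcStart + srcLen <= length(srcCols))
  cols <- srcCols[(srcStart + 1L):(srcStart + srcLen)]
  refBefore <- sum(isBase(rChars[seq_len(cols[1L] - 1L)]))
  ops <- character(0)
  prev <- cols[1L] - 1L
  for (cc in cols) {
    if (cc > prev + 1L) {
      mid <- (prev + 1L):(cc - 1L)
      ops <- c(ops, rep("D", sum(isBase(rChars[mid]))))
    }
    ops <- c(ops, if (isBase(rChars[cc])) "M" else "I")
    prev <- cc
  }
  while (length(ops) && ops[1L] == "D") {
    ops <- ops[-1L]; refBefore <- refBefore + 1L
  }
  while (length(ops) && ops[length(ops)] == "D") ops <- ops[-length(ops)]
  r <- rle(ops)
  read <- paste(sChars[cols], collapse = "")
  linearAlignment(readId, read, refId, refBefore,
                  paste0(r$lengths, r$values, collapse = ""))
}

#' Simulate reads with SAM records
#'
#' Reads are drawn uniformly from the two truth alleles per locus at the
#' configured coverage, errors applied per the configured rates, and the
#' true CIGAR emitted against the allele's nearest full-length haplotype
#' (coordinates composed through the tracked alignment). With probability
#' \code{misprojectionProb} the record instead targets a random other
#' haplotype with a naive all-M CIGAR, manufacturing wrong-level /
#' wrong-edge inputs for the optimizer.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param cfg its configuration (or an override).
#' @return list: \code{sam} (data.frame of SAM fields), \code{provenance},
#'   \code{refLens}.
#' @export
simulateReads <- function(truth, cfg = truth@config) {
  set.seed(cfg@seed + 1000003L)
  samRows <- list(); provRows <- list()
  refLens <- integer(0)
  qualChar <- "?"                            # Q30
  for (locus in names(truth@panels)) {
    panel <- truth@panels[[locus]]
    m <- panelMatrix(panel)
    hids <- truth@haplotypeIds[[locus]]
    hapUngapped <- vapply(hids, function(h) gsub("[-*]", "", panel@rows[[h]]),
                          "")
    refLens[hids] <- nchar(hapUngapped)
    pair <- truth@truth[[locus]]
    ## nearest haplotype per truth allele: fewest differing columns
    nearest <- vapply(pair, function(a) {
      diffs <- vapply(hids, function(h) sum(m[a, ] != m[h, ]), 0L)
      hids[order(diffs, hids)][1L]
    }, "")
    nReads <- round(cfg@coverage * cfg@locusLen / min(cfg@readLen,
                                                      cfg@locusLen))
    for (ri in seq_len(nReads)) {
      a <- pair[sample.int(2L, 1L)]
      hap <- nearest[match(a, pair)]
      aChars <- strsplit(panel@rows[[a]], "")[[1L]]
      aResCols <- which(aChars %in% c(BASES, "N"))
      alen <- length(aResCols)
      rl <- min(cfg@readLen, alen)
      start <- sample.int(alen - rl + 1L, 1L) - 1L    # 0-based
      srcCols <- aResCols[(start + 1L):(start + rl)]
      err <- applyReadErrors(aChars[srcCols], cfg)
      ## read sequence
      readChars <- character(0)
      for (t in seq_len(rl)) {
        if (err$keep[t]) readChars <- c(readChars, err$chars[t])
        if (!is.null(err$insAfter[[t + 1L]]))
          readChars <- c(readChars, err$insAfter[[t + 1L]])
      }
      if (!is.null(err$insAfter[[1L]]))
        readChars <- c(err$insAfter[[1L]], readChars)
      if (length(readChars) == 0L) next
      readId <- sprintf("%s_r%04d", locus, ri)
      mis <- runif(1) < cfg@misprojectionProb
      if (mis && length(hids) > 1L) {
        tgt <- sample(setdiff(hids, hap), 1L)
        tlen <- nchar(hapUngapped[[tgt]])
        nb <- length(readChars)
        if (nb <= tlen) {
          pos <- min(start, tlen - nb)
          samRows[[length(samRows) + 1L]] <- data.frame(
            qname = readId, flag = 0L, rname = tgt, pos = pos + 1L,
            mapq = 60L, cigar = sprintf("%dM", nb),
            seq = paste(readChars, collapse = ""),
            qual = strrep(qualChar, nb))
          provRows[[length(provRows) + 1L]] <- data.frame(
            read_id = readId, locus = locus, allele = a, start = start,
            misprojected = TRUE)
          next
        }
      }
      ## true CIGAR vs nearest haplotype, composed through the alignment
      hChars <- strsplit(panel@rows[[hap]], "")[[1L]]
      ops <- character(0)
      hapBefore <- sum(hChars[seq_len(srcCols[1L] - 1L)] %in%
                         c(BASES, "N"))
      for (t in seq_len(rl)) {
        colRange <- if (t == 1L) srcCols[t] else
          (srcCols[t - 1L] + 1L):srcCols[t]
        for (cc in colRange) {
          isSrc <- cc == srcCols[t]
          hBase <- hChars[cc] %in% c(BASES, "N")
          if (isSrc) {
            if (err$keep[t]) ops <- c(ops, if (hBase) "M" else "I")
            else if (hBase) ops <- c(ops, "D")
          } else if (hBase) ops <- c(ops, "D")
        }
        if (!is.null(err$insAfter[[t + 1L]]))
          ops <- c(ops, rep("I", length(err$insAfter[[t + 1L]])))
      }
      if (!is.null(err$insAfter[[1L]]))
        ops <- c(rep("I", length(err$insAfter[[1L]])), ops)
      ## trim leading/trailing deletions into the reference start
      while (length(ops) && ops[1L] == "D") {
        ops <- ops[-1L]; hapBefore <- hapBefore + 1L
      }
      while (length(ops) && ops[length(ops)] == "D")
        ops <- ops[-length(ops)]
      r <- rle(ops)
      cigar <- paste0(r$lengths, r$values, collapse = "")
      samRows[[length(samRows) + 1L]] <- data.frame(
        qname = readId, flag = 0L, rname = hap, pos = hapBefore + 1L,
        mapq = 60L, cigar = cigar,
        seq = paste(readChars, collapse = ""),
        qual = strrep(qualChar, length(readChars)))
      provRows[[length(provRows) + 1L]] <- data.frame(
        read_id = readId, locus = locus, allele = a, start = start,
        misprojected = FALSE)
    }
  }
  list(sam = do.call(rbind, samRows),
       provenance = do.call(rbind, provRows),
       refLens = refLens)
}

#' Simulate assembled contigs with known truth
#'
#' Each contig copies a haplotype background whose gene region is replaced
#' by a (genomic) allele's gene sequence, then receives \code{nEdits}
#' random single-base edits.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param nContigs number of contigs.
#' @param nEdits random edits per contig (substitution, insertion or
#'   deletion, equiprobable).
#' @param seed RNG seed.
#' @return list: \code{contigs} (named character), \code{truthLabels}
#'   (data.frame contig/locus/haplotype/allele).
#' @export
simulateContigs <- function(truth, nContigs = 10L, nEdits = 0L,
                            seed = truth@config@seed + 2000003L) {
  set.seed(seed)
  contigs <- character(0); lab <- list()
  for (ci in seq_len(nContigs)) {
    locus <- sample(names(truth@panels), 1L)
    panel <- truth@panels[[locus]]
    hap <- sample(truth@haplotypeIds[[locus]], 1L)
    db <- truth@dbs[[locus]]
    genomic <- db@ids[db@coverage == "genomic"]
    a <- sample(genomic, 1L)
    gc <- truth@features[[locus]]$geneCols
    hRow <- strsplit(panel@rows[[hap]], "")[[1L]]
    aRow <- strsplit(panel@rows[[a]], "")[[1L]]
    mix <- hRow
    mix[(gc[1L, 1L] + 1L):gc[1L, 2L]] <- aRow[(gc[1L, 1L] + 1L):gc[1L, 2L]]
    seq <- gsub("[-*]", "", paste(mix, collapse = ""))
    ch <- strsplit(seq, "")[[1L]]
    for (e in seq_len(nEdits)) {
      p <- sample.int(length(ch), 1L)
      kind <- sample(c("sub", "ins", "del"), 1L)
      if (kind == "sub") ch[p] <- mutateBase(ch[p])
      else if (kind == "ins") ch <- append(ch, sample(BASES, 1L), after = p)
      else ch <- ch[-p]
    }
    cid <- sprintf("contig%03d", ci)
    contigs[[cid]] <- paste(ch, collapse = "")
    lab[[ci]] <- data.frame(contig = cid, locus = locus, haplotype = hap,
                            allele = a)
  }
  list(contigs = contigs, truthLabels = do.call(rbind, lab))
}

#' Write a simulated dataset to disk
#'
#' Emits the aligned panel FASTA, annotation TSV, allele FASTA, SAM records,
#' truth TSV (and contig FASTA when given) under \code{dir}.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param reads result of \code{simulateReads} (optional).
#' @param contigs result of \code{simulateContigs} (optional).
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(truth, reads = NULL, contigs = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (locus in names(truth@panels))
    writeMsaFasta(truth@panels[[locus]],
                  file.path(dir, sprintf("%s_panel.fasta", locus)))
  writeAnnotationsTsv(truth@annotations, file.path(dir, "annotations.tsv"))
  for (locus in names(truth@dbs)) {
    db <- truth@dbs[[locus]]
    ss <- Biostrings::BStringSet(setNames(db@seqs, db@ids))
    Biostrings::writeXStringSet(
      ss, file.path(dir, sprintf("%s_alleles.fasta", locus)))
  }
  tr <- do.call(rbind, lapply(names(truth@truth), function(l)
    data.frame(locus = l, a1 = truth@truth[[l]][1L],
               a2 = truth@truth[[l]][2L])))
  write.table(tr, file.path(dir, "truth_genotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(reads)) {
    writeSamFile(reads$sam, reads$refLens, file.path(dir, "reads.sam"))
    write.table(reads$provenance, file.path(dir, "provenance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fq <- file(file.path(dir, "reads.fastq"), "w")
    writeLines(sprintf("@%s\n%s\n+\n%s", reads$sam$qname, reads$sam$seq,
                       reads$sam$qual), fq)
    close(fq)
  }
  if (!is.null(contigs)) {
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(contigs$contigs),
      file.path(dir, "contigs.fasta"))
    write.table(contigs$truthLabels, file.path(dir, "contig_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
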