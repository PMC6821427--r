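SYMBOLS <- c("A", "C", "G", "T", "N")

baseCodes <- function(chars) {
  x <- match(chars, SYMBOLS) - 1L
  x[chars == "-"] <- -1L
  x[is.na(x)] <- 4L   # unknown characters behave like N
  x
}

edgeLabelCodes <- function(labels) {
  x <- match(labels, SYMBOLS) - 1L
  x[labels == "-"] <- 5L
  x
}

#' Affine-gap scoring scheme
#'
#' A gap cell is either a read base on a gap edge (or a floating insertion),
#' or a read gap on a base edge; a run of k gap cells of one type costs
#' \code{gapOpen + (k-1) * gapExtend}. Cells where a gap edge meets a read
#' gap are transparent: score 0, gap runs uninterrupted. \code{N} on either
#' side scores \code{nScore}.
#'
#' @param match,mismatch,gapOpen,gapExtend,nScore scores; defaults are
#'   mapper-like (+1, -4, -6, -1, 0).
#' @export
scoringScheme <- function(match = 1, mismatch = -4, gapOpen = -6,
                          gapExtend = -1, nScore = 0) {
  new("ScoringScheme", match = match, mismatch = mismatch,
      gapOpen = gapOpen, gapExtend = gapExtend, nScore = nScore)
}

schemeVector <- function(s) c(s@match, s@mismatch, s@gapOpen, s@gapExtend,
                              s@nScore)

#' Inspection-stage parameters
#'
#' @param gapTriggerLen minimum indel run length (inserted plus deleted
#'   bases) that flags a region for removal.
#' @param flankW aligned read bases removed on each side of a flagged run.
#' @param longReadMode disable removal entirely (long-read contract).
#' @export
inspectionParams <- function(gapTriggerLen = 2L, flankW = 5L,
                             longReadMode = FALSE) {
  new("InspectionParams", gapTriggerLen = as.integer(gapTriggerLen),
      flankW = as.integer(flankW), longReadMode = longReadMode)
}

makeCells <- function(level = integer(0), edge = integer(0),
                      elab = integer(0), base = character(0),
                      readPos = integer(0)) {
  k <- length(level)
  structure(list(level = as.integer(level),
                 edge = rep_len(as.integer(edge), k),
                 elab = rep_len(as.integer(elab), k),
                 base = rep_len(base, k),
                 bcode = baseCodes(rep_len(base, k)),
                 readPos = rep_len(as.integer(readPos), k)),
            class = "data.frame",
            row.names = if (k) seq_len(k) else integer(0))
}

newGraphAlignment <- function(readId, cells, clipPrefix, clipSuffix, mode,
                              scheme, removed = matrix(0L, 0L, 2L),
                              meta = list()) {
  ga <- new("GraphAlignment", readId = readId, cells = cells,
            removed = removed, clipPrefix = as.integer(clipPrefix),
            clipSuffix = as.integer(clipSuffix), score = 0, mode = mode,
            meta = meta)
  ga@score <- scoreGraphAlignment(ga, scheme)
  ga
}

#' @export
setMethod("show", "GraphAlignment", function(object) {
  cat(sprintf(
    "GraphAlignment %s: %d cells, levels %d..%d, score %.1f, mode %s\n",
    object@readId, nrow(object@cells),
    if (nrow(object@cells)) min(object@cells$level) else NA_integer_,
    if (nrow(object@cells)) max(object@cells$level) else NA_integer_,
    object@score, object@mode))
})

#' Score a graph alignment under an affine scheme
#'
#' @param x a \linkS4class{GraphAlignment} or its \code{cells} data.frame.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return numeric score; clipped bases and removed intervals contribute 0.
#' @export
scoreGraphAlignment <- function(x, scheme = scoringScheme()) {
  cells <- if (is(x, "GraphAlignment")) x@cells else x
  if (nrow(cells) == 0L) return(0)
  elab <- cells$elab
  elab[is.na(elab)] <- -1L
  cpp_score_cells(elab, cells$bcode, schemeVector(scheme))
}

#' Project a linear alignment onto the graph
#'
#' Each CIGAR-aligned base is placed on the reference haplotype's edge at the
#' level of its reference residue; deletions advance levels as read-gap
#' cells; gap columns of the reference between consecutive residues are
#' traversed transparently. Inserted read bases are placed onto the
#' reference's gap columns at the insertion site by a small anchored graph
#' DP over the gap-column run, and the placement is kept only when every
#' base matches its column; otherwise the bases become floating insertions
#' attached to the preceding level, which the inspection stage treats as
#' level-misassignment evidence. Soft clips are recorded as clips.
#'
#' @param lin a \linkS4class{LinearAlignment} against a full-length panel
#'   haplotype.
#' @param prg the \linkS4class{PrgGraph}.
#' @param scheme scoring scheme used for the reported score.
#' @param mode \code{"short"} or \code{"long"}.
#' @return A \linkS4class{GraphAlignment}.
#' @export
projectAlignment <- function(lin, prg, scheme = scoringScheme(),
                             mode = "short") {
  ref <- lin@referenceId
  if (!ref %in% names(prg@paths))
    stop(sprintf("reference '%s' is not a sequence of the graph", ref))
  if (prg@panel@partial[[ref]])
    stop(sprintf("reference '%s' is not a full-length haplotype", ref))
  cm <- prg@cmap[[ref]]
  path <- prg@paths[[ref]]
  elabAll <- edgeLabelCodes(prg@edges$label)
  refLen <- length(cm$res2lvl)
  readChars <- strsplit(lin@readSeq, "")[[1L]]
  n <- length(readChars)

  p <- lin@refStart          # 0-based ref residue
  r <- 0L                    # 0-based read pos
  clipPrefix <- 0L; clipSuffix <- 0L
  prevLevel <- NA_integer_
  acc <- vector("list", length(lin@cigarOps) * 2L)
  nAcc <- 0L
  push <- function(lvl, rp) {
    edge <- path[lvl + 1L]
    bs <- rep("-", length(lvl))
    bs[!is.na(rp)] <- readChars[rp[!is.na(rp)] + 1L]
    nAcc <<- nAcc + 1L
    acc[[nAcc]] <<- makeCells(lvl, edge, elabAll[edge], bs, rp)
  }
  pushFloating <- function(lvl, rp) {
    nAcc <<- nAcc + 1L
    acc[[nAcc]] <<- makeCells(rep(lvl, length(rp)), NA_integer_, -1L,
                              readChars[rp + 1L], rp)
  }

  ## An insertion is placed by a small anchored graph DP over the run of
  ## reference gap columns at the insertion site, so the bases land on the
  ## columns (and via polishing, the edges) that actually connect; bases
  ## that cannot be placed become floating insertions.
  gapRunAfter <- function(l) {
    avail <- integer(0)
    while (l < prg@levelCount && is.na(cm$lvl2res[l + 1L])) {
      avail <- c(avail, l); l <- l + 1L
    }
    avail
  }
  gapRunBefore <- function(l) {
    avail <- integer(0)
    while (l >= 0L && is.na(cm$lvl2res[l + 1L])) {
      avail <- c(l, avail); l <- l - 1L
    }
    avail
  }
  ## returns the last covered level, or NA when the bases stayed floating
  emitInsertion <- function(avail, r, k, leading, attach,
                            anchoredRight = TRUE) {
    if (length(avail) == 0L) {
      pushFloating(attach, r:(r + k - 1L))
      return(NA_integer_)
    }
    lb <- avail[1L]; rb <- avail[length(avail)] + 1L
    sg <- subgraphFor(prg, lb, rb)
    codes <- baseCodes(readChars[(r + 1L):(r + k)])
    res <- if (leading) {
      endNodeG <- prg@edges$from[path[rb + 1L]]
      runSubAlign(prg, sg, codes, scheme, freeStart = TRUE,
                  clipStart = lb == 0L,
                  endNode = sg$localNode[endNodeG] - 1L)
    } else {
      startNodeG <- prg@edges$to[path[lb]]      # ref edge at level lb-1
      if (anchoredRight && rb < prg@levelCount && !is.na(path[rb + 1L])) {
        endNodeG <- prg@edges$from[path[rb + 1L]]
        runSubAlign(prg, sg, codes, scheme,
                    startNode = sg$localNode[startNodeG] - 1L,
                    endNode = sg$localNode[endNodeG] - 1L)
      } else {
        runSubAlign(prg, sg, codes, scheme,
                    startNode = sg$localNode[startNodeG] - 1L,
                    freeEnd = TRUE, clipEnd = rb == prg@levelCount)
      }
    }
    ## accept the placement only when it is clean: every inserted base
    ## matches its column and the rest of the run is traversed
    ## transparently. Anything less means the insertion does not belong at
    ## this site; it floats, and inspection treats it as misassignment
    ## evidence.
    if (!res$feasible ||
        !isTRUE(all.equal(res$score, k * scheme@match))) {
      pushFloating(attach, r:(r + k - 1L))
      return(NA_integer_)
    }
    if (res$clipPrefix > 0L) clipPrefix <<- clipPrefix + res$clipPrefix
    if (res$clipSuffix > 0L) clipSuffix <<- clipSuffix + res$clipSuffix
    nAcc <<- nAcc + 1L
    acc[[nAcc]] <<- subAlignCells(res, sg, prg, lb, readChars, r)
    if (leading) lb + res$endBoundary - 1L else rb - 1L
  }

  for (i in seq_along(lin@cigarOps)) {
    op <- lin@cigarOps[i]; k <- lin@cigarLens[i]
    if (op %in% c("M", "=", "X")) {
      if (p + k > refLen)
        stop(sprintf("alignment of '%s' exceeds reference length", lin@readId))
      resLv <- cm$res2lvl[(p + 1L):(p + k)]
      start <- if (is.na(prevLevel)) resLv[1L] else prevLevel + 1L
      allLv <- start:resLv[k]
      rp <- rep(NA_integer_, length(allLv))
      rp[match(resLv, allLv)] <- r:(r + k - 1L)
      push(allLv, rp)
      prevLevel <- resLv[k]; p <- p + k; r <- r + k
    } else if (op == "D") {
      if (p + k > refLen)
        stop(sprintf("alignment of '%s' exceeds reference length", lin@readId))
      resLv <- cm$res2lvl[(p + 1L):(p + k)]
      start <- if (is.na(prevLevel)) resLv[1L] else prevLevel + 1L
      allLv <- start:resLv[k]
      push(allLv, rep(NA_integer_, length(allLv)))
      prevLevel <- resLv[k]; p <- p + k
    } else if (op == "I") {
      if (is.na(prevLevel)) {
        c0 <- if (p < refLen) cm$res2lvl[p + 1L] else prg@levelCount
        avail <- if (p < refLen) gapRunBefore(c0 - 1L) else integer(0)
        newPrev <- emitInsertion(avail, r, k, leading = TRUE,
                                 attach = if (p < refLen) c0 else 0L)
        if (!is.na(newPrev)) prevLevel <- newPrev
      } else {
        avail <- gapRunAfter(prevLevel + 1L)
        refFollows <- i < length(lin@cigarOps) &&
          any(lin@cigarOps[(i + 1L):length(lin@cigarOps)] %in%
                c("M", "=", "X", "D"))
        newPrev <- emitInsertion(avail, r, k, leading = FALSE,
                                 attach = prevLevel,
                                 anchoredRight = refFollows)
        if (!is.na(newPrev)) prevLevel <- newPrev
      }
      r <- r + k
    } else if (op == "S") {
      if (r == 0L) clipPrefix <- k else clipSuffix <- clipSuffix + k
      r <- r + k
    }                                   # H: ignored
  }
  cells <- do.call(rbind, acc[seq_len(nAcc)])
  newGraphAlignment(lin@readId, cells, clipPrefix, clipSuffix, mode, scheme,
                    meta = list(referenceId = ref, locus = prg@locus,
                                extensionRan = FALSE))
}

cellClass <- function(cells) {
  ## M = aligned base, G = indel cell, T = transparent
  cls <- rep("T", nrow(cells))
  isBase <- cells$bcode >= 0L
  elab <- cells$elab; elab[is.na(elab)] <- -1L
  cls[isBase & (elab <= 4L & elab >= 0L)] <- "M"
  cls[isBase & (elab == 5L | elab == -1L)] <- "G"
  cls[!isBase & elab >= 0L & elab <= 4L] <- "G"
  cls
}

#' Inspection: excise suspect bases around long indel runs
#'
#' Every run of indel cells (insertions plus deletions, transparent cells not
#' interrupting) totalling at least \code{gapTriggerLen} is excised together
#' with \code{flankW} aligned read bases on each side; the excised read
#' coordinates are recorded in \code{removed}. In long-read mode the
#' alignment is returned unchanged, since projected gaps are expected there.
#'
#' @param ga a projected \linkS4class{GraphAlignment}.
#' @param params an \linkS4class{InspectionParams}.
#' @param scheme scoring scheme for the re-scored result.
#' @export
inspectAlignment <- function(ga, params = inspectionParams(),
                             scheme = scoringScheme()) {
  if (params@longReadMode || ga@mode == "long") return(ga)
  cells <- ga@cells
  cls <- cellClass(cells)
  g <- which(cls == "G")
  if (length(g) == 0L) return(ga)
  ## group indel cells into runs separated by aligned (M) cells
  ## (transparent cells do not interrupt a run)
  mPos <- which(cls == "M")
  runId <- cumsum(c(TRUE, vapply(seq_along(g)[-1L], function(i)
    any(mPos > g[i - 1L] & mPos < g[i]), TRUE)))
  drop <- rep(FALSE, nrow(cells))
  for (run in split(g, runId)) {
    ## floating insertions could not be placed at their site at all: treat
    ## any run containing one as level-misassignment evidence, whatever its
    ## length
    hasFloat <- any(is.na(cells$edge[run]))
    if (length(run) < params@gapTriggerLen && !hasFloat) next
    left <- mPos[mPos < min(run)]
    right <- mPos[mPos > max(run)]
    lo <- if (params@flankW > 0L && length(left))
      left[max(1L, length(left) - params@flankW + 1L)] else min(run)
    hi <- if (params@flankW > 0L && length(right))
      right[min(params@flankW, length(right))] else max(run)
    drop[lo:hi] <- TRUE
  }
  if (!any(drop)) return(ga)
  ## removed read intervals, one per contiguous dropped region
  removed <- ga@removed
  region <- cumsum(c(TRUE, diff(which(drop)) > 1L))
  for (reg in split(which(drop), region)) {
    rp <- cells$readPos[reg]
    rp <- rp[!is.na(rp)]
    if (length(rp)) {
      removed <- rbind(removed, c(min(rp), max(rp) + 1L))
    } else {
      after <- cells$readPos[seq_len(nrow(cells)) > max(reg)]
      after <- after[!is.na(after)]
      at <- if (length(after)) after[1L] else ga@clipPrefix
      removed <- rbind(removed, c(at, at))   # pure-deletion excision
    }
  }
  newGraphAlignment(ga@readId, cells[!drop, , drop = FALSE],
                    ga@clipPrefix, ga@clipSuffix, ga@mode, scheme,
                    removed = removed, meta = ga@meta)
}

splitSegments <- function(cells) {
  ## contiguous runs of levels among non-floating cells define segments;
  ## floating cells belong to the segment they sit inside
  lv <- cells$level
  anchored <- !is.na(cells$edge)
  brk <- c(FALSE, diff(ifelse(anchored, lv, NA))[
    seq_len(nrow(cells) - 1L)] > 1L & anchored[-1L])
  ## recompute break positions: a new segment starts at an anchored cell
  ## whose level exceeds the previous anchored cell's level by > 1
  lastLv <- NA_integer_
  seg <- integer(nrow(cells))
  cur <- 1L
  for (i in seq_len(nrow(cells))) {
    if (anchored[i]) {
      if (!is.na(lastLv) && lv[i] > lastLv + 1L) cur <- cur + 1L
      lastLv <- lv[i]
    }
    seg[i] <- cur
  }
  seg
}

#' Polishing: best edge choice at fixed levels
#'
#' Holds each cell's level fixed and re-chooses, by dynamic programming over
#' boundary nodes with transitions restricted to graph edges, the
#' maximum-score edge per level. Floating insertions keep their cost;
#' contiguous level segments (holes arise from inspection) are polished
#' independently.
#'
#' @param ga a \linkS4class{GraphAlignment} from project/inspect.
#' @param prg the graph.
#' @param scheme scoring scheme.
#' @export
polishAlignment <- function(ga, prg, scheme = scoringScheme()) {
  cells <- ga@cells
  if (nrow(cells) == 0L) stop("polish: empty level range")
  e <- prg@edges
  elabAll <- edgeLabelCodes(e$label)
  seg <- splitSegments(cells)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    sub <- cells[idx, , drop = FALSE]
    anch <- !is.na(sub$edge)
    if (!any(anch)) next
    l0 <- min(sub$level[anch]); l1 <- max(sub$level[anch])
    cand <- which(e$level >= l0 & e$level <= l1)
    cand <- cand[order(e$level[cand], e$label[cand], e$from[cand])]
    res <- cpp_polish(sub$bcode, !anch,
                      e$level[cand], e$from[cand], e$to[cand],
                      elabAll[cand], l0, l1 - l0 + 1L,
                      schemeVector(scheme))
    chosen <- cand[res$choice]          # edge row per level l0..l1
    cells$edge[idx[anch]] <- chosen[sub$level[anch] - l0 + 1L]
    cells$elab[idx[anch]] <- elabAll[cells$edge[idx[anch]]]
  }
  ga@cells <- cells
  ga@score <- scoreGraphAlignment(cells, scheme)
  ga
}

subgraphFor <- function(prg, lb, rb) {
  ## levels [lb, rb), boundaries lb..rb, local renumbering
  e <- prg@edges
  rows <- which(e$level >= lb & e$level < rb)
  rows <- rows[order(e$level[rows], e$label[rows], e$from[rows])]
  nodes <- which(prg@nodeBoundary >= lb & prg@nodeBoundary <= rb)
  localNode <- match(seq_along(prg@nodeBoundary), nodes)  # global -> local
  list(rows = rows,
       nodeBoundary = prg@nodeBoundary[nodes] - lb,
       localNode = localNode,
       edgeLevel = e$level[rows] - lb,
       edgeFrom = localNode[e$from[rows]] - 1L,
       edgeTo = localNode[e$to[rows]] - 1L,
       edgeLab = edgeLabelCodes(e$label[rows]))
}

runSubAlign <- function(prg, sg, readCodes, scheme, startNode = -1L,
                        endNode = -1L, freeStart = FALSE, freeEnd = FALSE,
                        clipStart = FALSE, clipEnd = FALSE, band = NULL) {
  jLo <- integer(0); jHi <- integer(0)
  L <- max(c(sg$edgeLevel + 1L, sg$nodeBoundary, 0L))
  if (!is.null(band)) {
    b <- 0:L
    expect <- round(band$anchor0 + b * band$slope)
    jLo <- as.integer(expect - band$w); jHi <- as.integer(expect + band$w)
  }
  res <- cpp_full_align(readCodes, L, sg$nodeBoundary,
                        sg$edgeLevel, sg$edgeFrom, sg$edgeTo, sg$edgeLab,
                        schemeVector(scheme), freeStart, freeEnd,
                        clipStart, clipEnd, startNode, endNode, jLo, jHi)
  if (!res$feasible && !is.null(band))
    res <- cpp_full_align(readCodes, L, sg$nodeBoundary,
                          sg$edgeLevel, sg$edgeFrom, sg$edgeTo, sg$edgeLab,
                          schemeVector(scheme), freeStart, freeEnd,
                          clipStart, clipEnd, startNode, endNode,
                          integer(0), integer(0))
  res
}

subAlignCells <- function(res, sg, prg, lb, readChars, readOffset) {
  if (length(res$level) == 0L) return(makeCells())
  edgeGlobal <- rep(NA_integer_, length(res$edge))
  anch <- res$edge >= 0L
  edgeGlobal[anch] <- sg$rows[res$edge[anch] + 1L]
  elab <- rep(-1L, length(edgeGlobal))
  elab[anch] <- edgeLabelCodes(prg@edges$label)[edgeGlobal[anch]]
  rp <- rep(NA_integer_, length(res$readPos))
  hasBase <- res$readPos >= 0L
  rp[hasBase] <- res$readPos[hasBase] + readOffset
  base <- rep("-", length(rp))
  base[hasBase] <- readChars[rp[hasBase] + 1L]
  makeCells(res$level + lb, edgeGlobal, elab, base, rp)
}

#' Extension: re-align removed intervals and clipped ends by graph DP
#'
#' Every read interval not covered by cells (inspection removals and soft
#' clips alike) is re-aligned by banded full graph DP anchored at the
#' flanking retained cells; the band is widened to the full matrix if the
#' anchors cannot be connected, and if the graph structure still does not
#' admit a connection the whole read falls back to full graph alignment.
#' End intervals may remain soft-clipped only where they fall outside the
#' graph's level range. In long mode only end-extension applies.
#'
#' @param ga a polished \linkS4class{GraphAlignment}.
#' @param prg,scheme graph and scoring scheme.
#' @param readSeq the complete read sequence (needed to restore removed and
#'   clipped bases).
#' @export
extendAlignment <- function(ga, prg, scheme = scoringScheme(),
                            readSeq = ga@meta$readSeq) {
  if (is.null(readSeq)) stop("extendAlignment needs the full read sequence")
  readChars <- strsplit(readSeq, "")[[1L]]
  n <- length(readChars)
  cells <- ga@cells
  clipPrefix <- ga@clipPrefix
  clipSuffix <- ga@clipSuffix
  longMode <- ga@mode == "long"
  ranDP <- FALSE
  fellBack <- FALSE
  resolvedPrefix <- clipPrefix == 0L   # initial clips are re-aligned once
  resolvedSuffix <- clipSuffix == 0L

  ## A "job" is a stretch of read bases and/or levels between two retained
  ## base cells (or a read end) that is not yet represented: read positions
  ## not carried by any cell (clips excluded), or a hole in level coverage.
  ## Floating insertion cells inside a job's span are re-aligned with it.
  nextJob <- function() {
    edgeV <- cells$edge; rposV <- cells$readPos
    lvlV <- cells$level; bcV <- cells$bcode
    base <- which(!is.na(edgeV) & bcV >= 0L)
    if (length(base) == 0L) return(list(kind = "fallback"))
    covered <- rep(FALSE, n)
    covered[rposV[!is.na(rposV)] + 1L] <- TRUE
    ## clips already pushed outside the graph's level range stay resolved
    if (resolvedPrefix && clipPrefix > 0L) covered[seq_len(clipPrefix)] <- TRUE
    if (resolvedSuffix && clipSuffix > 0L)
      covered[(n - clipSuffix + 1L):n] <- TRUE
    anch <- which(!is.na(edgeV))
    holeAt <- anch[which(diff(lvlV[anch]) > 1L)]
    uncPos <- which(!covered) - 1L            # 0-based
    if (length(uncPos) == 0L && length(holeAt) == 0L)
      return(list(kind = "done"))
    rp <- rposV[base]
    if (length(uncPos) && uncPos[1L] < rp[1L])
      return(list(kind = "prefix", rightIdx = base[1L],
                  r0 = 0L, r1 = rp[1L] - 1L))
    ## candidate mid jobs (short mode only): earliest wins
    iMidU <- iMidH <- NA_integer_
    if (!longMode) {
      uIn <- uncPos[uncPos > rp[1L] & uncPos < rp[length(rp)]]
      if (length(uIn)) iMidU <- max(which(rp < uIn[1L]))
      if (length(holeAt)) {
        h <- holeAt[1L]
        bLeft <- which(base <= h)
        if (length(bLeft) == 0L || all(base <= h))
          return(list(kind = "fallback"))
        iMidH <- max(bLeft)
      }
    }
    if (!is.na(iMidU) || !is.na(iMidH)) {
      kI <- min(iMidU, iMidH, na.rm = TRUE)
      i <- base[kI]; j <- base[kI + 1L]
      return(list(kind = "mid", leftIdx = i, rightIdx = j,
                  r0 = rposV[i] + 1L, r1 = rposV[j] - 1L))
    }
    floatAfter <- base[length(base)] < nrow(cells) &&
      any(is.na(edgeV[(base[length(base)] + 1L):nrow(cells)]))
    if ((length(uncPos) && uncPos[length(uncPos)] > rp[length(rp)]) ||
        (!longMode && floatAfter))
      return(list(kind = "suffix", leftIdx = base[length(base)],
                  r0 = rp[length(rp)] + 1L, r1 = n - 1L))
    list(kind = "done")
  }

  sawJob <- FALSE
  repeat {
    job <- nextJob()
    if (job$kind == "done") break
    sawJob <- TRUE
    if (job$kind == "fallback") { fellBack <- TRUE; break }
    lenIv <- job$r1 - job$r0 + 1L       # may be 0 (pure level hole)
    subChars <- if (lenIv > 0L) readChars[(job$r0:job$r1) + 1L]
                else character(0)
    codes <- baseCodes(subChars)
    w <- 2L * lenIv + 10L

    if (job$kind == "mid") {
      i <- job$leftIdx; j <- job$rightIdx
      lb <- cells$level[i] + 1L
      rb <- cells$level[j]
      if (rb <= lb) {
        ## adjacent levels: nothing to traverse, bases stay floating
        ins <- if (lenIv > 0L)
          makeCells(rep(cells$level[i], lenIv), NA_integer_, -1L,
                    subChars, job$r0:job$r1) else cells[0L, ]
        cells <- rbind(cells[seq_len(i), ], ins,
                       cells[j:nrow(cells), ])
        next
      }
      startNodeG <- prg@edges$to[cells$edge[i]]
      endNodeG <- prg@edges$from[cells$edge[j]]
      sg <- subgraphFor(prg, lb, rb)
      band <- list(anchor0 = 0, slope = lenIv / max(1L, rb - lb), w = w)
      res <- runSubAlign(prg, sg, codes, scheme,
                         startNode = sg$localNode[startNodeG] - 1L,
                         endNode = sg$localNode[endNodeG] - 1L, band = band)
      ranDP <- TRUE
      if (!res$feasible) { fellBack <- TRUE; break }
      newCells <- subAlignCells(res, sg, prg, lb, readChars, job$r0)
      cells <- rbind(cells[seq_len(i), ], newCells,
                     cells[j:nrow(cells), ])
    } else if (job$kind == "prefix") {
      resolvedPrefix <- TRUE
      j <- job$rightIdx
      rb <- cells$level[j]
      if (rb == 0L) { clipPrefix <- job$r1 + 1L; next }
      endNodeG <- prg@edges$from[cells$edge[j]]
      sg <- subgraphFor(prg, 0L, rb)
      band <- list(anchor0 = lenIv - rb, slope = 1, w = w)
      res <- runSubAlign(prg, sg, codes, scheme, freeStart = TRUE,
                         clipStart = TRUE,
                         endNode = sg$localNode[endNodeG] - 1L, band = band)
      ranDP <- TRUE
      if (!res$feasible) { fellBack <- TRUE; break }
      newCells <- subAlignCells(res, sg, prg, 0L, readChars, job$r0)
      clipPrefix <- job$r0 + res$clipPrefix
      cells <- rbind(newCells, cells[j:nrow(cells), ])
    } else {                            # suffix
      resolvedSuffix <- TRUE
      i <- job$leftIdx
      lb <- cells$level[i] + 1L
      if (lb >= prg@levelCount) { clipSuffix <- n - job$r0; next }
      startNodeG <- prg@edges$to[cells$edge[i]]
      sg <- subgraphFor(prg, lb, prg@levelCount)
      band <- list(anchor0 = 0, slope = 1, w = w)
      res <- runSubAlign(prg, sg, codes, scheme,
                         startNode = sg$localNode[startNodeG] - 1L,
                         freeEnd = TRUE, clipEnd = TRUE, band = band)
      ranDP <- TRUE
      if (!res$feasible) { fellBack <- TRUE; break }
      newCells <- subAlignCells(res, sg, prg, lb, readChars, job$r0)
      clipSuffix <- res$clipSuffix
      cells <- rbind(cells[seq_len(i), ], newCells)
    }
  }

  if (fellBack) {
    out <- fullGraphAlign(readSeq, prg, scheme, readId = ga@readId,
                          mode = ga@mode)
    out@meta <- ga@meta
    out@meta$extensionRan <- TRUE
    out@meta$fellBack <- TRUE
    return(out)
  }
  ga@meta$extensionRan <- ranDP
  if (!sawJob) return(ga)                  # nothing to do: common fast path
  ga@cells <- cells
  ga@clipPrefix <- as.integer(clipPrefix)
  ga@clipSuffix <- as.integer(clipSuffix)
  ga@removed <- matrix(0L, 0L, 2L)
  ga@score <- scoreGraphAlignment(cells, scheme)
  ga
}

#' Exhaustive full graph alignment score (no traceback)
#'
#' Same semantics as \code{fullGraphAlign} but computes only the optimal
#' score, with rolling storage; used to decide cheaply whether a read can
#' benefit from full graph alignment.
#'
#' @param readSeq read bases.
#' @param prg,scheme graph and scoring scheme.
#' @export
fullGraphAlignScore <- function(readSeq, prg, scheme = scoringScheme()) {
  if (nchar(readSeq) == 0L) stop("empty read")
  readChars <- strsplit(toupper(readSeq), "")[[1L]]
  sg <- subgraphFor(prg, 0L, prg@levelCount)
  L <- max(c(sg$edgeLevel + 1L, sg$nodeBoundary, 0L))
  cpp_full_align_score(baseCodes(readChars), L, sg$nodeBoundary,
                       sg$edgeLevel, sg$edgeFrom, sg$edgeTo, sg$edgeLab,
                       schemeVector(scheme), TRUE, TRUE, TRUE, TRUE,
                       -1L, -1L)
}

#' Exhaustive full graph alignment
#'
#' Optimal affine-gap, semi-global alignment of a read against all level
#' paths of the graph: leading and trailing level skips are free, and read
#' ends may remain soft-clipped (at zero score) only outside the graph's
#' level range. Without a band this is exhaustive and serves as the
#' package's alignment oracle.
#'
#' @param readSeq read bases.
#' @param prg the graph.
#' @param scheme scoring scheme.
#' @param readId,mode metadata for the result.
#' @export
fullGraphAlign <- function(readSeq, prg, scheme = scoringScheme(),
                           readId = "read", mode = "short") {
  if (nchar(readSeq) == 0L) stop("empty read")
  readChars <- strsplit(toupper(readSeq), "")[[1L]]
  sg <- subgraphFor(prg, 0L, prg@levelCount)
  res <- runSubAlign(prg, sg, baseCodes(readChars), scheme,
                     freeStart = TRUE, freeEnd = TRUE,
                     clipStart = TRUE, clipEnd = TRUE)
  if (!res$feasible) stop("graph admits no alignment")
  cells <- subAlignCells(res, sg, prg, 0L, readChars, 0L)
  newGraphAlignment(readId, cells, res$clipPrefix, res$clipSuffix, mode,
                    scheme, meta = list(locus = prg@locus,
                                        extensionRan = NA))
}

#' Align one read: project, inspect, polish, extend
#'
#' The hybrid pipeline. Records in \code{meta} the scores after each stage
#' and whether the extension stage ran (the skip statistic).
#'
#' @param lin a \linkS4class{LinearAlignment}.
#' @param prg graph.
#' @param scheme scoring scheme.
#' @param mode \code{"short"} or \code{"long"}; long mode makes inspection
#'   the identity and limits extension to read ends.
#' @param params inspection parameters (long-read flag is implied by
#'   \code{mode}).
#' @return A \linkS4class{GraphAlignment}, or NULL (with a message) when the
#'   read's projected span lies outside the graph.
#' @export
alignRead <- function(lin, prg, scheme = scoringScheme(), mode = "short",
                      params = inspectionParams()) {
  if (lin@refStart >= length(prg@cmap[[lin@referenceId]]$res2lvl))
    return(NULL)
  ga <- projectAlignment(lin, prg, scheme, mode)
  ga@meta$readSeq <- lin@readSeq
  ga@meta$projectedScore <- ga@score
  if (mode == "long") params@longReadMode <- TRUE
  ga <- inspectAlignment(ga, params, scheme)
  ga@meta$inspectedScore <- ga@score
  ## inspection may excise every cell; extension then re-aligns from scratch
  if (nrow(ga@cells) > 0L) ga <- polishAlignment(ga, prg, scheme)
  ga@meta$polishedScore <- ga@score
  ga <- extendAlignment(ga, prg, scheme, readSeq = lin@readSeq)
  ## a short-mode read whose repaired alignment still scores below the
  ## perfect-match score may have switched between divergent haplotypes in
  ## a way the local heuristics cannot see: switch into full graph
  ## alignment mode (reads that projected cleanly never get here)
  if (mode == "short" &&
      ga@score < nchar(lin@readSeq) * scheme@match - 1e-9) {
    ga@meta$extensionRan <- TRUE      # the read paid for a full-graph DP
    if (fullGraphAlignScore(lin@readSeq, prg, scheme) > ga@score + 1e-9) {
      full <- fullGraphAlign(lin@readSeq, prg, scheme, readId = lin@readId,
                             mode = mode)
      meta <- ga@meta
      meta$fellBack <- TRUE
      full@meta <- meta
      ga <- full
    }
  }
  ga@meta$finalScore <- ga@score
  ga
}

#' Brute-force fixed-level optimum by path enumeration
#'
#' Enumerates every edge-choice path over the alignment's level range
#' (per contiguous segment) and scores each candidate with
#' \code{scoreGraphAlignment}; the maximum is the exhaustive reference the
#' polishing DP must attain. Exponential in the worst case: intended for
#' small graphs.
#'
#' @param ga a \linkS4class{GraphAlignment} (typically freshly projected).
#' @param prg,scheme graph and scoring scheme.
#' @param maxPaths enumeration guard.
#' @export
polishEnumerationScore <- function(ga, prg, scheme = scoringScheme(),
                                   maxPaths = 1e6) {
  cells <- ga@cells
  seg <- splitSegments(cells)
  elabAll <- edgeLabelCodes(prg@edges$label)
  total <- 0
  for (s in unique(seg)) {
    idx <- which(seg == s)
    sub <- cells[idx, , drop = FALSE]
    anch <- !is.na(sub$edge)
    if (!any(anch)) { total <- total + scoreGraphAlignment(sub, scheme); next }
    l0 <- min(sub$level[anch]); l1 <- max(sub$level[anch])
    best <- -Inf
    for (p in enumerateLevelPaths(prg, l0, l1, maxPaths)) {
      cand <- sub
      cand$edge[anch] <- p[sub$level[anch] - l0 + 1L]
      cand$elab[anch] <- elabAll[cand$edge[anch]]
      sc <- scoreGraphAlignment(cand, scheme)
      if (sc > best) best <- sc
    }
    total <- total + best
  }
  total
}
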