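#' Chaining penalties for assembly alignment
#'
#' Diagonals score \code{length * match}; horizontal (reference skip) and
#' vertical (contig skip) jumps are penalized affinely and identically;
#' leading/trailing reference skips are free (semi-global in the reference).
#'
#' @param match,jumpOpen,jumpExtend scores.
#' @export
chainScoring <- function(match = 1, jumpOpen = -6, jumpExtend = -0.5) {
  list(match = match, jumpOpen = jumpOpen, jumpExtend = jumpExtend)
}

.subMatCache <- new.env(parent = emptyenv())
.nucSubMat <- function() {
  if (is.null(.subMatCache$m))
    .subMatCache$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -4, baseOnly = FALSE)
  .subMatCache$m
}

kmerHits <- function(a, b, k) {
  ## all (posA, posB) 0-based start pairs of shared k-mers
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(matrix(0L, 0L, 2L))
  ka <- substring(a, 1:(na - k + 1L), k:na)
  kb <- substring(b, 1:(nb - k + 1L), k:nb)
  idx <- split(seq_along(ka), ka)
  hits <- idx[kb]
  lens <- lengths(hits)
  keep <- lens > 0L
  if (!any(keep)) return(matrix(0L, 0L, 2L))
  cbind(unlist(hits[keep], use.names = FALSE) - 1L,
        rep(which(keep), lens[keep]) - 1L)
}

#' Find gap-free exact-match diagonals between two sequences
#'
#' Maximal exact matches of length at least \code{minLen}, located by shared
#' k-mers merged along their diagonals. With \code{minLen >= k} the result
#' is exactly the set of maximal exact matches of that length.
#'
#' @param contig,haplotype sequences (character).
#' @param k k-mer size (>= 8 for the default anchoring regime).
#' @param minLen minimum diagonal length to keep.
#' @return data.frame with 0-based half-open \code{cs,ce,rs,re} and
#'   \code{len}.
#' @export
findDiagonals <- function(contig, haplotype, k = 15L, minLen = 20L) {
  hits <- kmerHits(haplotype, contig, k)   # col1 = ref pos, col2 = contig pos
  empty <- data.frame(cs = integer(0), ce = integer(0), rs = integer(0),
                      re = integer(0), len = integer(0))
  if (nrow(hits) == 0L) return(empty)
  d <- hits[, 2L] - hits[, 1L]             # contig - ref offset
  out <- lapply(split(seq_len(nrow(hits)), d), function(ii) {
    cp <- sort(hits[ii, 2L])
    grp <- cumsum(c(1L, diff(cp) > k))
    do.call(rbind, lapply(split(cp, grp), function(run)
      c(run[1L], run[length(run)] + k)))
  })
  segs <- do.call(rbind, unname(Map(function(m, dd)
    cbind(m, m - as.integer(dd)), out, names(out))))
  res <- data.frame(cs = segs[, 1L], ce = segs[, 2L],
                    rs = segs[, 3L], re = segs[, 4L])
  res$len <- res$ce - res$cs
  res <- res[res$len >= minLen, , drop = FALSE]
  res[order(res$cs, res$rs), , drop = FALSE]
}

#' All maximal exact matches, any length (exhaustive anchors)
#'
#' Quadratic diagonal scan; the anchor set used when chaining must be exact
#' against the full-matrix DP.
#'
#' @param contig,haplotype sequences.
#' @return data.frame like \code{findDiagonals}.
#' @export
exhaustiveDiagonals <- function(contig, haplotype) {
  a <- strsplit(contig, "")[[1L]]; b <- strsplit(haplotype, "")[[1L]]
  n <- length(a); m <- length(b)
  acc <- vector("list", n + m - 1L)
  for (off in (-(m - 1L)):(n - 1L)) {
    ci <- max(0L, off):(min(n - 1L, m - 1L + off))
    ri <- ci - off
    eq <- a[ci + 1L] == b[ri + 1L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)
    if (length(w))
      acc[[off + m]] <- data.frame(
        cs = ci[starts[w]], ce = ci[ends[w]] + 1L,
        rs = ri[starts[w]], re = ri[ends[w]] + 1L,
        len = r$lengths[w])
  }
  d <- do.call(rbind, acc)
  if (is.null(d)) d <- findDiagonals("", "", 1L, 1L)
  d[order(d$cs, d$rs), , drop = FALSE]
}

#' Chain diagonals into a semi-global alignment
#'
#' Dynamic programming over the diagonal set: the highest-scoring strictly
#' monotone chain under affine jump penalties, global in the contig and free
#' at the reference ends. Overlapping diagonals are reconciled by minimally
#' trimming the downstream diagonal's start.
#'
#' @param diagonals data.frame from \code{findDiagonals}.
#' @param contigLen,refLen sequence lengths.
#' @param scoring from \code{chainScoring}.
#' @param contigId,haplotypeId identifiers carried into the result.
#' @param contigSeq,refSeq optional sequences; when given, jump regions up
#'   to 2 kb are re-aligned by global DP so that the base-level coordinate
#'   map is exact near feature boundaries.
#' @return A \linkS4class{ChainedAlignment}.
#' @export
chainSemiglobal <- function(diagonals, contigLen, refLen,
                            scoring = chainScoring(), contigId = "contig",
                            haplotypeId = "ref", contigSeq = NULL,
                            refSeq = NULL) {
  if (nrow(diagonals) == 0L)
    return(new("ChainedAlignment", contigId = contigId,
               haplotypeId = haplotypeId, diagonals = diagonals,
               jumps = data.frame(), score = 0,
               refMap = rep(NA_integer_, refLen),
               contigLen = as.integer(contigLen),
               refLen = as.integer(refLen), unalignable = TRUE))
  res <- cpp_chain_dp(diagonals$cs, diagonals$ce, diagonals$rs,
                      diagonals$re, contigLen, scoring$match,
                      scoring$jumpOpen, scoring$jumpExtend)
  sel <- diagonals[res$chain, , drop = FALSE]
  sel$cs <- sel$cs + res$trim
  sel$rs <- sel$rs + res$trim
  sel$len <- sel$ce - sel$cs
  ## jumps between consecutive chained diagonals
  nj <- nrow(sel) - 1L
  jumps <- if (nj > 0L)
    data.frame(h = sel$rs[-1L] - sel$re[-nrow(sel)],
               v = sel$cs[-1L] - sel$ce[-nrow(sel)])
  else data.frame(h = integer(0), v = integer(0))
  if (nrow(jumps)) {
    aff <- function(g) ifelse(g > 0L, scoring$jumpOpen +
                                (g - 1L) * scoring$jumpExtend, 0)
    jumps$penalty <- aff(jumps$h) + aff(jumps$v)
  }
  refMap <- rep(NA_integer_, refLen)
  for (i in seq_len(nrow(sel)))
    refMap[(sel$rs[i] + 1L):sel$re[i]] <- sel$cs[i]:(sel$ce[i] - 1L)
  ## base-level re-alignment inside jumps (for annotation projection)
  if (!is.null(contigSeq) && !is.null(refSeq) && nj > 0L) {
    for (i in seq_len(nj)) {
      h <- jumps$h[i]; v <- jumps$v[i]
      if (h <= 0L || v <= 0L || h > 2000L || v > 2000L) next
      if (h == v) {                      # substitution run: diagonal map
        refMap[(sel$re[i] + 1L):sel$rs[i + 1L]] <-
          sel$ce[i]:(sel$cs[i + 1L] - 1L)
        next
      }
      rseg <- substr(refSeq, sel$re[i] + 1L, sel$rs[i + 1L])
      cseg <- substr(contigSeq, sel$ce[i] + 1L, sel$cs[i + 1L])
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cseg), Biostrings::DNAString(rseg),
        type = "global", gapOpening = 6, gapExtension = 1,
        substitutionMatrix = .nucSubMat())
      pg <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
      sg <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
      cpos <- sel$ce[i]; rpos <- sel$re[i]
      for (t in seq_along(pg)) {
        if (pg[t] != "-" && sg[t] != "-") refMap[rpos + 1L] <- cpos
        if (pg[t] != "-") cpos <- cpos + 1L
        if (sg[t] != "-") rpos <- rpos + 1L
      }
    }
  }
  new("ChainedAlignment", contigId = contigId, haplotypeId = haplotypeId,
      diagonals = sel, jumps = jumps, score = res$score,
      refMap = as.integer(refMap),
      contigLen = as.integer(contigLen), refLen = as.integer(refLen),
      unalignable = FALSE)
}

#' @export
setMethod("show", "ChainedAlignment", function(object) {
  cat(sprintf(
    "ChainedAlignment %s vs %s: %d diagonals, score %.1f%s\n",
    object@contigId, object@haplotypeId, nrow(object@diagonals),
    object@score, if (object@unalignable) " (unalignable)" else ""))
})

#' Full-matrix semi-global alignment score (reference implementation)
#'
#' Exact DP over the complete alignment matrix under the chaining gap model:
#' diagonal moves only on exact matches (\code{+match}), affine horizontal
#' and vertical gaps (a substitution costs one of each), free leading and
#' trailing reference skips, global in the contig. Used to validate
#' \code{chainSemiglobal}.
#'
#' @param contig,haplotype sequences.
#' @param scoring from \code{chainScoring}.
#' @return numeric score.
#' @export
semiglobalDpScore <- function(contig, haplotype, scoring = chainScoring()) {
  a <- strsplit(contig, "")[[1L]]; b <- strsplit(haplotype, "")[[1L]]
  n <- length(a); m <- length(b)
  go <- scoring$jumpOpen; ge <- scoring$jumpExtend; ma <- scoring$match
  ## rows = contig prefix length 0..n; columns = reference 0..m
  M <- rep(-Inf, m + 1L); H <- rep(-Inf, m + 1L); V <- rep(-Inf, m + 1L)
  M[] <- 0                                  # free leading reference skip
  ## H within row 0 is never better than the free start; V needs row > 0
  for (i in seq_len(n)) {
    prevBest <- pmax(M, H, V)
    Mn <- rep(-Inf, m + 1L); Hn <- rep(-Inf, m + 1L)
    Vn <- pmax(M + go, H + go, V + ge)      # vertical: consume contig base
    if (m > 0L) {
      eq <- a[i] == b
      diag <- prevBest[1:m] + ifelse(eq, ma, -Inf)
      Mn[2:(m + 1L)] <- diag
    }
    ## horizontal within the row: affine, vectorized via running max
    best0 <- pmax(Mn, Vn)
    run <- -Inf
    for (j in seq_len(m)) {
      run <- max(run + ge, best0[j] + go)
      Hn[j + 1L] <- run
    }
    M <- Mn; H <- Hn; V <- Vn
  }
  max(M, H, V)                              # free trailing reference skip
}

#' Identify contig/haplotype candidate pairs
#'
#' Pairs sharing at least one exact match of \code{minAnchorLen} bases.
#'
#' @param contigs,haplotypes named character vectors.
#' @param minAnchorLen anchor length.
#' @return data.frame with columns \code{contig}, \code{haplotype}.
#' @export
identifyOverlappingContigs <- function(contigs, haplotypes,
                                       minAnchorLen = 20L) {
  out <- list()
  for (cn in names(contigs)) for (hn in names(haplotypes)) {
    if (nrow(kmerHits(haplotypes[[hn]], contigs[[cn]],
                      minAnchorLen)) > 0L)
      out[[length(out) + 1L]] <- data.frame(contig = cn, haplotype = hn)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(contig = character(0), haplotype = character(0))
}

#' Best-scoring haplotype chain for a contig
#'
#' @param contigSeq contig sequence.
#' @param contigId contig name.
#' @param haplotypes named character vector of candidate haplotypes.
#' @param k,minLen diagonal anchoring parameters.
#' @param scoring chaining penalties.
#' @return The highest-scoring \linkS4class{ChainedAlignment} (ties break to
#'   the lexicographically first haplotype id), or NULL when every candidate
#'   is unalignable.
#' @export
bestHaplotype <- function(contigSeq, contigId, haplotypes, k = 15L,
                          minLen = 20L, scoring = chainScoring()) {
  best <- NULL
  for (hn in sort(names(haplotypes))) {
    d <- findDiagonals(contigSeq, haplotypes[[hn]], k, minLen)
    ch <- chainSemiglobal(d, nchar(contigSeq), nchar(haplotypes[[hn]]),
                          scoring, contigId, hn, contigSeq,
                          haplotypes[[hn]])
    if (ch@unalignable) next
    if (is.null(best) || ch@score > best@score) best <- ch
  }
  best
}

#' Project haplotype annotations onto a contig
#'
#' Maps each feature's reference interval through the chain's base-level
#' alignment. Features entirely inside reference skips are flagged
#' unprojectable; partial overlaps are truncated and flagged.
#'
#' @param chain a \linkS4class{ChainedAlignment}.
#' @param ann annotation GRanges (as from \code{readAnnotationsTsv}).
#' @return data.frame: locus, kind, exon_index, ref_start, ref_end,
#'   contig_start, contig_end (0-based half-open), status.
#' @export
projectAnnotations <- function(chain, ann) {
  ann <- ann[as.character(GenomicRanges::seqnames(ann)) ==
               chain@haplotypeId]
  rows <- lapply(seq_along(ann), function(i) {
    s <- GenomicRanges::start(ann)[i] - 1L
    e <- GenomicRanges::end(ann)[i]
    mp <- chain@refMap[(s + 1L):e]
    ok <- !is.na(mp)
    if (!any(ok))
      return(data.frame(locus = ann$locus[i], kind = ann$kind[i],
                        exon_index = ann$exon_index[i], ref_start = s,
                        ref_end = e, contig_start = NA_integer_,
                        contig_end = NA_integer_, status = "unprojectable"))
    status <- if (ok[1L] && ok[length(ok)]) "projected" else "truncated"
    data.frame(locus = ann$locus[i], kind = ann$kind[i],
               exon_index = ann$exon_index[i], ref_start = s, ref_end = e,
               contig_start = min(mp[ok]), contig_end = max(mp[ok]) + 1L,
               status = status)
  })
  do.call(rbind, rows)
}

#' Match an extracted sequence against the allele database
#'
#' Global Levenshtein edit distance against every allele of the locus;
#' genomic mode compares gene-level genomic sequences (genomic-coverage
#' alleles), exon mode compares concatenated exon sequences (exon-only
#' alleles). Ties break to the lexicographically smallest allele id.
#'
#' @param extractedSeq extracted gene (or concatenated exon) sequence.
#' @param db an \linkS4class{AlleleDatabase}.
#' @param mode \code{"genomic"} or \code{"exon_concatenated"}.
#' @return list(alleleId, editDistance).
#' @export
matchDatabase <- function(extractedSeq, db,
                          mode = c("genomic", "exon_concatenated")) {
  mode <- match.arg(mode)
  if (nchar(extractedSeq) == 0L) stop("extracted sequence is empty")
  keep <- if (mode == "genomic") db@coverage == "genomic"
          else db@coverage == "exon_only"
  if (!any(keep)) keep <- rep(TRUE, length(db@ids))  # degenerate database
  cand <- if (mode == "genomic") db@geneSeqs[keep] else db@exonSeqs[keep]
  ids <- db@ids[keep]
  d <- as.integer(adist(extractedSeq, cand))
  best <- which(d == min(d))
  pick <- best[order(ids[best])][1L]
  list(alleleId = ids[pick], editDistance = d[pick])
}

#' Type assembled contigs
#'
#' Full pipeline per contig: candidate haplotypes by shared anchors, best
#' chained semi-global alignment, annotation projection, gene extraction and
#' minimum-edit-distance database matching. Each gene yields at most one
#' call per contig; competing projections resolve by lowest edit distance,
#' then longest extracted span.
#'
#' @param contigs named character vector of contig sequences.
#' @param haplotypes named character vector of annotated reference
#'   haplotypes.
#' @param ann annotation GRanges.
#' @param dbs named list (locus -> \linkS4class{AlleleDatabase}).
#' @param mode matching mode (see \code{matchDatabase}).
#' @param k,minLen,minAnchorLen anchoring parameters.
#' @param scoring chaining penalties.
#' @return data.frame of calls: contig, locus, allele, edit_distance, mode,
#'   gene_start, gene_end.
#' @export
typeAssembly <- function(contigs, haplotypes, ann, dbs,
                         mode = "genomic", k = 15L, minLen = 20L,
                         minAnchorLen = 20L, scoring = chainScoring()) {
  calls <- list()
  cand <- identifyOverlappingContigs(contigs, haplotypes, minAnchorLen)
  for (cn in unique(cand$contig)) {
    haps <- haplotypes[cand$haplotype[cand$contig == cn]]
    ch <- bestHaplotype(contigs[[cn]], cn, haps, k, minLen, scoring)
    if (is.null(ch)) next
    feats <- projectAnnotations(ch, ann)
    genes <- feats[feats$kind == "gene" & feats$status != "unprojectable", ,
                   drop = FALSE]
    for (gi in seq_len(nrow(genes))) {
      loc <- genes$locus[gi]
      if (is.null(dbs[[loc]])) next
      seq <- substr(contigs[[cn]], genes$contig_start[gi] + 1L,
                    genes$contig_end[gi])
      if (mode == "exon_concatenated") {
        ex <- feats[feats$kind == "exon" & feats$locus == loc &
                      feats$status != "unprojectable", , drop = FALSE]
        if (nrow(ex) == 0L) next
        seq <- paste(vapply(seq_len(nrow(ex)), function(e)
          substr(contigs[[cn]], ex$contig_start[e] + 1L,
                 ex$contig_end[e]), ""), collapse = "")
      }
      if (nchar(seq) == 0L) next
      m <- matchDatabase(seq, dbs[[loc]], mode)
      calls[[length(calls) + 1L]] <- data.frame(
        contig = cn, locus = loc, allele = m$alleleId,
        edit_distance = m$editDistance, mode = mode,
        gene_start = genes$contig_start[gi],
        gene_end = genes$contig_end[gi],
        span = genes$contig_end[gi] - genes$contig_start[gi])
    }
  }
  if (length(calls) == 0L)
    return(data.frame(contig = character(0), locus = character(0),
                      allele = character(0), edit_distance = integer(0),
                      mode = character(0), gene_start = integer(0),
                      gene_end = integer(0)))
  d <- do.call(rbind, calls)
  ## once-per-gene-per-contig: best by edit distance, then span
  d <- d[order(d$contig, d$locus, d$edit_distance, -d$span), , drop = FALSE]
  d <- d[!duplicated(d[, c("contig", "locus")]), , drop = FALSE]
  rownames(d) <- NULL
  d$span <- NULL
  d
}

#' Write assembly typing calls
#' @param calls data.frame from \code{typeAssembly}.
#' @param path output file.
#' @export
writeAssemblyCalls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
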