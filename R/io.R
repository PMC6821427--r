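#' Read an aligned panel from FASTA
#'
#' Aligned FASTA over \code{A,C,G,T,N,-}; a header suffix \code{|partial}
#' marks exon-only rows, whose uncovered columns must carry the absent marker
#' \code{*}.
#'
#' @param path FASTA file.
#' @param locus locus name (defaults to the file stem).
#' @return An \linkS4class{MsaPanel}.
#' @export
readMsaFasta <- function(path, locus = NULL) {
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  partial <- grepl("\\|partial$", ids)
  ids <- sub("\\|partial$", "", ids)
  rows <- setNames(as.character(ss), ids)
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  msaPanel(rows, partial = ids[partial], locus = locus)
}

#' Write an aligned panel to FASTA
#' @param panel an \linkS4class{MsaPanel}.
#' @param path output file.
#' @export
writeMsaFasta <- function(panel, path) {
  ids <- names(panel@rows)
  hdr <- ifelse(panel@partial, paste0(ids, "|partial"), ids)
  ss <- Biostrings::BStringSet(setNames(panel@rows, hdr))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read feature annotations from the package's tab-separated format
#'
#' Columns: haplotype_id, locus, feature_kind (gene|exon), exon_index,
#' start, end (0-based half-open, ungapped haplotype coordinates).
#'
#' @param path TSV file with a header line.
#' @return A \link[GenomicRanges]{GRanges} on haplotype ids (1-based closed
#'   internally) with metadata columns \code{locus}, \code{kind},
#'   \code{exon_index}.
#' @export
readAnnotationsTsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  annotationsToGRanges(d)
}

annotationsToGRanges <- function(d) {
  gr <- GenomicRanges::GRanges(
    seqnames = d$haplotype_id,
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end))
  gr$locus <- d$locus
  gr$kind <- d$feature_kind
  gr$exon_index <- d$exon_index
  gr
}

#' Write annotations to the tab-separated format
#' @param ann a GRanges as returned by \code{readAnnotationsTsv}.
#' @param path output file.
#' @export
writeAnnotationsTsv <- function(ann, path) {
  d <- data.frame(haplotype_id = as.character(GenomicRanges::seqnames(ann)),
                  locus = ann$locus, feature_kind = ann$kind,
                  exon_index = ann$exon_index,
                  start = GenomicRanges::start(ann) - 1L,
                  end = GenomicRanges::end(ann))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a graph to JSON lines
#'
#' One header record (\code{type, locus, level_count, node_count,
#' node_boundary}) followed by one record per edge (\code{type, level, from,
#' to, label, origins}). The panel is fully recoverable from the edge origin
#' sets, so the round trip \code{readPrgJson(writePrgJson(g))} reproduces the
#' graph exactly.
#'
#' @param prg a \linkS4class{PrgGraph}.
#' @param path output file.
#' @export
writePrgJson <- function(prg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  partialIds <- names(prg@panel@partial)[prg@panel@partial]
  writeLines(jsonlite::toJSON(list(
    type = "header", locus = prg@locus, level_count = prg@levelCount,
    node_count = length(prg@nodeBoundary),
    node_boundary = prg@nodeBoundary, partial_ids = partialIds),
    auto_unbox = TRUE), con)
  e <- prg@edges
  for (i in seq_len(nrow(e))) {
    writeLines(jsonlite::toJSON(list(
      type = "edge", level = e$level[i], from = e$from[i], to = e$to[i],
      label = e$label[i], origins = e$origins[[i]]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a graph from JSON lines
#' @param path file written by \code{writePrgJson}.
#' @return A \linkS4class{PrgGraph}.
#' @export
readPrgJson <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  hdr <- recs[[1L]]
  if (!identical(hdr$type, "header")) stop("missing header record")
  edges <- recs[-1L]
  L <- as.integer(hdr$level_count)
  ids <- unique(unlist(lapply(edges, `[[`, "origins")))
  rows <- setNames(rep(strrep(ABSENT_CHAR, L), length(ids)), ids)
  rowm <- matrix(ABSENT_CHAR, nrow = length(ids), ncol = L,
                 dimnames = list(ids, NULL))
  for (r in edges) rowm[r$origins, r$level + 1L] <- r$label
  rows <- setNames(apply(rowm, 1L, paste, collapse = ""), ids)
  panel <- msaPanel(rows, partial = intersect(hdr$partial_ids, ids),
                    locus = hdr$locus)
  prg <- buildPrg(panel)
  stopifnot(prg@levelCount == L,
            nrow(prg@edges) == length(edges))
  prg
}

#' Read linear alignments from SAM or BAM
#'
#' SAM text is converted at the boundary via \link[Rsamtools]{asBam};
#' unmapped records are dropped. SAM's 1-based positions are converted to the
#' package's 0-based convention.
#'
#' @param path SAM or BAM file.
#' @return list of \linkS4class{LinearAlignment}.
#' @export
readSamAlignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  x <- Rsamtools::scanBam(path, param = p)[[1L]]
  keep <- which(!bitwAnd(x$flag, 4L))
  ops <- GenomicAlignments::explodeCigarOps(x$cigar[keep])
  lens <- GenomicAlignments::explodeCigarOpLengths(x$cigar[keep])
  seqs <- as.character(x$seq[keep])
  quals <- as.character(x$qual[keep])
  lapply(seq_along(keep), function(j) {
    i <- keep[j]
    new("LinearAlignment", readId = x$qname[i], readSeq = seqs[j],
        quals = quals[j], referenceId = as.character(x$rname[i]),
        refStart = x$pos[i] - 1L, cigarOps = ops[[j]],
        cigarLens = lens[[j]], isReverse = bitwAnd(x$flag[i], 16L) > 0L,
        mapq = as.integer(x$mapq[i]))
  })
}

#' Construct a linear alignment record
#'
#' @param readId,readSeq read name and bases.
#' @param referenceId panel haplotype the read is aligned to.
#' @param refStart 0-based reference start.
#' @param cigar CIGAR string (M,=,X,I,D,S,H).
#' @param quals base qualities ("" when absent).
#' @param isReverse,mapq strand flag and mapping quality.
#' @export
linearAlignment <- function(readId, readSeq, referenceId, refStart, cigar,
                            quals = "", isReverse = FALSE, mapq = 60L) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  new("LinearAlignment", readId = readId, readSeq = toupper(readSeq),
      quals = quals, referenceId = referenceId,
      refStart = as.integer(refStart), cigarOps = ops,
      cigarLens = as.integer(lens), isReverse = isReverse,
      mapq = as.integer(mapq))
}

#' @export
setMethod("show", "LinearAlignment", function(object) {
  cat(sprintf("LinearAlignment %s vs %s@%d %s\n", object@readId,
              object@referenceId, object@refStart,
              paste0(object@cigarLens, object@cigarOps, collapse = "")))
})

#' Write SAM records
#'
#' @param records data.frame with columns qname, flag, rname, pos (1-based),
#'   mapq, cigar, seq, qual.
#' @param refLens named integer vector of reference lengths for the header.
#' @param path output SAM file.
#' @export
writeSamFile <- function(records, refLens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(refLens))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, refLens[[nm]]), con)
  if (nrow(records))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       records$qname, records$flag, records$rname,
                       records$pos, records$mapq, records$cigar,
                       records$seq, records$qual), con)
  invisible(path)
}

#' Export graph alignments as a tab-separated report
#'
#' Columns: read_id, locus, first_level, last_level, edge path (per-level
#' edge labels, run-length encoded as \code{count=label} tokens), score,
#' mode, extension_ran.
#'
#' @param gas list of \linkS4class{GraphAlignment}.
#' @param prg the graph they refer to.
#' @param path output file.
#' @export
exportGraphAlignments <- function(gas, prg, path) {
  rows <- lapply(gas, function(ga) {
    cells <- ga@cells
    lab <- ifelse(is.na(cells$edge), "i", prg@edges$label[cells$edge])
    r <- rle(lab)
    data.frame(read_id = ga@readId, locus = prg@locus,
               first_level = min(cells$level), last_level = max(cells$level),
               edge_path = paste(r$lengths, r$values, sep = "=",
                                 collapse = ","),
               score = ga@score, mode = ga@mode,
               extension_ran = isTRUE(ga@meta$extensionRan))
  })
  d <- do.call(rbind, rows)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
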