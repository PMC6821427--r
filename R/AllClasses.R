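#' @useDynLib prgtyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats setNames rgeom runif
#' @importFrom utils adist head tail write.table read.table
NULL

PANEL_ALPHABET <- c("A", "C", "G", "T", "N", "-", "*")
ABSENT_CHAR <- "*"

#' Aligned panel of reference haplotypes and allele sequences
#'
#' An \code{MsaPanel} holds one locus worth of aligned sequences: full-length
#' genomic haplotypes and (possibly partial, exon-only) allele sequences, all
#' over the alphabet \code{A,C,G,T,N,-}. Partial rows mark columns outside
#' their covered blocks with the distinguished absent marker \code{*}; within
#' covered blocks they may contain genuine gaps \code{-} like any other row.
#'
#' @slot rows named character vector of aligned rows (equal widths).
#' @slot partial named logical; \code{TRUE} for exon-only (partial) rows.
#' @slot locus single locus name.
#' @exportClass MsaPanel
setClass("MsaPanel",
  representation(rows = "character", partial = "logical", locus = "character"))

setValidity("MsaPanel", function(object) {
  r <- object@rows
  if (length(r) == 0L) return("panel has no rows")
  if (is.null(names(r)) || anyDuplicated(names(r)))
    return("rows must be uniquely named")
  w <- unique(nchar(r))
  if (length(w) != 1L) {
    bad <- names(r)[nchar(r) != nchar(r[[1L]])]
    return(sprintf("rows of unequal length (e.g. '%s')", bad[1L]))
  }
  if (!identical(names(object@partial), names(r)))
    return("partial flags must parallel rows")
  chars <- unique(strsplit(paste(r, collapse = ""), "")[[1L]])
  if (!all(chars %in% PANEL_ALPHABET))
    return(sprintf("illegal characters in rows: %s",
                   paste(setdiff(chars, PANEL_ALPHABET), collapse = ",")))
  full <- r[!object@partial]
  if (length(full) == 0L)
    return(sprintf("no full-length row anchors the partial rows (locus '%s')",
                   object@locus))
  if (any(grepl("\\*", full, fixed = FALSE)))
    return("full-length rows must not contain the absent marker '*'")
  TRUE
})

#' Column-structured population reference graph
#'
#' One level per alignment column; each edge belongs to one level, carries a
#' single symbol label (\code{A,C,G,T,N} or the gap label \code{-}) and the
#' nonempty set of panel sequences exhibiting that symbol in that column.
#' Nodes sit at the boundaries 0..L between levels; node ids are global
#' integers and \code{nodeBoundary} records each node's boundary.
#'
#' @slot locus locus name.
#' @slot levelCount number of levels (MSA columns) L.
#' @slot edges data.frame with columns \code{level} (0-based), \code{from},
#'   \code{to} (node ids), \code{label}, \code{origins} (list of ids).
#' @slot nodeBoundary integer vector; \code{nodeBoundary[i]} is the boundary
#'   (0..L) of node id \code{i}.
#' @slot paths named list; per sequence an integer vector of length L of edge
#'   row indices (NA where a partial row is absent).
#' @slot panel the \code{MsaPanel} the graph was built from.
#' @slot cmap per-sequence level coordinate maps (see \code{coordinateMap}).
#' @exportClass PrgGraph
setClass("PrgGraph",
  representation(locus = "character", levelCount = "integer",
                 edges = "data.frame", nodeBoundary = "integer",
                 paths = "list", panel = "MsaPanel", cmap = "list"))

setValidity("PrgGraph", function(object) {
  e <- object@edges
  L <- object@levelCount
  need <- c("level", "from", "to", "label", "origins")
  if (!all(need %in% names(e))) return("edges missing required columns")
  if (nrow(e) > 0L) {
    if (any(e$level < 0L | e$level >= L)) return("edge level out of range")
    if (any(object@nodeBoundary[e$from] != e$level))
      return("edge 'from' node not at its level's left boundary")
    if (any(object@nodeBoundary[e$to] != e$level + 1L))
      return("edge 'to' node not at its level's right boundary")
    if (any(lengths(e$origins) == 0L)) return("edge with empty origin set")
  }
  for (id in names(object@paths)) {
    p <- object@paths[[id]]
    if (length(p) != L) return(sprintf("path of '%s' has wrong length", id))
  }
  TRUE
})

#' A SAM-style linear alignment of one read against one panel haplotype
#'
#' @slot readId,readSeq,quals read name, bases, base qualities ("" if absent).
#' @slot referenceId a full-length haplotype id of the panel.
#' @slot refStart 0-based leftmost reference residue of the alignment.
#' @slot cigarOps,cigarLens parsed CIGAR (ops in M,=,X,I,D,S,H).
#' @slot isReverse reverse-strand flag (bases are stored in reference
#'   orientation, as in SAM).
#' @slot mapq mapping quality.
#' @exportClass LinearAlignment
setClass("LinearAlignment",
  representation(readId = "character", readSeq = "character",
                 quals = "character", referenceId = "character",
                 refStart = "integer", cigarOps = "character",
                 cigarLens = "integer", isReverse = "logical",
                 mapq = "integer"))

setValidity("LinearAlignment", function(object) {
  if (!all(object@cigarOps %in% c("M", "=", "X", "I", "D", "S", "H")))
    return("unsupported CIGAR operation")
  consume <- object@cigarOps %in% c("M", "=", "X", "I", "S")
  if (sum(object@cigarLens[consume]) != nchar(object@readSeq))
    return(sprintf("CIGAR consumes %d read bases but read '%s' has %d",
                   sum(object@cigarLens[consume]), object@readId,
                   nchar(object@readSeq)))
  TRUE
})

#' A read's traversal of PRG edges
#'
#' \code{cells} is the ordered walk: one row per cell with the level, the edge
#' row index in the graph's edge table (NA for a floating insertion), the read
#' base (\code{-} when the cell consumes no read base) and the 0-based read
#' position (NA for read-gap cells). \code{removed} holds 0-based half-open
#' read intervals excised by inspection; every read base is in exactly one of
#' cells / removed / clips.
#'
#' @exportClass GraphAlignment
setClass("GraphAlignment",
  representation(readId = "character", cells = "data.frame",
                 removed = "matrix", clipPrefix = "integer",
                 clipSuffix = "integer", score = "numeric",
                 mode = "character", meta = "list"))

#' Affine-gap scoring scheme for graph alignment
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(match = "numeric", mismatch = "numeric",
                 gapOpen = "numeric", gapExtend = "numeric",
                 nScore = "numeric"))

setValidity("ScoringScheme", function(object) {
  if (!(object@match > 0 && object@mismatch < 0))
    return("need match > 0 > mismatch")
  if (!(object@gapOpen <= object@gapExtend && object@gapExtend <= 0))
    return("need gapOpen <= gapExtend <= 0")
  TRUE
})

#' Inspection-stage parameters
#' @exportClass InspectionParams
setClass("InspectionParams",
  representation(gapTriggerLen = "integer", flankW = "integer",
                 longReadMode = "logical"))

setValidity("InspectionParams", function(object) {
  if (object@gapTriggerLen < 1L) return("gapTriggerLen must be >= 1")
  if (object@flankW < 0L) return("flankW must be >= 0")
  TRUE
})

#' Sequencing error model for the allele likelihood
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(sub = "numeric", insOpen = "numeric", insExtend = "numeric",
                 delOpen = "numeric", delExtend = "numeric", mode = "character"))

setValidity("ErrorModel", function(object) {
  p <- c(object@sub, object@insOpen, object@insExtend,
         object@delOpen, object@delExtend)
  if (any(p <= 0 | p >= 1)) return("all rates must lie in (0,1)")
  if (!object@mode %in% c("short", "long")) return("mode must be short|long")
  TRUE
})

#' Per-locus allele database
#'
#' Holds, per allele: the full ungapped sequence, the aligned panel row
#' (with \code{*} outside covered blocks for exon-only alleles), the coverage
#' class, and the gene / concatenated-exon subsequences used for assembly
#' typing.
#'
#' @exportClass AlleleDatabase
setClass("AlleleDatabase",
  representation(locus = "character", ids = "character", seqs = "character",
                 rows = "character", coverage = "character",
                 geneSeqs = "character", exonSeqs = "character"))

setValidity("AlleleDatabase", function(object) {
  if (anyDuplicated(object@ids)) return("allele ids must be unique")
  if (any(nchar(object@seqs) == 0L)) return("allele sequences must be nonempty")
  if (!all(object@coverage %in% c("genomic", "exon_only")))
    return("coverage must be genomic|exon_only")
  TRUE
})

#' Chained semi-global contig-vs-haplotype alignment
#'
#' @slot diagonals data.frame of chained, trimmed gap-free segments
#'   (\code{cs,ce,rs,re}; 0-based half-open, equal lengths).
#' @slot jumps data.frame of inter-diagonal jumps (horizontal = reference
#'   skip, vertical = contig skip) with lengths and penalties.
#' @slot refMap integer vector, one entry per reference residue: the 0-based
#'   aligned contig position or NA where unaligned.
#' @exportClass ChainedAlignment
setClass("ChainedAlignment",
  representation(contigId = "character", haplotypeId = "character",
                 diagonals = "data.frame", jumps = "data.frame",
                 score = "numeric", refMap = "integer",
                 contigLen = "integer", refLen = "integer",
                 unalignable = "logical"))

#' Simulation configuration
#' @exportClass SimConfig
setClass("SimConfig",
  representation(seed = "integer", nLoci = "integer", nHaplotypes = "integer",
                 nAllelesPerLocus = "integer", locusLen = "integer",
                 divergence = "numeric", indelProb = "numeric",
                 indelGeomP = "numeric", coverage = "numeric",
                 readLen = "integer", mode = "character",
                 readSubRate = "numeric", readIndelRate = "numeric",
                 fractionExonOnly = "numeric", misprojectionProb = "numeric"))

setValidity("SimConfig", function(object) {
  pr <- c(object@divergence, object@indelProb, object@indelGeomP,
          object@readSubRate, object@readIndelRate, object@fractionExonOnly,
          object@misprojectionProb)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0,1]")
  if (object@nAllelesPerLocus < 1L) return("need at least one allele per locus")
  if (!object@mode %in% c("short", "long")) return("mode must be short|long")
  TRUE
})

#' Simulated truth set: panel, annotations, database, genotypes
#' @exportClass TruthSet
setClass("TruthSet",
  representation(panels = "list", annotations = "ANY", dbs = "list",
                 truth = "list", haplotypeIds = "list", alleleIds = "list",
                 features = "list", config = "SimConfig"))
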