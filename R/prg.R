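#' Construct an aligned sequence panel
#'
#' @param rows named character vector of aligned rows over
#'   \code{A,C,G,T,N,-} plus \code{*} (absent marker, partial rows only).
#' @param partial logical vector (recycled) flagging exon-only partial rows;
#'   alternatively character vector of ids to flag.
#' @param locus locus name.
#' @return An \linkS4class{MsaPanel}.
#' @examples
#' msaPanel(c(H1 = "ACGT", H2 = "ACAT", H3 = "AC-T"))
#' @export
msaPanel <- function(rows, partial = FALSE, locus = "locus1") {
  if (length(rows) == 0L) stop("empty panel: no rows supplied")
  rows <- toupper(rows)
  if (is.character(partial)) partial <- names(rows) %in% partial
  if (length(partial) == 0L) partial <- FALSE
  partial <- rep_len(as.logical(partial), length(rows))
  names(partial) <- names(rows)
  new("MsaPanel", rows = rows, partial = partial, locus = locus)
}

#' @export
setMethod("show", "MsaPanel", function(object) {
  cat(sprintf("MsaPanel '%s': %d rows x %d columns (%d partial)\n",
              object@locus, length(object@rows), nchar(object@rows[[1L]]),
              sum(object@partial)))
})

#' Number of alignment columns of a panel
#' @param panel an \linkS4class{MsaPanel}.
#' @export
panelColumns <- function(panel) nchar(panel@rows[[1L]])

panelMatrix <- function(panel) {
  m <- do.call(rbind, strsplit(panel@rows, ""))
  rownames(m) <- names(panel@rows)
  m
}

## Union-find over a small character key set.
.uf_components <- function(keys, pairs) {
  parent <- seq_along(keys)
  names(parent) <- keys
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(pairs)) for (p in pairs) {
    a <- findp(match(p[1L], keys)); b <- findp(match(p[2L], keys))
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_along(keys), findp, 0L)
}

#' Build a population reference graph from an aligned panel
#'
#' One level per alignment column. Each level carries one edge per distinct
#' symbol observed in that column (gap \code{-} included), labelled with the
#' set of originating sequences. Boundary nodes merge sequences by the
#' transitive closure of "exhibits the same symbol in an adjacent column", so
#' re-convergent columns share nodes and recombinant traversals exist wherever
#' the alignment supports them. Partial (exon-only) rows contribute edges only
#' inside their covered blocks and have partial haplotype paths.
#'
#' @param panel an \linkS4class{MsaPanel}.
#' @return A \linkS4class{PrgGraph}.
#' @examples
#' g <- buildPrg(msaPanel(c(H1 = "ACGT", H2 = "ACAT", H3 = "AC-T")))
#' subset(prgEdges(g), level == 2L)
#' @export
buildPrg <- function(panel) {
  validObject(panel)
  m <- panelMatrix(panel)
  L <- ncol(m)
  n <- nrow(m)
  ids <- rownames(m)
  covered <- m != ABSENT_CHAR

  ## --- boundary nodes -------------------------------------------------
  nodeOfSeq <- matrix(NA_integer_, nrow = n, ncol = L + 1L)
  nodeBoundary <- integer(0)
  nextNode <- 0L
  for (b in 0:L) {
    lc <- if (b >= 1L) covered[, b] else rep(FALSE, n)
    rc <- if (b < L) covered[, b + 1L] else rep(FALSE, n)
    part <- which(lc | rc)
    if (length(part) == 0L) next
    llab <- ifelse(lc[part], m[cbind(part, rep(b, length(part)))], NA)
    rlab <- ifelse(rc[part], m[cbind(part, rep(b + 1L, length(part)))], NA)
    ## quick path: single component when one side is shared by everyone
    oneComp <- (all(!is.na(llab)) && length(unique(llab)) == 1L) ||
               (all(!is.na(rlab)) && length(unique(rlab)) == 1L)
    if (oneComp) {
      comp <- rep(1L, length(part))
    } else {
      lk <- ifelse(is.na(llab), NA, paste0("L", llab))
      rk <- ifelse(is.na(rlab), NA, paste0("R", rlab))
      keys <- unique(c(lk[!is.na(lk)], rk[!is.na(rk)]))
      both <- !is.na(lk) & !is.na(rk)
      pairs <- if (any(both)) unique(Map(c, lk[both], rk[both])) else list()
      roots <- .uf_components(keys, pairs)
      keyOf <- ifelse(!is.na(lk), lk, rk)
      comp <- roots[match(keyOf, keys)]
      comp <- match(comp, unique(comp))   # renumber in first-seen order
    }
    nodeIds <- nextNode + seq_len(max(comp))
    nodeOfSeq[part, b + 1L] <- nodeIds[comp]
    nodeBoundary <- c(nodeBoundary, rep(b, max(comp)))
    nextNode <- nextNode + max(comp)
  }

  ## --- edges: one per (level, label) ---------------------------------
  lev <- integer(0); lab <- character(0); fr <- integer(0); to <- integer(0)
  orig <- list()
  for (l in 0:(L - 1L)) {
    col <- m[, l + 1L]
    here <- which(covered[, l + 1L])
    if (length(here) == 0L) next
    for (s in sort(unique(col[here]))) {
      o <- here[col[here] == s]
      lev <- c(lev, l); lab <- c(lab, s)
      fr <- c(fr, nodeOfSeq[o[1L], l + 1L])
      to <- c(to, nodeOfSeq[o[1L], l + 2L])
      orig <- c(orig, list(ids[o]))
    }
  }
  edges <- data.frame(level = lev, from = fr, to = to, label = lab,
                      stringsAsFactors = FALSE)
  edges$origins <- orig

  ## --- haplotype paths and coordinate maps ---------------------------
  key <- paste(edges$level, edges$label)
  paths <- lapply(seq_len(n), function(i) {
    p <- rep(NA_integer_, L)
    cov <- which(covered[i, ])
    p[cov] <- match(paste(cov - 1L, m[i, cov]), key)
    p
  })
  names(paths) <- ids
  cmap <- lapply(seq_len(n), function(i) {
    res <- which(m[i, ] %in% c("A", "C", "G", "T", "N"))
    lvl2res <- rep(NA_integer_, L)
    lvl2res[res] <- seq_along(res) - 1L
    list(res2lvl = res - 1L, lvl2res = lvl2res)
  })
  names(cmap) <- ids

  new("PrgGraph", locus = panel@locus, levelCount = L, edges = edges,
      nodeBoundary = nodeBoundary, paths = paths, panel = panel, cmap = cmap)
}

#' @export
setMethod("show", "PrgGraph", function(object) {
  cat(sprintf("PrgGraph '%s': %d levels, %d edges, %d nodes, %d sequences\n",
              object@locus, object@levelCount, nrow(object@edges),
              length(object@nodeBoundary), length(object@paths)))
})

#' Edge table of a graph
#' @param prg a \linkS4class{PrgGraph}.
#' @export
prgEdges <- function(prg) prg@edges

#' Haplotype path of one sequence
#' @param prg a \linkS4class{PrgGraph}.
#' @param id sequence id.
#' @return integer vector of edge row indices, NA where the row is absent.
#' @export
haplotypePath <- function(prg, id) {
  if (!id %in% names(prg@paths)) stop(sprintf("unknown sequence id '%s'", id))
  prg@paths[[id]]
}

#' Level coordinate map for one sequence
#'
#' Maps 0-based ungapped residue indices to 0-based graph levels, and back.
#'
#' @param prg a \linkS4class{PrgGraph}.
#' @param id sequence id (defaults to all).
#' @return For one id, a list with \code{res2lvl} (residue -> level) and
#'   \code{lvl2res} (level -> residue, NA at gap/absent columns); for several,
#'   a named list of such lists.
#' @export
coordinateMap <- function(prg, id = NULL) {
  if (is.null(id)) return(prg@cmap)
  if (!id %in% names(prg@cmap)) stop(sprintf("unknown sequence id '%s'", id))
  prg@cmap[[id]]
}

#' Spell the sequence along a path of edges
#'
#' @param prg a \linkS4class{PrgGraph}.
#' @param edges integer vector of edge row indices at consecutive levels.
#' @return The concatenation of non-gap labels.
#' @export
spellPath <- function(prg, edges) {
  edges <- edges[!is.na(edges)]
  if (length(edges) == 0L) return("")
  e <- prg@edges[edges, ]
  if (any(diff(e$level) != 1L) ||
      (length(edges) > 1L && any(e$to[-length(edges)] != e$from[-1L])))
    stop("edge list is not a connected, level-consecutive path")
  paste(e$label[e$label != "-"], collapse = "")
}

#' Ungapped sequence of a panel row
#' @param panel an \linkS4class{MsaPanel}.
#' @param id row id.
#' @export
ungappedSequence <- function(panel, id) {
  gsub("[-*]", "", panel@rows[[id]])
}

#' Enumerate all level paths between two boundaries
#'
#' Exhaustive DFS over the graph's edge structure; used as an oracle for the
#' fixed-level polishing DP and for spelled-path enumeration on small graphs.
#'
#' @param prg a \linkS4class{PrgGraph}.
#' @param fromLevel,toLevel 0-based inclusive level range.
#' @param maxPaths abort (with an error) beyond this many paths.
#' @return list of integer vectors of edge row indices.
#' @export
enumerateLevelPaths <- function(prg, fromLevel = 0L,
                                toLevel = prg@levelCount - 1L,
                                maxPaths = 1e6) {
  e <- prg@edges
  out <- list()
  byLevel <- split(seq_len(nrow(e)), e$level)
  recurse <- function(path, node, l) {
    if (l > toLevel) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    cand <- byLevel[[as.character(l)]]
    if (l > fromLevel) cand <- cand[e$from[cand] == node]
    for (i in cand) {
      if (length(out) >= maxPaths) stop("path enumeration limit exceeded")
      recurse(c(path, i), e$to[i], l + 1L)
    }
  }
  recurse(integer(0), NA_integer_, fromLevel)
  out
}
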