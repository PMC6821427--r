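#' A diploid genotype call for one locus
#' @exportClass GenotypeCall
setClass("GenotypeCall",
  representation(locus = "character", a1 = "character", a2 = "character",
                 logLik = "numeric", q = "numeric", called = "logical",
                 posterior = "data.frame", nReads = "integer",
                 reason = "character"))

#' @export
setMethod("show", "GenotypeCall", function(object) {
  cat(sprintf("GenotypeCall %s: (%s, %s) Q=%.3f %s [%d reads]%s\n",
              object@locus, object@a1, object@a2, object@q,
              if (object@called) "called" else "uncalled", object@nReads,
              if (nzchar(object@reason)) paste0(" (", object@reason, ")")
              else ""))
})

#' Sequencing error model
#'
#' Substitutions are modelled per base (\code{log(1-sub)} for a match,
#' \code{log(sub/3)} for a mismatch); indels affinely
#' (\code{log(open) + (k-1) log(extend)} for a length-k run). The long-read
#' model carries substantially larger indel rates, reflecting the error
#' profile of nanopore/PacBio reads.
#'
#' @param mode \code{"short"} or \code{"long"}; picks the default rates.
#' @param sub,insOpen,insExtend,delOpen,delExtend overrides.
#' @export
errorModel <- function(mode = c("short", "long"), sub = NULL,
                       insOpen = NULL, insExtend = NULL,
                       delOpen = NULL, delExtend = NULL) {
  mode <- match.arg(mode)
  d <- if (mode == "short")
    list(sub = 0.003, insOpen = 1e-4, insExtend = 0.1,
         delOpen = 1e-4, delExtend = 0.1)
  else
    list(sub = 0.01, insOpen = 0.03, insExtend = 0.3,
         delOpen = 0.03, delExtend = 0.3)
  new("ErrorModel",
      sub = if (is.null(sub)) d$sub else sub,
      insOpen = if (is.null(insOpen)) d$insOpen else insOpen,
      insExtend = if (is.null(insExtend)) d$insExtend else insExtend,
      delOpen = if (is.null(delOpen)) d$delOpen else delOpen,
      delExtend = if (is.null(delExtend)) d$delExtend else delExtend,
      mode = mode)
}

modelLogP <- function(model) {
  c(log1p(-model@sub), log(model@sub / 3),
    log(model@insOpen), log(model@insExtend),
    log(model@delOpen), log(model@delExtend))
}

#' Build an allele database from panel rows
#'
#' @param panel the \linkS4class{MsaPanel} containing the allele rows.
#' @param alleleIds which rows are alleles.
#' @param geneCols,exonCols optional 0-based half-open MSA column intervals
#'   (matrix, one row per interval) delimiting the gene and its exons; used
#'   to derive the gene-level and concatenated-exon sequences for assembly
#'   typing. With \code{NULL}, the full sequence stands in for the gene.
#' @return An \linkS4class{AlleleDatabase}.
#' @export
alleleDatabaseFromPanel <- function(panel, alleleIds, geneCols = NULL,
                                    exonCols = NULL) {
  stopifnot(all(alleleIds %in% names(panel@rows)))
  rows <- panel@rows[alleleIds]
  seqs <- gsub("[-*]", "", rows)
  colSlice <- function(row, cols) {
    if (is.null(cols)) return(gsub("[-*]", "", row))
    ch <- strsplit(row, "")[[1L]]
    paste(unlist(lapply(seq_len(nrow(cols)), function(i)
      ch[(cols[i, 1L] + 1L):cols[i, 2L]])), collapse = "") |>
      gsub(pattern = "[-*]", replacement = "")
  }
  geneSeqs <- vapply(rows, colSlice, "", cols = geneCols)
  exonSeqs <- vapply(rows, colSlice, "", cols = exonCols)
  new("AlleleDatabase", locus = panel@locus, ids = alleleIds,
      seqs = unname(seqs), rows = unname(rows),
      coverage = unname(ifelse(panel@partial[alleleIds],
                               "exon_only", "genomic")),
      geneSeqs = unname(geneSeqs), exonSeqs = unname(exonSeqs))
}

#' @export
setMethod("show", "AlleleDatabase", function(object) {
  cat(sprintf("AlleleDatabase '%s': %d alleles (%d exon-only)\n",
              object@locus, length(object@ids),
              sum(object@coverage == "exon_only")))
})

alleleLabelMatrix <- function(db, prg) {
  stopifnot(all(nchar(db@rows) == prg@levelCount))
  m <- do.call(cbind, lapply(db@rows, function(r) {
    ch <- strsplit(r, "")[[1L]]
    x <- edgeLabelCodes(ch)
    x[ch == ABSENT_CHAR] <- -2L
    x
  }))
  colnames(m) <- db@ids
  m
}

#' Log-likelihood of a read given one allele
#'
#' Walks the read's graph alignment against the allele's (possibly partial)
#' column row: matches contribute \code{log(1-sub)}, mismatches
#' \code{log(sub/3)}, indel runs affine open/extend log-probabilities.
#' Columns the allele does not cover (exon-only alleles outside their exons)
#' contribute nothing and are not counted as evaluated.
#'
#' @param ga a \linkS4class{GraphAlignment}.
#' @param alleleId allele.
#' @param db,prg database and graph.
#' @param model an \linkS4class{ErrorModel}.
#' @param normalized divide by the number of evaluated columns (the scale
#'   used for genotyping, making exon-only and genomic alleles comparable).
#' @return log-probability (plus \code{"neval"} attribute).
#' @export
readAlleleLogLik <- function(ga, alleleId, db, prg, model = errorModel(),
                             normalized = FALSE) {
  k <- match(alleleId, db@ids)
  if (is.na(k)) stop(sprintf("allele '%s' absent from locus '%s'",
                             alleleId, db@locus))
  lab <- alleleLabelMatrix(db, prg)[, k, drop = FALSE]
  out <- cpp_read_allele_loglik(ga@cells$level, ga@cells$bcode,
                                is.na(ga@cells$edge), lab, modelLogP(model))
  ll <- out[1L, 1L]
  ne <- out[2L, 1L]
  structure(if (normalized) ll / max(ne, 1) else ll, neval = ne)
}

#' Per-read per-allele likelihood table for one locus
#'
#' @param gas list of \linkS4class{GraphAlignment} for the locus.
#' @param db,prg database and graph.
#' @param model error model.
#' @return list with \code{mat} (retained reads x alleles, per-column
#'   normalized log-likelihoods), \code{neval}, \code{retained} flags and
#'   \code{reason} per input read.
#' @export
likelihoodTable <- function(gas, db, prg, model = errorModel()) {
  lab <- alleleLabelMatrix(db, prg)
  logp <- modelLogP(model)
  nR <- length(gas)
  mat <- matrix(NA_real_, nR, ncol(lab), dimnames = list(NULL, db@ids))
  nev <- matrix(0, nR, ncol(lab))
  retained <- rep(FALSE, nR)
  reason <- rep("", nR)
  for (i in seq_len(nR)) {
    ga <- gas[[i]]
    if (is.null(ga) || nrow(ga@cells) == 0L) { reason[i] <- "no_cells"; next }
    out <- cpp_read_allele_loglik(ga@cells$level, ga@cells$bcode,
                                  is.na(ga@cells$edge), lab, logp)
    if (all(out[2L, ] == 0)) { reason[i] <- "no_evaluated_columns"; next }
    ## whole-read scale, but rescaled to a common evaluated-column count so
    ## exon-only (partially covering) and genomic alleles are comparable;
    ## for an all-genomic database this is the plain log-likelihood
    mat[i, ] <- out[1L, ] / pmax(out[2L, ], 1) * max(out[2L, ])
    nev[i, ] <- out[2L, ]
    retained[i] <- TRUE
  }
  list(mat = mat[retained, , drop = FALSE],
       neval = nev[retained, , drop = FALSE],
       retained = retained, reason = reason, alleles = db@ids,
       locus = db@locus)
}

#' Mixture log-likelihood of an unordered allele pair
#'
#' \eqn{\sum_r \log(\frac{1}{2} P(r|a_1) + \frac{1}{2} P(r|a_2))}, computed
#' in log space.
#'
#' @param table a likelihood table from \code{likelihoodTable}.
#' @param a1,a2 allele ids.
#' @export
pairLogLik <- function(table, a1, a2) {
  l1 <- table$mat[, a1]
  l2 <- table$mat[, a2]
  m <- pmax(l1, l2)
  sum(m + log(0.5 * exp(l1 - m) + 0.5 * exp(l2 - m)))
}

#' Call the maximum-likelihood diploid genotype for one locus
#'
#' Evaluates every unordered allele pair (with replacement), normalizes the
#' pair likelihoods into a posterior under a uniform pair prior, and calls
#' the best pair when its posterior Q reaches the threshold. Ties break to
#' the lexicographically smallest pair.
#'
#' @param table likelihood table.
#' @param threshold minimum posterior for \code{called = TRUE}.
#' @return A \linkS4class{GenotypeCall}.
#' @export
callGenotype <- function(table, threshold = 0.7) {
  A <- length(table$alleles)
  nR <- nrow(table$mat)
  if (nR == 0L)
    return(new("GenotypeCall", locus = table$locus, a1 = NA_character_,
               a2 = NA_character_, logLik = NA_real_, q = NA_real_,
               called = FALSE, posterior = data.frame(), nReads = 0L,
               reason = "zero retained reads"))
  ord <- order(table$alleles)
  idx <- which(upper.tri(matrix(0, A, A), diag = TRUE), arr.ind = TRUE)
  ## enumerate in lexicographic allele order for deterministic ties
  i1 <- ord[idx[, 1L]]; i2 <- ord[idx[, 2L]]
  key <- order(table$alleles[i1], table$alleles[i2])
  i1 <- i1[key]; i2 <- i2[key]
  ll <- vapply(seq_along(i1), function(p)
    pairLogLik(table, table$alleles[i1[p]], table$alleles[i2[p]]), 0)
  m <- max(ll)
  post <- exp(ll - m); post <- post / sum(post)
  best <- which.max(ll)   # first max = lexicographically smallest pair
  pair <- sort(c(table$alleles[i1[best]], table$alleles[i2[best]]))
  new("GenotypeCall", locus = table$locus, a1 = pair[1L], a2 = pair[2L],
      logLik = ll[best], q = post[best], called = post[best] >= threshold,
      posterior = data.frame(a1 = table$alleles[i1], a2 = table$alleles[i2],
                             logLik = ll, posterior = post),
      nReads = as.integer(nR), reason = "")
}

#' Type a whole sample: all loci, all reads
#'
#' Groups graph alignments by locus, builds likelihood tables and calls each
#' locus; loci without reads are reported uncalled.
#'
#' @param gasByLocus named list (locus -> list of graph alignments).
#' @param prgs named list of \linkS4class{PrgGraph}.
#' @param dbs named list of \linkS4class{AlleleDatabase}.
#' @param model error model.
#' @param threshold call threshold.
#' @return list of \linkS4class{GenotypeCall}, one per locus in \code{prgs};
#'   attribute \code{"summary"} holds call-rate and skip statistics.
#' @export
typeSample <- function(gasByLocus, prgs, dbs, model = errorModel(),
                       threshold = 0.7) {
  calls <- lapply(names(prgs), function(loc) {
    gas <- gasByLocus[[loc]]
    if (is.null(gas) || length(gas) == 0L)
      return(new("GenotypeCall", locus = loc, a1 = NA_character_,
                 a2 = NA_character_, logLik = NA_real_, q = NA_real_,
                 called = FALSE, posterior = data.frame(), nReads = 0L,
                 reason = "no reads"))
    tab <- likelihoodTable(gas, dbs[[loc]], prgs[[loc]], model)
    callGenotype(tab, threshold)
  })
  names(calls) <- names(prgs)
  ext <- unlist(lapply(unlist(gasByLocus, recursive = FALSE), function(g)
    isTRUE(g@meta$extensionRan)))
  attr(calls, "summary") <- list(
    callRate = mean(vapply(calls, function(x) x@called, TRUE)),
    extensionSkipFraction = if (length(ext)) 1 - mean(ext) else NA_real_)
  calls
}

#' Write genotype calls as a tab-separated file
#' @param calls list of \linkS4class{GenotypeCall}.
#' @param path output file.
#' @export
writeGenotypeCalls <- function(calls, path) {
  d <- do.call(rbind, lapply(calls, function(x)
    data.frame(locus = x@locus, allele1 = x@a1, allele2 = x@a2,
               Q = x@q, called = x@called, n_reads = x@nReads)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype calls with full pair posteriors, as JSON
#' @param calls list of \linkS4class{GenotypeCall}.
#' @param path output file.
#' @export
writeGenotypeCallsJson <- function(calls, path) {
  obj <- lapply(calls, function(x)
    list(locus = x@locus, a1 = x@a1, a2 = x@a2, Q = x@q, called = x@called,
         n_reads = x@nReads, posterior = x@posterior))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
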