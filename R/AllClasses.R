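#' BsjCallSet: one caller's backsplice junction calls
#'
#' A \linkS4class{RangedSummarizedExperiment} holding the backsplice
#' junctions reported by a single circRNA caller. Row ranges are the
#' junction intervals (internal 1-based closed coordinates; the outermost
#' bases joined by the backsplice), the \code{counts} assay holds
#' per-sample junction read counts, and \code{callerId} records which tool
#' produced them. Junctions are unique per (chrom, start, end, strand);
#' readers collapse duplicates by summing counts.
#'
#' @slot callerId single string naming the caller (e.g. "dcc", "segemehl").
#' @export
setClass("BsjCallSet",
         contains = "RangedSummarizedExperiment",
         slots = c(callerId = "character"))

setValidity("BsjCallSet", function(object) {
  msg <- character()
  if (length(object@callerId) != 1L || !nzchar(object@callerId))
    msg <- c(msg, "callerId must be a single non-empty string")
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (any(!is.finite(cnt)) || any(cnt < 0))
      msg <- c(msg, "counts must be finite and non-negative")
  }
  if (length(object) > 0L) {
    key <- .junctionKey(rowRanges(object))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate junctions (same chrom/start/end/strand)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BsjCallSet
#'
#' @param ranges \code{GRanges} of junction intervals (1-based closed).
#' @param counts integer matrix, junctions x samples; column names are the
#'   sample IDs (the sample order of the set).
#' @param callerId single string identifying the caller.
#' @param circType optional character vector of per-junction structural
#'   annotations (\code{exonic}, \code{intronic}, \code{intergenic},
#'   \code{unknown}) as some callers report them.
#' @return A \linkS4class{BsjCallSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 500), "+")
#' bsj <- BsjCallSet(gr, matrix(3L, 1, 2, dimnames = list(NULL, c("s1", "s2"))),
#'                   callerId = "toy")
#' sampleOrder(bsj)
#' @export
BsjCallSet <- function(ranges, counts, callerId = "caller", circType = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop("counts must have column names (sample IDs)", call. = FALSE)
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowRanges = ranges)
  if (!is.null(circType))
    rowData(se)$circType <- circType
  new("BsjCallSet", se, callerId = callerId)
}

#' @rdname BsjCallSet-class
#' @param object,x a \code{BsjCallSet}.
#' @export
setGeneric("callerId", function(x) standardGeneric("callerId"))

#' @rdname BsjCallSet-class
#' @export
setMethod("callerId", "BsjCallSet", function(x) x@callerId)

#' @rdname BsjCallSet-class
#' @export
setGeneric("sampleOrder", function(x) standardGeneric("sampleOrder"))

#' @rdname BsjCallSet-class
#' @export
setMethod("sampleOrder", "BsjCallSet", function(x) colnames(x))

setMethod("show", "BsjCallSet", function(object) {
  cat("BsjCallSet from caller '", object@callerId, "'\n", sep = "")
  callNextMethod()
})

#' CircCandidateSet: consensus-filtered circRNA candidates
#'
#' A \linkS4class{RangedSummarizedExperiment} of circRNA candidates that
#' survived two-caller consensus and expression filtering. Row data carry
#' the sequential \code{circ_id} (assigned after sorting by chrom, start,
#' end) and a \code{circType}; the \code{counts} assay holds the reference
#' caller's per-sample counts.
#'
#' @slot referenceCaller caller whose counts are the reference abundances.
#' @export
setClass("CircCandidateSet",
         contains = "RangedSummarizedExperiment",
         slots = c(referenceCaller = "character"))

setValidity("CircCandidateSet", function(object) {
  msg <- character()
  if (!"circ_id" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'circ_id'")
  else if (anyDuplicated(rowData(object)$circ_id))
    msg <- c(msg, "circ_id values must be unique")
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  if (length(msg)) msg else TRUE
})

#' @rdname CircCandidateSet-class
#' @param x a \code{CircCandidateSet}.
#' @export
setGeneric("circIds", function(x) standardGeneric("circIds"))

#' @rdname CircCandidateSet-class
#' @export
setMethod("circIds", "CircCandidateSet", function(x) rowData(x)$circ_id)

#' @rdname CircCandidateSet-class
#' @export
setMethod("callerId", "CircCandidateSet", function(x) x@referenceCaller)

setMethod("show", "CircCandidateSet", function(object) {
  cat("CircCandidateSet (reference caller '", object@referenceCaller,
      "')\n", sep = "")
  callNextMethod()
})

#' GeneModels: gene and exon annotation
#'
#' Minimal gene-model container: one \code{GRanges} of gene spans (named by
#' gene ID, with a \code{gene_name} column) and a \code{GRangesList} of
#' exons per gene, sorted by start within each gene. All coordinates are
#' internal 1-based closed.
#'
#' @slot geneRanges \code{GRanges}, one span per gene, names = gene IDs.
#' @slot exonsByGene \code{GRangesList} parallel to \code{geneRanges}.
#' @export
setClass("GeneModels",
         slots = c(geneRanges = "GRanges", exonsByGene = "GRangesList"))

setValidity("GeneModels", function(object) {
  msg <- character()
  g <- object@geneRanges
  e <- object@exonsByGene
  if (is.null(names(g)) && length(g) > 0L)
    msg <- c(msg, "geneRanges must be named by gene ID")
  if (length(g) && anyDuplicated(names(g)))
    msg <- c(msg, "gene IDs must be unique")
  if (!identical(names(e), names(g)))
    msg <- c(msg, "exonsByGene must be parallel to geneRanges (same names)")
  else if (length(g)) {
    for (i in seq_along(g)) {
      ex <- e[[i]]
      if (length(ex) == 0L) next
      if (is.unsorted(start(ex)))
        msg <- c(msg, paste0("exons of gene '", names(g)[i],
                             "' not sorted by start"))
      if (any(start(ex) < start(g)[i]) || any(end(ex) > end(g)[i]))
        msg <- c(msg, paste0("exon outside gene span for '",
                             names(g)[i], "'"))
      if (length(msg) > 4L) break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModels object
#'
#' @param geneRanges named \code{GRanges} of gene spans.
#' @param exonsByGene \code{GRangesList} of exons, same names/order.
#' @return A \linkS4class{GeneModels}.
#' @export
GeneModels <- function(geneRanges = GRanges(),
                       exonsByGene = GRangesList()) {
  if (length(geneRanges) && is.null(names(exonsByGene)))
    names(exonsByGene) <- names(geneRanges)
  new("GeneModels", geneRanges = geneRanges, exonsByGene = exonsByGene)
}

#' @rdname GeneModels-class
#' @param x a \code{GeneModels}.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModels-class
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@geneRanges)

#' @rdname GeneModels-class
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))

#' @rdname GeneModels-class
#' @export
setMethod("exonsByGene", "GeneModels", function(x) x@exonsByGene)

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels with", length(object@geneRanges), "genes and",
      sum(lengths(object@exonsByGene)), "exons\n")
})

setMethod("length", "GeneModels", function(x) length(x@geneRanges))

#' ChainSet: a parsed UCSC chain file
#'
#' Pairwise-alignment chains for coordinate liftover. Each chain is a list
#' with fields \code{id}, \code{score}, source side (\code{sName},
#' \code{sSize}, \code{sStrand}, \code{sStart}, \code{sEnd}; 0-based
#' half-open as in the chain format), target side (\code{tName}, ...), and
#' a \code{blocks} matrix with columns \code{size}, \code{sGap},
#' \code{tGap} (gaps after each block; last block has gaps 0). Validity
#' enforces the chain-format arithmetic: block sizes plus gaps must equal
#' the declared source and target spans.
#'
#' @slot chains list of chain records.
#' @export
setClass("ChainSet", slots = c(chains = "list"))

setValidity("ChainSet", function(object) {
  msg <- character()
  for (ch in object@chains) {
    b <- ch$blocks
    if (any(b[, "size"] <= 0))
      msg <- c(msg, paste0("chain ", ch$id, ": block sizes must be > 0"))
    sSpan <- sum(b[, "size"]) + sum(b[, "sGap"])
    tSpan <- sum(b[, "size"]) + sum(b[, "tGap"])
    if (sSpan != ch$sEnd - ch$sStart)
      msg <- c(msg, paste0("chain ", ch$id,
                           ": blocks+gaps do not match declared source span"))
    if (tSpan != ch$tEnd - ch$tStart)
      msg <- c(msg, paste0("chain ", ch$id,
                           ": blocks+gaps do not match declared target span"))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ChainSet-class
#' @param x a \code{ChainSet}.
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' @rdname ChainSet-class
#' @export
setMethod("chains", "ChainSet", function(x) x@chains)

setMethod("show", "ChainSet", function(object) {
  cat("ChainSet with", length(object@chains), "chain(s)\n")
  for (ch in head(object@chains, 5L))
    cat(sprintf("  chain %s: %s:%d-%d (%s) -> %s:%d-%d (%s), score %g, %d block(s)\n",
                ch$id, ch$sName, ch$sStart, ch$sEnd, ch$sStrand,
                ch$tName, ch$tStart, ch$tEnd, ch$tStrand,
                ch$score, nrow(ch$blocks)))
  if (length(object@chains) > 5L) cat("  ...\n")
})

setMethod("length", "ChainSet", function(x) length(x@chains))
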