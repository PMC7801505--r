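# Relating circRNA junctions to gene models: host genes, exon-intron
# boundary concordance, exon content, and summary distributions.

#' @noRd
.circRanges <- function(circs) {
  if (is(circs, "CircCandidateSet")) rowRanges(circs) else circs
}

#' @noRd
.circIdsOf <- function(circs) {
  if (is(circs, "CircCandidateSet")) return(circIds(circs))
  gr <- circs
  if (!is.null(gr$circ_id)) gr$circ_id
  else if (!is.null(names(gr))) names(gr)
  else paste0("circ", seq_along(gr))
}

#' Host genes overlapping each circRNA
#'
#' Genes whose span overlaps the circRNA interval by at least one base.
#' An empty result for a circRNA means it is intergenic.
#'
#' @param circs a \linkS4class{CircCandidateSet} or \code{GRanges}.
#' @param models a \linkS4class{GeneModels}.
#' @return \code{CharacterList}, one element of host gene IDs per circRNA.
#' @export
overlapGenes <- function(circs, models) {
  gr <- .circRanges(circs)
  genes <- geneRanges(models)
  hits <- findOverlaps(gr, genes, ignore.strand = TRUE)
  out <- rep(list(character()), length(gr))
  if (length(hits)) {
    sp <- split(names(genes)[subjectHits(hits)], queryHits(hits))
    out[as.integer(names(sp))] <- sp
  }
  CharacterList(out)
}

#' Exon-intron boundary concordance of circRNA ends
#'
#' An end is concordant when it coincides (within \code{tolerance} bases)
#' with an exon boundary of any overlapping gene: the circRNA start with
#' an exon start and the circRNA end with an exon end. Returns one of
#' \code{both_ends}, \code{one_end}, \code{neither}, or \code{intergenic}
#' (no gene overlap) per circRNA.
#'
#' @param circs a \linkS4class{CircCandidateSet} or \code{GRanges}.
#' @param models a \linkS4class{GeneModels}.
#' @param tolerance maximum distance (nt) to an exon boundary; default 0
#'   (exact).
#' @return factor over the four boundary classes, one value per circRNA.
#' @export
boundaryConcordance <- function(circs, models, tolerance = 0L) {
  gr <- .circRanges(circs)
  hosts <- overlapGenes(gr, models)
  ex <- exonsByGene(models)
  cls <- vapply(seq_along(gr), function(i) {
    h <- hosts[[i]]
    if (length(h) == 0L) return("intergenic")
    exAll <- unlist(ex[h], use.names = FALSE)
    if (length(exAll) == 0L) return("neither")
    sOK <- any(abs(start(exAll) - start(gr)[i]) <= tolerance)
    eOK <- any(abs(end(exAll) - end(gr)[i]) <= tolerance)
    if (sOK && eOK) "both_ends" else if (sOK || eOK) "one_end" else "neither"
  }, "")
  factor(cls, levels = .BOUNDARY_CLASSES)
}

#' Number of exons contained in each circRNA
#'
#' Counts the distinct exons of overlapping genes that lie fully inside
#' the circRNA interval (distinct by start/end, so identical exons shared
#' by several transcripts count once).
#'
#' @inheritParams boundaryConcordance
#' @return integer vector, one count per circRNA.
#' @export
exonCount <- function(circs, models) {
  gr <- .circRanges(circs)
  hosts <- overlapGenes(gr, models)
  ex <- exonsByGene(models)
  vapply(seq_along(gr), function(i) {
    h <- hosts[[i]]
    if (length(h) == 0L) return(0L)
    exAll <- unlist(ex[h], use.names = FALSE)
    if (length(exAll) == 0L) return(0L)
    inside <- start(exAll) >= start(gr)[i] & end(exAll) <= end(gr)[i]
    length(unique(paste(start(exAll)[inside], end(exAll)[inside])))
  }, 0L)
}

#' Number of circRNAs hosted by each gene
#'
#' @inheritParams boundaryConcordance
#' @return named integer vector: for every gene hosting at least one
#'   circRNA, how many candidates overlap it. \code{table()} of the result
#'   is the circRNAs-per-gene histogram.
#' @export
circsPerGene <- function(circs, models) {
  hosts <- overlapGenes(circs, models)
  tab <- table(unlist(hosts, use.names = FALSE))
  setNames(as.integer(tab), names(tab))
}

#' Per-chromosome circRNA counts
#'
#' @param circs a \linkS4class{CircCandidateSet} or \code{GRanges}.
#' @return data.frame with \code{chrom} and \code{count}, sorted by
#'   decreasing count.
#' @export
perChromCounts <- function(circs) {
  gr <- .circRanges(circs)
  tab <- table(as.character(seqnames(gr)))
  out <- data.frame(chrom = names(tab), count = as.integer(tab),
                    row.names = NULL)
  out[order(-out$count), , drop = FALSE]
}

#' Infer a human host gene for unannotated homologous circRNAs
#'
#' CircRNAs fully homologous to a database circRNA but lacking a host gene
#' in the source species can be screened for genes annotated at the lifted
#' locus in the target species. Precondition: every supplied call must be
#' \code{homologous} and have an empty source-species host list; a
#' violation is an error.
#'
#' @param calls \code{DataFrame} from \code{\link{classifyConservation}}
#'   (rows selected by the caller).
#' @param humanModels \linkS4class{GeneModels} on the target genome.
#' @param sourceHosts \code{CharacterList} of source-species host genes,
#'   parallel to \code{calls} (e.g. from \code{\link{overlapGenes}}).
#' @return \code{CharacterList} of target-species gene IDs per call
#'   (empty when the lifted locus is intergenic).
#' @export
inferHumanHostGene <- function(calls, humanModels, sourceHosts) {
  if (nrow(calls) == 0L) return(CharacterList())
  if (any(as.character(calls$category) != "homologous"))
    stop("precondition violation: all calls must be homologous",
         call. = FALSE)
  if (any(lengths(sourceHosts) > 0L))
    stop("precondition violation: source-species host list must be empty",
         call. = FALSE)
  lo <- pmin(calls$lifted5Pos, calls$lifted3Pos)
  hi <- pmax(calls$lifted5Pos, calls$lifted3Pos)
  lifted <- GRanges(calls$lifted5Chrom, IRanges(lo, hi))
  overlapGenes(lifted, humanModels)
}
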