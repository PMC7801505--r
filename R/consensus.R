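# Two-caller consensus: junction matching, expression filtering, ID
# assignment, and multi-set comparison.

#' Match backsplice junctions between two callers
#'
#' A junction pair is matched when chrom, start and end are identical in
#' internal coordinates and the strands are compatible (equal, or at least
#' one unknown; \code{strict = TRUE} requires equality). Each junction is
#' matched at most once; among multiple strand-compatible partners the
#' first in genomic order wins.
#'
#' @param a,b \linkS4class{BsjCallSet}s with identical sample order.
#' @param strict require strand equality.
#' @return \code{DataFrame} with columns \code{idxA}, \code{idxB} (row
#'   indices into \code{a} and \code{b}).
#' @export
matchJunctions <- function(a, b, strict = FALSE) {
  stopifnot(is(a, "BsjCallSet"), is(b, "BsjCallSet"))
  if (!identical(sampleOrder(a), sampleOrder(b)))
    stop("sample order differs between call sets", call. = FALSE)
  keyA <- .junctionKey(rowRanges(a), with_strand = FALSE)
  keyB <- .junctionKey(rowRanges(b), with_strand = FALSE)
  common <- intersect(keyA, keyB)
  if (length(common) == 0L)
    return(DataFrame(idxA = integer(), idxB = integer()))
  idxA <- idxB <- integer()
  strA <- as.character(strand(rowRanges(a)))
  strB <- as.character(strand(rowRanges(b)))
  byA <- split(seq_along(keyA), keyA)
  byB <- split(seq_along(keyB), keyB)
  for (k in common) {
    ia <- byA[[k]]; ib <- byB[[k]]
    usedB <- logical(length(ib))
    for (i in ia) {
      comp <- if (strict) strB[ib] == strA[i] else
        .strandCompatible(strA[i], strB[ib])
      j <- which(comp & !usedB)
      if (length(j)) {
        usedB[j[1L]] <- TRUE
        idxA <- c(idxA, i)
        idxB <- c(idxB, ib[j[1L]])
      }
    }
  }
  ord <- order(idxA)
  DataFrame(idxA = idxA[ord], idxB = idxB[ord])
}

#' Is a count "expressed"?
#'
#' A junction is considered expressed in a sample when its read count
#' reaches the minimum (default 2 reads).
#'
#' @param count non-negative integer count(s).
#' @param minCount expression threshold (default 2).
#' @return logical vector.
#' @examples
#' isExpressed(c(0, 1, 2, 5))
#' @export
isExpressed <- function(count, minCount = 2L) {
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  count >= minCount
}

#' Consensus expression filter over matched junctions
#'
#' Applies the two-caller expression-pattern filter to matched junctions.
#' In both modes a sample "supports" a junction only when the count
#' reaches \code{minCount} in that same sample in \emph{both} callers.
#' \describe{
#'   \item{all_samples}{keep a junction when at least \code{minSamples}
#'     samples support it (the rule used for a single-condition design).}
#'   \item{within_group}{keep it when some single group contains at least
#'     \code{minSamples} supporting samples.}
#' }
#' The looser reading, in which each caller may satisfy the threshold in
#' different samples, is available via \code{samplesShared = FALSE}.
#' Survivors carry the reference caller's counts and sequential IDs
#' (\code{circRNA1}, \code{circRNA2}, ...) assigned after sorting by
#' (chrom, start, end), making the numbering deterministic.
#'
#' @param a,b \linkS4class{BsjCallSet}s (same sample order).
#' @param design sample sheet data.frame (see
#'   \code{\link{readSampleSheet}}) covering every sample in the call sets.
#' @param mode \code{"all_samples"} or \code{"within_group"}.
#' @param minSamples minimum number of supporting samples (default 3).
#' @param minCount minimum read count per supporting sample (default 2).
#' @param reference which caller's counts are reported: \code{"b"}
#'   (default) or \code{"a"}.
#' @param matches optional precomputed \code{\link{matchJunctions}} result.
#' @param samplesShared if \code{FALSE}, the supporting samples need not
#'   be the same in both callers.
#' @param idPrefix prefix for sequential identifiers.
#' @return A \linkS4class{CircCandidateSet}.
#' @export
filterCandidates <- function(a, b, design,
                             mode = c("all_samples", "within_group"),
                             minSamples = 3L, minCount = 2L,
                             reference = c("b", "a"),
                             matches = NULL,
                             samplesShared = TRUE,
                             idPrefix = "circRNA") {
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  samples <- sampleOrder(a)
  if (!all(samples %in% design$sample_id))
    stop("design is missing sample(s): ",
         paste(setdiff(samples, design$sample_id), collapse = ", "),
         call. = FALSE)
  grp <- design$group[match(samples, design$sample_id)]
  if (mode == "within_group") {
    if (minSamples > max(table(grp)))
      stop("configuration error: minSamples exceeds every group size",
           call. = FALSE)
  }
  if (is.null(matches)) matches <- matchJunctions(a, b)

  emptySet <- function() {
    empty <- SummarizedExperiment(
      assays = list(counts = matrix(integer(), 0, length(samples),
                                    dimnames = list(NULL, samples))),
      rowRanges = GRanges())
    rowData(empty)$circ_id <- character()
    rowData(empty)$circType <- character()
    new("CircCandidateSet", empty,
        referenceCaller = callerId(if (reference == "b") b else a))
  }
  if (nrow(matches) == 0L) return(emptySet())

  cntA <- assay(a, "counts")[matches$idxA, , drop = FALSE]
  cntB <- assay(b, "counts")[matches$idxB, , drop = FALSE]
  exprA <- cntA >= minCount
  exprB <- cntB >= minCount
  support <- if (samplesShared) exprA & exprB else NULL

  keep <- if (mode == "all_samples") {
    if (samplesShared) rowSums(support) >= minSamples
    else rowSums(exprA) >= minSamples & rowSums(exprB) >= minSamples
  } else {
    groups <- unique(grp)
    anyGroup <- rep(FALSE, nrow(matches))
    for (g in groups) {
      cols <- which(grp == g)
      ok <- if (samplesShared)
        rowSums(support[, cols, drop = FALSE]) >= minSamples
      else rowSums(exprA[, cols, drop = FALSE]) >= minSamples &
        rowSums(exprB[, cols, drop = FALSE]) >= minSamples
      anyGroup <- anyGroup | ok
    }
    anyGroup
  }

  if (!any(keep)) return(emptySet())
  refSet <- if (reference == "b") b else a
  refIdx <- (if (reference == "b") matches$idxB else matches$idxA)[keep]
  gr <- rowRanges(refSet)[refIdx]
  cnt <- assay(refSet, "counts")[refIdx, , drop = FALSE]
  circType <- if (!is.null(rowData(refSet)$circType))
    rowData(refSet)$circType[refIdx] else rep("unknown", length(refIdx))

  ord <- order(as.character(seqnames(gr)), start(gr), end(gr))
  gr <- gr[ord]
  cnt <- cnt[ord, , drop = FALSE]
  circType <- circType[ord]

  se <- SummarizedExperiment(assays = list(counts = cnt), rowRanges = gr)
  rowData(se)$circ_id <- paste0(idPrefix, seq_along(gr))
  rowData(se)$circType <- circType
  new("CircCandidateSet", se, referenceCaller = callerId(refSet))
}

#' Compare circRNA coordinate sets across tissues or studies
#'
#' Exact-coordinate membership comparison of any number of named sets, as
#' drawn in UpSet plots: every non-empty membership pattern over the sets
#' is listed with the number of elements showing exactly that pattern.
#' Pattern counts therefore sum to the size of the union.
#'
#' @param sets named list of character vectors (e.g. junction coordinate
#'   keys) or of \code{GRanges} (converted to chrom:start:end:strand keys).
#' @param minSize drop patterns with fewer elements from the output
#'   (display convenience; default 0 keeps all).
#' @return data.frame with one logical column per set, plus \code{count},
#'   sorted by decreasing count.
#' @examples
#' compareSets(list(A = c("x", "y"), B = c("y", "z")))
#' @export
compareSets <- function(sets, minSize = 0L) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names", call. = FALSE)
  sets <- lapply(sets, function(s) {
    if (is(s, "GRanges")) .junctionKey(s) else as.character(s)
  })
  sets <- lapply(sets, unique)
  univ <- unique(unlist(sets, use.names = FALSE))
  if (length(univ) == 0L) {
    out <- as.data.frame(setNames(rep(list(logical()), length(sets)),
                                  names(sets)))
    out$count <- integer()
    return(out)
  }
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(univ))
  pattern <- apply(member, 1L, paste, collapse = "")
  tab <- table(pattern)
  pats <- names(tab)
  flagMat <- do.call(rbind, lapply(pats, function(p)
    as.logical(member[match(p, pattern), , drop = TRUE])))
  out <- as.data.frame(flagMat)
  names(out) <- names(sets)
  out$count <- as.integer(tab)
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  out[out$count >= minSize, , drop = FALSE]
}
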