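# SRPBM normalization and nonparametric differential expression.

#' SRPBM normalization
#'
#' Spliced Reads Per Billion Mapped reads: each backsplice count is
#' divided by the sample's total mapped reads and scaled by 1e9. The
#' totals should be the per-sample number of reads aligned to the
#' reference annotation; whether that means uniquely or multiply mapped
#' reads is left to the caller, who supplies the totals.
#'
#' @param counts circRNA x sample count matrix.
#' @param mappedTotals per-sample totals, either named (matched to
#'   \code{colnames(counts)}) or positional; all must be > 0.
#' @return numeric matrix of the same shape.
#' @examples
#' srpbm(matrix(5, 1, 1, dimnames = list("c1", "s1")), c(s1 = 1e9))
#' @export
srpbm <- function(counts, mappedTotals) {
  counts <- as.matrix(counts)
  if (!is.null(names(mappedTotals)) && !is.null(colnames(counts))) {
    m <- match(colnames(counts), names(mappedTotals))
    if (anyNA(m))
      stop("mapped totals missing for sample(s): ",
           paste(colnames(counts)[is.na(m)], collapse = ", "),
           call. = FALSE)
    mappedTotals <- mappedTotals[m]
  }
  if (length(mappedTotals) != ncol(counts))
    stop("need one mapped total per sample", call. = FALSE)
  bad <- which(mappedTotals <= 0)
  if (length(bad))
    stop("zero or negative mapped total for sample ",
         if (!is.null(colnames(counts))) colnames(counts)[bad[1L]]
         else bad[1L], call. = FALSE)
  sweep(counts, 2L, mappedTotals, "/") * 1e9
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H statistic with the standard tie correction and a
#' chi-square p-value on k-1 degrees of freedom (via
#' \code{\link[stats]{kruskal.test}}). When every value is identical
#' across all groups the test carries no information and returns H = 0,
#' p = 1 rather than an error. For tiny samples an exact permutation
#' p-value over all group relabelings is available.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, parallel to \code{values}; at least two
#'   groups, each non-empty.
#' @param exact compute the permutation p-value (enumerates all
#'   assignments; only sensible for about n <= 10).
#' @return list with \code{statistic} and \code{p.value}.
#' @export
kruskalWallis <- function(values, groups, exact = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(table(groups) == 0L))
    stop("every group needs at least one value", call. = FALSE)
  if (length(values) != length(groups))
    stop("values and groups must be parallel", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p.value = 1))
  kt <- stats::kruskal.test(values, groups)
  H <- unname(kt$statistic)
  p <- kt$p.value
  if (exact) {
    H <- round(H, 12)   # guard FP noise in the >= comparison
    perms <- .groupAssignments(as.integer(table(groups)))
    stats <- vapply(perms, function(g) {
      k <- stats::kruskal.test(values, factor(g))$statistic
      round(unname(k), 12)
    }, 0)
    p <- mean(stats >= H)
  }
  list(statistic = H, p.value = p)
}

# All distinct assignments of n = sum(sizes) items into groups of the
# given sizes (each assignment an integer label vector). Used for the
# exact permutation p-value.
#' @noRd
.groupAssignments <- function(sizes) {
  n <- sum(sizes)
  recur <- function(remaining, sizes, g) {
    if (length(sizes) == 1L) {
      lab <- integer(n)
      lab[remaining] <- g
      return(list(lab))
    }
    out <- list()
    # fix the smallest remaining index into the current group to avoid
    # counting permutations of identical partitions multiple times is not
    # needed here: labelled groups, so plain combinations are correct
    combs <- utils::combn(remaining, sizes[1L], simplify = FALSE)
    for (cc in combs) {
      rest <- recur(setdiff(remaining, cc), sizes[-1L], g + 1L)
      out <- c(out, lapply(rest, function(lab) {
        lab[cc] <- g
        lab
      }))
    }
    out
  }
  recur(seq_len(n), sizes, 1L)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, bounded by 1
#' (\code{\link[stats]{p.adjust}} with \code{method = "BH"}).
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' SRPBM + Kruskal-Wallis differential expression
#'
#' The full nonparametric differential-expression path for circRNA
#' counts: SRPBM normalization, optional batch adjustment, a per-circRNA
#' Kruskal-Wallis test across groups, and Benjamini-Hochberg correction.
#' The batch adjustment is a simple documented stand-in (per-batch
#' median-centering of log1p SRPBM values per circRNA), off by default.
#'
#' @param counts circRNA x sample count matrix; row names are circRNA
#'   IDs.
#' @param mappedTotals per-sample mapped-read totals (see
#'   \code{\link{srpbm}}).
#' @param design sample sheet data.frame covering all samples.
#' @param grouping design column to test across (default "group").
#' @param alpha significance cut-off on the adjusted p-value (default
#'   0.05).
#' @param batchAdjust apply the batch stand-in using the design's
#'   \code{batch} column.
#' @param exact use the exact permutation Kruskal-Wallis p-value.
#' @return \code{DataFrame}: \code{circ_id}, one \code{median_<group>}
#'   column of per-group median SRPBM per group, \code{kwStatistic},
#'   \code{pValue}, \code{adjustedP}, \code{significant}.
#' @export
runDe <- function(counts, mappedTotals, design, grouping = "group",
                  alpha = 0.05, batchAdjust = FALSE, exact = FALSE) {
  counts <- as.matrix(counts)
  samples <- colnames(counts)
  if (is.null(samples)) stop("counts must have sample column names",
                             call. = FALSE)
  m <- match(samples, design$sample_id)
  if (anyNA(m))
    stop("design is missing sample(s): ",
         paste(samples[is.na(m)], collapse = ", "), call. = FALSE)
  grp <- factor(design[[grouping]][m])
  norm <- srpbm(counts, mappedTotals)

  testVals <- norm
  if (batchAdjust) {
    batch <- design$batch[m]
    if (is.null(batch) || all(!nzchar(batch)))
      stop("batchAdjust = TRUE but the design has no batch labels",
           call. = FALSE)
    lg <- log1p(norm)
    for (b in unique(batch)) {
      cols <- which(batch == b)
      ctr <- apply(lg[, cols, drop = FALSE], 1L, stats::median)
      lg[, cols] <- lg[, cols, drop = FALSE] - ctr
    }
    testVals <- lg
  }

  ids <- if (!is.null(rownames(counts))) rownames(counts) else
    paste0("circ", seq_len(nrow(counts)))
  res <- lapply(seq_len(nrow(counts)), function(i)
    kruskalWallis(testVals[i, ], grp, exact = exact))
  pv <- vapply(res, `[[`, 0, "p.value")
  adj <- bhAdjust(pv)
  med <- vapply(levels(grp), function(g)
    apply(norm[, grp == g, drop = FALSE], 1L, stats::median),
    numeric(nrow(counts)))
  if (is.null(dim(med))) med <- matrix(med, nrow = 1L,
                                       dimnames = list(NULL, levels(grp)))
  out <- DataFrame(circ_id = ids)
  for (g in levels(grp)) out[[paste0("median_", g)]] <- med[, g]
  out$kwStatistic <- vapply(res, `[[`, 0, "statistic")
  out$pValue <- pv
  out$adjustedP <- adj
  out$significant <- adj < alpha
  out
}
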