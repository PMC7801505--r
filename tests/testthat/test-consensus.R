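# Two-caller consensus: junction matching, expression filters, ID
# assignment, and set comparison.

test_that("junction matching requires exact coordinates", {
  a <- makeCallSet("chr1", c(100, 300), c(200, 400), "+",
                   rbind(c(3, 3), c(3, 3)), c("s1", "s2"), "A")
  bSame <- makeCallSet("chr1", 100, 200, "+", rbind(c(5, 5)),
                       c("s1", "s2"), "B")
  bShift <- makeCallSet("chr1", 101, 200, "+", rbind(c(5, 5)),
                        c("s1", "s2"), "B")
  expect_equal(nrow(matchJunctions(a, bSame)), 1L)
  expect_equal(nrow(matchJunctions(a, bShift)), 0L)
})

test_that("matching is plain set intersection on identical-coordinate sets", {
  # A = {j1, j2}, B = {j2, j3} -> only j2
  a <- makeCallSet("chr1", c(100, 500), c(200, 900), "+",
                   rbind(c(1, 1), c(1, 1)), c("s1", "s2"), "A")
  b <- makeCallSet("chr1", c(500, 2000), c(900, 3000), "+",
                   rbind(c(1, 1), c(1, 1)), c("s1", "s2"), "B")
  m <- matchJunctions(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(start(rowRanges(a))[m$idxA], 500L)
  # and matches the brute-force intersection of coordinate keys
  keys <- intersect(paste(seqnames(rowRanges(a)), start(rowRanges(a)),
                          end(rowRanges(a))),
                    paste(seqnames(rowRanges(b)), start(rowRanges(b)),
                          end(rowRanges(b))))
  expect_equal(nrow(m), length(keys))
})

test_that("strand compatibility: unknown matches either, strict does not", {
  a <- makeCallSet("chr1", 100, 200, "+", rbind(c(3, 3)), c("s1", "s2"), "A")
  b <- makeCallSet("chr1", 100, 200, "*", rbind(c(3, 3)), c("s1", "s2"), "B")
  expect_equal(nrow(matchJunctions(a, b)), 1L)
  expect_equal(nrow(matchJunctions(a, b, strict = TRUE)), 0L)
  bMinus <- makeCallSet("chr1", 100, 200, "-", rbind(c(3, 3)),
                        c("s1", "s2"), "B")
  expect_equal(nrow(matchJunctions(a, bMinus)), 0L)
})

test_that("sample order mismatch is a design error", {
  a <- makeCallSet("chr1", 100, 200, "+", rbind(c(3, 3)), c("s1", "s2"), "A")
  b <- makeCallSet("chr1", 100, 200, "+", rbind(c(3, 3)), c("s2", "s1"), "B")
  expect_error(matchJunctions(a, b), "sample order")
})

test_that("the expression threshold is a plain inclusive minimum", {
  expect_equal(isExpressed(c(0, 1, 2, 7)), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(isExpressed(5, minCount = 5))
  expect_error(isExpressed(-1), "non-negative")
})

test_that("all_samples mode demands the same supporting samples in both tools", {
  design <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                       group = c("g1", "g1", "g2", "g2"),
                       timepoint = "", batch = "")
  # caller A expressed in s1,s2,s3; caller B in s1,s2,s4:
  # only two shared supporting samples -> rejected under the shared rule
  a <- makeCallSet("chr1", 100, 200, "+", rbind(c(2, 2, 2, 0)),
                   design$sample_id, "A")
  b <- makeCallSet("chr1", 100, 200, "+", rbind(c(2, 2, 0, 2)),
                   design$sample_id, "B")
  strictRes <- filterCandidates(a, b, design, mode = "all_samples",
                                minSamples = 3)
  expect_equal(length(strictRes), 0L)
  # the documented looser reading keeps it (3 samples per tool, not shared)
  loose <- filterCandidates(a, b, design, mode = "all_samples",
                            minSamples = 3, samplesShared = FALSE)
  expect_equal(length(loose), 1L)
})

test_that("within_group mode needs the shared samples inside one group", {
  design <- data.frame(sample_id = paste0("s", 1:6),
                       group = rep(c("g1", "g2"), each = 3),
                       timepoint = "", batch = "")
  # three shared supporting samples, all in group g1
  a <- makeCallSet("chr1", 100, 200, "+", rbind(c(2, 2, 2, 0, 0, 0)),
                   design$sample_id, "A")
  b <- makeCallSet("chr1", 100, 200, "+", rbind(c(4, 4, 4, 0, 0, 0)),
                   design$sample_id, "B")
  expect_equal(length(filterCandidates(a, b, design,
                                       mode = "within_group")), 1L)
  # three supporting samples scattered across groups: kept by all_samples,
  # rejected by within_group
  a2 <- makeCallSet("chr1", 100, 200, "+", rbind(c(2, 2, 0, 2, 0, 0)),
                    design$sample_id, "A")
  b2 <- makeCallSet("chr1", 100, 200, "+", rbind(c(2, 2, 0, 2, 0, 0)),
                    design$sample_id, "B")
  expect_equal(length(filterCandidates(a2, b2, design,
                                       mode = "all_samples")), 1L)
  expect_equal(length(filterCandidates(a2, b2, design,
                                       mode = "within_group")), 0L)
  expect_error(filterCandidates(a, b, design, mode = "within_group",
                                minSamples = 4), "configuration error")
})

test_that("empty match list gives an empty candidate set", {
  design <- data.frame(sample_id = c("s1", "s2", "s3"), group = "g",
                       timepoint = "", batch = "")
  a <- makeCallSet("chr1", 100, 200, "+", rbind(c(2, 2, 2)),
                   design$sample_id, "A")
  b <- makeCallSet("chr2", 100, 200, "+", rbind(c(2, 2, 2)),
                   design$sample_id, "B")
  res <- filterCandidates(a, b, design, mode = "all_samples")
  expect_s4_class(res, "CircCandidateSet")
  expect_equal(length(res), 0L)
})

test_that("survivors carry reference counts and position-sorted sequential IDs", {
  design <- data.frame(sample_id = c("s1", "s2", "s3"), group = "g",
                       timepoint = "", batch = "")
  # rows deliberately out of genomic order
  a <- makeCallSet("chr1", c(5000, 100), c(6000, 200), "+",
                   rbind(c(2, 3, 2), c(2, 2, 2)), design$sample_id, "A")
  b <- makeCallSet("chr1", c(100, 5000), c(200, 6000), "+",
                   rbind(c(9, 9, 9), c(7, 7, 7)), design$sample_id, "B",
                   circType = c("exonic", "intronic"))
  res <- filterCandidates(a, b, design, mode = "all_samples")
  expect_equal(circIds(res), c("circRNA1", "circRNA2"))
  expect_equal(start(rowRanges(res)), c(100L, 5000L))
  expect_equal(unname(assay(res, "counts")[1, ]), c(9L, 9L, 9L))
  expect_equal(rowData(res)$circType, c("exonic", "intronic"))
  expect_equal(callerId(res), "B")
})

test_that("filtering is invariant to input row order and monotone in thresholds", {
  models <- genAnnotation(21)
  chain <- genChain(22)
  truth <- genTruth(23, models, chain, nCirc = 20,
                    categories = "homologous")
  design <- exampleDesign("encephalon")
  tabs <- genCallerTables(truth, design, fpRate = c(0.3, 0.3),
                          dropoutRate = 0.1, seed = 24)
  res <- filterCandidates(tabs$a, tabs$b, design, mode = "all_samples")
  # permute rows of both callers
  perm <- function(x) {
    set.seed(99)
    idx <- sample(length(x))
    BsjCallSet(rowRanges(x)[idx],
               assay(x, "counts")[idx, , drop = FALSE],
               callerId = callerId(x),
               circType = rowData(x)$circType[idx])
  }
  res2 <- filterCandidates(perm(tabs$a), perm(tabs$b), design,
                           mode = "all_samples")
  expect_equal(granges(rowRanges(res)), granges(rowRanges(res2)))
  expect_equal(circIds(res), circIds(res2))

  # monotonicity: stricter thresholds never add survivors
  nAt <- function(minCount, minSamples)
    length(filterCandidates(tabs$a, tabs$b, design, mode = "all_samples",
                            minCount = minCount, minSamples = minSamples))
  counts <- vapply(1:5, function(mc) nAt(mc, 3), 0L)
  expect_true(all(diff(counts) <= 0))
  samps <- vapply(1:6, function(ms) nAt(2, ms), 0L)
  expect_true(all(diff(samps) <= 0))
})

test_that("set comparison enumerates every membership pattern exactly", {
  res <- compareSets(list(A = c("x", "y"), B = c("y", "z")))
  get <- function(a, b) res$count[res$A == a & res$B == b]
  expect_equal(get(TRUE, FALSE), 1L)
  expect_equal(get(FALSE, TRUE), 1L)
  expect_equal(get(TRUE, TRUE), 1L)
  expect_equal(sum(res$count), 3L)   # |union|

  # one empty set: its exclusive pattern is absent
  res2 <- compareSets(list(A = c("x"), B = character()))
  expect_false(any(res2$B & !res2$A))
  # identical sets collapse to a single all-TRUE pattern
  res3 <- compareSets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(nrow(res3), 1L)
  expect_true(res3$A & res3$B)
  expect_error(compareSets(list(A = "x", A = "y")), "duplicate")
})

test_that("set comparison agrees with brute-force enumeration on random sets", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    sets <- setNames(lapply(seq_len(k), function(i)
      sample(letters, sample(0:15, 1))), LETTERS[seq_len(k)])
    res <- compareSets(sets)
    oracle <- oracleCompareSets(lapply(sets, unique))
    expect_equal(sum(res$count), length(unique(unlist(sets))))
    resPat <- apply(res[, seq_len(k), drop = FALSE], 1,
                    paste, collapse = "|")
    expect_equal(unname(setNames(res$count, resPat)[names(oracle)]),
                 as.vector(oracle))
    expect_equal(nrow(res), length(oracle))
  }
})

test_that("minSize display filter drops small patterns only", {
  res <- compareSets(list(A = letters[1:10], B = letters[8:12]),
                     minSize = 3)
  expect_true(all(res$count >= 3))
})
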