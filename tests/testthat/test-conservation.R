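# Chain lifting and the six-category conservation classifier.

test_that("an identity chain maps intervals onto themselves", {
  cs <- makeChain("s1", 0, list(c(1000, 0, 0)), "t1", 0)
  q <- GRanges("s1", IRanges(c(1, 101), c(50, 400)), strand = "+")
  res <- liftInterval(cs, q)
  expect_equal(res$status, c("mapped", "mapped"))
  expect_equal(res$targetStart, start(q))
  expect_equal(res$targetEnd, end(q))
  expect_equal(res$remapRatio, c(1, 1))
})

test_that("a target gap before the query shifts it by the gap size", {
  # block 50, then target gap 10, then block 100: source pos >= 50 maps +10
  cs <- makeChain("s1", 0, list(c(50, 0, 10), c(100, 0, 0)), "t1", 0)
  q <- GRanges("s1", IRanges(61, 80))
  res <- liftInterval(cs, q)
  expect_equal(res$status, "mapped")
  expect_equal(res$targetStart, 71L)
  expect_equal(res$targetEnd, 90L)
  # source gap instead: query inside it is unmapped
  cs2 <- makeChain("s1", 0, list(c(50, 20, 0), c(100, 0, 0)), "t1", 0)
  q2 <- GRanges("s1", IRanges(55, 65))   # fully inside the 50..69 gap
  expect_equal(liftInterval(cs2, q2)$status, "unmapped")
})

test_that("the remap-ratio rule is all-or-none at the 0.95 default", {
  # 20-base query with exactly 1 base in a source gap: ratio 0.95, mapped
  cs <- makeChain("s1", 0, list(c(50, 1, 0), c(100, 0, 0)), "t1", 0)
  q1 <- GRanges("s1", IRanges(32, 51))   # bases 31..50 (0-based), gap = {50}
  res1 <- liftInterval(cs, q1)
  expect_equal(res1$remapRatio, 0.95)
  expect_equal(res1$status, "mapped")
  # 2 gap bases out of 20: ratio 0.9, unmapped
  cs2 <- makeChain("s1", 0, list(c(50, 2, 0), c(100, 0, 0)), "t1", 0)
  res2 <- liftInterval(cs2, GRanges("s1", IRanges(33, 52)))
  expect_equal(res2$remapRatio, 0.9)
  expect_equal(res2$status, "unmapped")
})

test_that("inverting chains flip strand and report plus-strand coordinates", {
  cs <- makeChain("s1", 0, list(c(100, 0, 0)), "t1", 0, tStrand = "-",
                  tSize = 100)
  q <- GRanges("s1", IRanges(11, 20), strand = "+")
  res <- liftInterval(cs, q)
  expect_equal(res$status, "mapped")
  # source 0-based 10..19 -> reversed target = 100-1-(10..19) = 89..80
  expect_equal(res$targetStart, 81L)
  expect_equal(res$targetEnd, 90L)
  expect_equal(res$targetStrand, "-")
})

test_that("equal-score overlapping chains resolve to the lowest chain id", {
  c1 <- makeChain("s1", 0, list(c(100, 0, 0)), "t1", 0, id = "2")
  c2 <- makeChain("s1", 0, list(c(100, 0, 0)), "t1", 500, id = "10")
  both <- new("ChainSet", chains = c(chains(c1), chains(c2)))
  res <- liftInterval(both, GRanges("s1", IRanges(5, 10)))
  expect_equal(res$targetStart, 5L)   # chain "2" (numeric order), not "10"
  # higher score wins regardless of id
  c3 <- makeChain("s1", 0, list(c(100, 0, 0)), "t1", 500, id = "10",
                  score = 1e6)
  both2 <- new("ChainSet", chains = c(chains(c1), chains(c3)))
  expect_equal(liftInterval(both2, GRanges("s1", IRanges(5, 10)))$targetStart,
               505L)
})

test_that("lifting agrees with the per-base expansion oracle on random chains", {
  set.seed(1234)
  for (rep in 1:300) {
    cs <- randomChain()
    ch <- chains(cs)[[1]]
    for (j in 1:3) {
      w <- sample(1:5, 1)
      s1 <- sample(max(1, ch$sStart - 5):(ch$sEnd + 5), 1)
      q <- GRanges("src", IRanges(s1, s1 + w - 1))
      got <- liftInterval(cs, q)
      want <- oracleLift(cs, "src", s1, s1 + w - 1)
      expect_equal(got$status, want$status)
      if (want$status == "mapped") {
        expect_equal(got$targetStart, as.integer(want$start))
        expect_equal(got$targetEnd, as.integer(want$end))
        expect_equal(got$remapRatio, want$ratio)
      }
    }
  }
})

test_that("classifier category definitions behave on hand-built fixtures", {
  cs <- makeChain("s1", 0, list(c(10000, 0, 0)), "t1", 0)
  db <- GRanges("t1", IRanges(c(1000, 5000), c(2000, 5400)))
  db$circ_id <- c("R1", "R2")
  mk <- function(s, e) GRanges("s1", IRanges(s, e), strand = "+",
                               circ_id = "q")
  cat1 <- function(circ, tol = 2)
    as.character(classifyConservation(circ, cs, db,
                                      toleranceNt = tol)$category)
  # exact both ends of R1 -> homologous
  expect_equal(cat1(mk(1000, 2000)), "homologous")
  # 5' end at R1.start + 2 (inclusive tolerance boundary), 3' unmatched
  expect_equal(cat1(mk(1002, 3000)), "five_prime_utilized")
  # +3 is outside the +/-2 window
  expect_equal(cat1(mk(1003, 3000)), "no_homologous")
  # 3' end only
  expect_equal(cat1(mk(800, 1998)), "three_prime_utilized")
  # 5' matched by R1 only, 3' by R2 only -> both sites, different records
  expect_equal(cat1(mk(1000, 5000)), "both_sites_utilized")
  # negative boundary case at both ends (-3/+3)
  expect_equal(cat1(mk(997, 2003)), "no_homologous")
  # tolerance 3 turns the same fixture homologous
  expect_equal(cat1(mk(997, 2003), tol = 3), "homologous")
})

test_that("an unliftable end forces not_aligned", {
  cs <- makeChain("s1", 0, list(c(100, 50, 0), c(100, 0, 0)), "t1", 0)
  db <- GRanges("t1", IRanges(1, 200), circ_id = "R1")
  circ <- GRanges("s1", IRanges(50, 120), strand = "+", circ_id = "q")
  res <- classifyConservation(circ, cs, db)
  expect_equal(as.character(res$category), "not_aligned")
  expect_equal(res$status3, "unmapped")
})

test_that("every circRNA gets exactly one category and counts partition", {
  models <- genAnnotation(41)
  chain <- genChain(42)
  truth <- genTruth(43, models, chain, nCirc = 30)
  db <- genCircDb(truth, chain)
  calls <- classifyConservation(truth@circs, chain, db)
  expect_false(anyNA(calls$category))
  summ <- summarizeCategories(calls)
  expect_equal(sum(summ$count), length(truth@circs))
  expect_equal(sum(summ$percentage), 100, tolerance = 0.05)
})

test_that("raising tolerance never demotes a category", {
  models <- genAnnotation(44)
  chain <- genChain(45)
  truth <- genTruth(46, models, chain, nCirc = 24)
  db <- genCircDb(truth, chain)
  rank <- c(not_aligned = 0, no_homologous = 0, five_prime_utilized = 1,
            three_prime_utilized = 1, both_sites_utilized = 2,
            homologous = 3)
  prev <- rank[as.character(classifyConservation(truth@circs, chain, db,
                                                 toleranceNt = 0)$category)]
  for (tol in c(1, 2, 4, 8)) {
    cur <- rank[as.character(classifyConservation(truth@circs, chain, db,
                                                  toleranceNt = tol)$category)]
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("category summary uses all detected circRNAs as denominator", {
  expect_equal(summarizeCategories("homologous")$percentage[6], 100)
  s <- summarizeCategories(rep(c("homologous", "not_aligned",
                                 "no_homologous"), c(2, 1, 1)))
  expect_equal(s$percentage[s$category == "homologous"], 50)
  expect_error(summarizeCategories(character()), "no calls")
  expect_error(summarizeCategories("nonsense"), "unknown")
})
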