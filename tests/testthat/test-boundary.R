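params <- ScoreParams()

test_that("log-space fitness handles the degenerate and perfect cases", {
  n <- 40
  zero <- matrix(0, n, n)
  expect_identical(rnaboundFitness(zero, 15, 25, params), -Inf)

  # perfectly self-contained block: every in-segment row carries unit score
  k <- 15; l <- 26
  perfect <- matrix(0, n, n)
  for (t in 0:5) {
    perfect[k + t, l - t] <- 1
    perfect[l - t, k + t] <- 1
  }
  expect_equal(rnaboundFitness(perfect, k, l, params), 0)
  # and 0 is the maximum: every admissible segment scores <= 0
  for (kk in c(11, 15, 20)) for (ll in c(24, 26, 30)) {
    if (ll > kk)
      expect_lte(rnaboundFitness(perfect, kk, ll, params), 0)
  }
})

test_that("fitness contract errors outside the admissible range", {
  s <- matrix(0, 40, 40)
  expect_error(rnaboundFitness(s, 5, 20, params), "admissible")
  expect_error(rnaboundFitness(s, 15, 35, params), "admissible")
  expect_error(rnaboundFitness(s, 20, 15, params), "admissible")
  expect_error(dotuFitness(BasePairMatrix(s), 7, 7), "invalid")
})

test_that("log-space fitness matches the literal linear-space oracle", {
  for (s in 1:8) {
    bp <- randomSparseBP(30, npairs = 25, seed = 100 + s)
    S <- scoreMatrix(bp, params)
    set.seed(s)
    for (r in 1:10) {
      k <- sample(11:18, 1); l <- sample((k + 1):20, 1)
      expect_equal(rnaboundFitness(S, k, l, params),
                   oracleRnabound(S, k, l, flankLength(params)),
                   tolerance = 1e-9)
    }
    # inside-only transform variant against the same oracle
    P <- as.matrix(bp)
    expect_equal(rnaboundFitness(S, 12, 19, params, outside = P),
                 oracleRnabound(S, 12, 19, flankLength(params), outside = P),
                 tolerance = 1e-9)
  }
})

test_that("comparator fitness matches hand-computed single-pair cases", {
  m <- BasePairMatrix(data.frame(i = 3, j = 8, p = 0.8), n = 10)
  expect_equal(dotuFitness(m, 1, 10), (2 * 0.8) / 10)   # pair inside
  expect_equal(dotuFitness(m, 1, 5), -0.8 / 5)          # pair straddles
  zero <- BasePairMatrix(matrix(0, 10, 10))
  for (i in c(1, 4)) for (j in c(6, 10))
    expect_equal(dotuFitness(zero, i, j), 0)
})

test_that("comparator fitness matches the literal double-loop oracle everywhere", {
  bp <- randomSparseBP(25, npairs = 20, seed = 42)
  P <- as.matrix(bp)
  for (i in seq(1, 24, by = 3)) for (j in seq(i + 1, 25, by = 4)) {
    expect_equal(dotuFitness(bp, i, j), oracleDotu(P, i, j), tolerance = 1e-12)
  }
})

test_that("optimized scanners equal exhaustive per-segment re-evaluation", {
  for (s in 1:6) {
    n <- sample(30:40, 1)
    bp <- randomSparseBP(n, npairs = n, seed = 200 + s)
    S <- scoreMatrix(bp, params)
    f <- flankLength(params)

    pred <- findBoundaries(bp, "rnabound", params)
    best <- -Inf; bu <- NA; bv <- NA
    for (k in (f + 1):(n - f - 1)) for (l in (k + 1):(n - f)) {
      v <- rnaboundFitness(S, k, l, params)
      if (v > best) { best <- v; bu <- k; bv <- l }
    }
    if (is.finite(best)) {
      expect_equal(unname(predictedBoundaries(pred)), c(bu, bv))
      expect_equal(fitnessScore(pred), best, tolerance = 1e-12)
    } else {
      expect_equal(predictionStatus(pred), "no-structure")
    }

    predd <- findBoundaries(bp, "dotu")
    bestd <- -Inf; du <- NA; dv <- NA
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v <- dotuFitness(bp, i, j)
      if (v > bestd) { bestd <- v; du <- i; dv <- j }
    }
    expect_equal(unname(predictedBoundaries(predd)), c(du, dv))
    expect_equal(fitnessScore(predd), bestd, tolerance = 1e-12)
  }
})

test_that("ties break to the smallest start then smallest end", {
  zero <- BasePairMatrix(matrix(0, 30, 30))
  pred <- findBoundaries(zero, "dotu")
  expect_equal(unname(predictedBoundaries(pred)), c(1, 2))
  expect_equal(fitnessScore(pred), 0)
  # empty matrix has no admissible finite-score segment for the log fitness
  predr <- findBoundaries(zero, "rnabound")
  expect_equal(predictionStatus(predr), "no-structure")
  expect_true(all(is.na(predictedBoundaries(predr))))
})

test_that("window shorter than 2f + 2 is a parameter error", {
  small <- BasePairMatrix(matrix(0, 15, 15))
  expect_error(findBoundaries(small, "rnabound"), "too short")
  expect_s4_class(findBoundaries(small, "dotu"), "BoundaryPrediction")
})

test_that("shifting a planted structure shifts the prediction equally", {
  for (d in c(5, 17)) {
    a <- plantStructure(160, "hairpin", start = 41, end = 90, seed = 3)
    b <- plantStructure(160, "hairpin", start = 41 + d, end = 90 + d, seed = 3)
    pa <- predictedBoundaries(findBoundaries(caseMatrix(a)))
    pb <- predictedBoundaries(findBoundaries(caseMatrix(b)))
    expect_equal(unname(pb), unname(pa) + d)
  }
})

test_that("log-fitness never exceeds zero on random matrices", {
  for (s in 1:5) {
    bp <- randomSparseBP(34, npairs = 40, seed = 300 + s)
    S <- scoreMatrix(bp, params)
    set.seed(s)
    for (r in 1:15) {
      k <- sample(11:20, 1); l <- sample((k + 1):24, 1)
      expect_lte(rnaboundFitness(S, k, l, params), 0)
    }
  }
})

test_that("adjacent double hairpin: the log fitness covers both stems", {
  # H/ACA-like: two adjacent stem-loops inside one domain, no pairs spanning
  # between them beyond the margin
  case <- plantStructure(200, "double_hairpin", start = 51, end = 150, seed = 5)
  pred <- findBoundaries(caseMatrix(case))
  stems <- casePairs(case)[casePairs(case)$role == "stem", ]
  uv <- predictedBoundaries(pred)
  expect_lte(uv[["u"]], min(stems$i))
  expect_gte(uv[["v"]], max(stems$j))
})

test_that("suboptimal extraction returns non-overlapping segments in score order", {
  # two separate planted hairpins in one window, no cross pairs
  c1 <- plantStructure(160, "hairpin", start = 21, end = 60, seed = 1)
  c2 <- plantStructure(160, "hairpin", start = 101, end = 140, seed = 2)
  m <- BasePairMatrix(as.matrix(caseMatrix(c1)) + as.matrix(caseMatrix(c2)),
                      source = "synthetic")
  segs <- suboptimalSegments(m, "rnabound", params)
  expect_gte(length(segs), 2)
  sc <- S4Vectors::mcols(segs)$score
  expect_true(all(diff(sc) <= 0))
  got <- cbind(IRanges::start(segs), IRanges::end(segs))
  expect_true(any(got[, 1] == 21 & got[, 2] == 60))
  expect_true(any(got[, 1] == 101 & got[, 2] == 140))
  # no overlap
  ov <- IRanges::findOverlaps(segs, segs)
  expect_equal(length(ov), length(segs))  # only self-hits

  # single structure: consistent with the argmax
  one <- suboptimalSegments(caseMatrix(c1), "rnabound", params)
  top <- predictedBoundaries(findBoundaries(caseMatrix(c1)))
  expect_equal(c(IRanges::start(one)[1], IRanges::end(one)[1]),
               unname(top))

  # all-zero matrix yields nothing
  empty <- suboptimalSegments(BasePairMatrix(matrix(0, 60, 60)), "rnabound")
  expect_equal(length(empty), 0)
})

test_that("the score-transform scope switch changes only the crossing terms", {
  # noise above the null probability so the transform scope matters
  case <- plantStructure(120, "hairpin", start = 31, end = 80, seed = 9,
                         noise_prob = 0.005, noise_density = 0.02)
  a <- findBoundaries(caseMatrix(case), transform = "all")
  b <- findBoundaries(caseMatrix(case), transform = "inside-only")
  # both variants are exposed and both recover a segment here
  expect_equal(predictionStatus(a), "ok")
  expect_equal(predictionStatus(b), "ok")
  S <- scoreMatrix(caseMatrix(case), params)
  P <- as.matrix(caseMatrix(case))
  k <- 31; l <- 80
  fa <- rnaboundFitness(S, k, l, params)
  fb <- rnaboundFitness(S, k, l, params, outside = P)
  expect_true(is.finite(fa) && is.finite(fb))
  expect_false(isTRUE(all.equal(fa, fb)))
})
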