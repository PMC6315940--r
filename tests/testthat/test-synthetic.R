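test_that("generation is bit-reproducible and leaves the RNG alone", {
  a <- plantStructure(150, "hairpin", 41, 90, noise_prob = 0.0004, seed = 7)
  b <- plantStructure(150, "hairpin", 41, 90, noise_prob = 0.0004, seed = 7)
  expect_identical(as.matrix(caseMatrix(a)), as.matrix(caseMatrix(b)))
  set.seed(123); before <- runif(3)
  set.seed(123)
  invisible(suppressWarnings(plantStructure(150, "hairpin", 41, 90,
                                            noise_prob = 0.1, seed = 1)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("a zero-noise case contains exactly its declared planted pairs", {
  case <- plantStructure(150, "hairpin", 41, 90, stem_prob = 0.95,
                         noise_prob = 0, seed = 1)
  got <- bpPairs(caseMatrix(case))
  planted <- casePairs(case)
  planted <- planted[order(planted$i, planted$j), ]
  expect_equal(got$i, planted$i)
  expect_equal(got$j, planted$j)
  expect_equal(got$p, planted$p)
  # planted pairs confined to the domain, stems at the declared probability
  expect_true(all(planted$i >= 41 & planted$j <= 90))
  expect_true(all(planted$p[planted$role == "stem"] == 0.95))
  # every in-domain position carries some in-domain mass
  m <- as.matrix(caseMatrix(case))
  expect_true(all(rowSums(m[41:90, 41:90]) > 0))
  # hairpin-loop constraint: no pair closer than 4 nt
  expect_true(all(planted$j - planted$i >= 4))
})

test_that("sub-null noise is invisible to the score transform", {
  p0 <- nullProb(ScoreParams())
  noisy <- plantStructure(150, "cloverleaf", 31, 120,
                          noise_prob = 0.0004, seed = 11)
  clean <- plantStructure(150, "cloverleaf", 31, 120,
                          noise_prob = 0, seed = 11)
  expect_identical(scoreMatrix(caseMatrix(noisy)), scoreMatrix(caseMatrix(clean)))
  # the noise itself is there, below the ceiling
  d <- as.matrix(caseMatrix(noisy)) - as.matrix(caseMatrix(clean))
  expect_gt(sum(d > 0), 0)
  expect_lte(max(d), 0.0004)
})

test_that("impossible geometries are parameter errors", {
  expect_error(plantStructure(50, "hairpin", 10, 14, seed = 1), "hairpin")
  expect_error(plantStructure(60, "cloverleaf", 10, 40, seed = 1), "cloverleaf")
  expect_error(plantStructure(40, "double_hairpin", 10, 25, seed = 1),
               "double hairpin")
  expect_error(plantStructure(50, "hairpin", 30, 20, seed = 1), "start < end")
})

test_that("row mass stays valid after planting and noise injection", {
  for (s in 1:5) {
    # heavy noise deliberately overloads some rows; rescaling restores validity
    case <- suppressWarnings(
      plantStructure(120, "double_hairpin", 21, 100,
                     noise_prob = 0.01, noise_density = 0.05, seed = s))
    expect_lte(max(Matrix::rowSums(bpProbs(caseMatrix(case)))), 1 + 1e-9)
  }
})

test_that("toy folder handles the no-pair and single-pair cases exactly", {
  expect_equal(sum(as.matrix(toyFold("AAAAA"))), 0)
  # GAAAC: ensemble = {open, (G1 C5)}; p = w / (1 + w)
  w <- exp(1)
  got <- bpPairs(toyFold("GAAAC"))
  expect_equal(nrow(got), 1)
  expect_equal(got$i, 1)
  expect_equal(got$j, 5)
  expect_equal(got$p, w / (1 + w), tolerance = 1e-12)
  # stronger pairing energy raises the probability
  p2 <- bpPairs(toyFold("GAAAC", pair_energy = -3))$p
  expect_gt(p2, got$p)
  expect_error(toyFold("ACGX"), "at least 5")
  expect_error(toyFold("ACGXACG"), "alphabet")
})

test_that("toy folder equals exhaustive structure enumeration", {
  w <- exp(1)
  for (s in 1:10) {
    seq <- randomRNA(sample(8:12, 1), seed = 400 + s)
    got <- as.matrix(toyFold(seq))
    want <- enumFoldProbs(seq, w)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
    expect_lte(max(rowSums(got)), 1 + 1e-12)
  }
})

test_that("alignment mutation respects its rate contracts", {
  # reference carrying canonical planted pairs
  ch <- strsplit(randomRNA(40, seed = 1), "")[[1]]
  pairs <- cbind(c(3, 5, 8), c(30, 25, 20))
  ch[pairs[, 1]] <- c("G", "A", "U")
  ch[pairs[, 2]] <- c("C", "U", "G")
  seq <- paste(ch, collapse = "")
  a0 <- mutateAlignment(seq, pairs, rows = 5, sub_rate = 0, seed = 2)
  expect_equal(length(unique(alignmentRows(a0))), 1)  # all rows identical

  a1 <- mutateAlignment(seq, pairs, rows = 8, sub_rate = 0,
                        compensatory_rate = 1, seed = 3)
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  for (row in alignmentRows(a1)) {
    ch <- strsplit(row, "")[[1]]
    for (t in seq_len(nrow(pairs)))
      expect_true(paste0(ch[pairs[t, 1]], ch[pairs[t, 2]]) %in% canonical)
  }
  # unpaired positions untouched when sub_rate = 0
  unp <- setdiff(1:40, as.vector(pairs))
  ref <- strsplit(seq, "")[[1]]
  for (row in alignmentRows(a1))
    expect_equal(strsplit(row, "")[[1]][unp], ref[unp])
})

test_that("identity decreases with the substitution rate", {
  seq <- randomRNA(120, seed = 6)
  mpis <- vapply(c(0.02, 0.1, 0.3), function(rate) {
    vals <- vapply(1:8, function(s)
      meanPairwiseIdentity(mutateAlignment(seq, cbind(integer(), integer()),
                                           rows = 4, sub_rate = rate,
                                           seed = s)),
      numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mpis) < 0))
})

test_that("planted cases feed the full pipeline end to end", {
  case <- plantStructure(150, "hairpin", 41, 90, noise_prob = 0.0004, seed = 13)
  pred <- findBoundaries(caseMatrix(case), frame = "alignment")
  truth <- caseTruth(case)
  actual <- c(truth[1], truth[2]); attr(actual, "frame") <- "alignment"
  d <- boundaryDifference(actual, pred)
  expect_equal(unname(d), c(0, 0))
})
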