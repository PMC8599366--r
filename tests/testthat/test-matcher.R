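test_that("ncc matches its closed form and degenerate rules", {
  u <- c(1, 2, 3)
  expect_equal(ncc(u, u), 1)
  expect_equal(ncc(u, -u + 10), -1)
  expect_equal(ncc(u, c(2, 4, 7)), nccOracle(u, c(2, 4, 7)),
               tolerance = 1e-12)
  expect_equal(ncc(u, c(5, 5, 5)), 0)     # constant vector rule
  expect_error(ncc(u, c(1, 2)), class = "eus_parameter_error")
  set.seed(20)
  for (k in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(ncc(a, b), nccOracle(a, b), tolerance = 1e-12)
    expect_lte(abs(ncc(a, b)), 1)
  }
})

test_that("match scores decompose into independent per-block NCCs", {
  basis <- smallBasis()
  fa <- extractFeatureVector(randomImage(64, 64, seed = 30), basis)
  fb <- extractFeatureVector(randomImage(64, 64, seed = 31), basis)
  ## self-match: 1.0 everywhere
  self <- matchScore(fa, fa)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_true(all(abs(self$perScale - 1) < 1e-12))
  ## decomposition oracle: independent NCC per block, arithmetic mean
  sb <- scaleBlocks(fa)
  per <- vapply(seq_len(nrow(sb)), function(b) {
    r <- sb$start[b]:sb$end[b]
    nccOracle(featureValues(fa)[r], featureValues(fb)[r])
  }, 0)
  ms <- matchScore(fa, fb)
  expect_equal(ms$perScale, per, tolerance = 1e-12)
  expect_equal(ms$score, mean(per), tolerance = 1e-12)
  ## block-wise vector surgery: equal on block 1, orthogonal-after-centering
  ## elsewhere gives the mean of (1, 0, ...)
  v <- featureValues(fa)
  w <- v
  for (b in 2:nrow(sb)) {
    r <- sb$start[b]:sb$end[b]
    x <- v[r] - mean(v[r])
    y <- rev(x) - x              # orthogonalize against x
    y <- y - sum(y * x) / sum(x * x) * x
    w[r] <- y
  }
  fw <- new("HaarFeatureVector", values = w, indexMap = fa@indexMap,
            scaleBlocks = sb, fingerprint = fa@fingerprint)
  ms2 <- matchScore(fa, fw)
  expect_equal(ms2$perScale[1], 1, tolerance = 1e-12)
  expect_true(all(abs(ms2$perScale[-1]) < 1e-9))
  expect_equal(ms2$score, mean(c(1, rep(0, nrow(sb) - 1))), tolerance = 1e-9)
  ## symmetry
  expect_equal(matchScore(fb, fa)$score, ms$score, tolerance = 1e-12)
  ## fingerprint mismatch is a contract error
  other <- extractFeatureVector(randomImage(64, 64, seed = 32),
                                haarBasisSet(scales = 0:1,
                                             matchSize = c(64L, 64L)))
  expect_error(matchScore(fa, other), class = "eus_contract_error")
})

test_that("whole-vector scoring is available as the alternative reading", {
  basis <- smallBasis()
  fa <- extractFeatureVector(randomImage(64, 64, seed = 33), basis)
  fb <- extractFeatureVector(randomImage(64, 64, seed = 34), basis)
  ms <- matchScore(fa, fb, perScale = FALSE)
  expect_equal(ms$score, nccOracle(featureValues(fa), featureValues(fb)),
               tolerance = 1e-12)
})

test_that("self-matching a dictionary image returns its own pose exactly", {
  dict <- smallDictionary()
  basis <- smallBasis()
  for (k in c(1L, 7L, 16L)) {
    res <- findBestMatch(dict, dictionaryImage(dict, k), basis)
    expect_equal(res@bestIndex, k)
    expect_equal(res@score, 1, tolerance = 1e-12)
  }
})

test_that("ties break to the lowest dictionary index", {
  dict <- smallDictionary()
  basis <- smallBasis()
  dup <- dict
  dup@vectors[5, ] <- dup@vectors[2, ]      # duplicate entry 2 at index 5
  dup@images[[5]] <- dup@images[[2]]
  res <- findBestMatch(dup, dictionaryImage(dup, 2), basis)
  expect_equal(res@bestIndex, 2L)
})

test_that("findBestMatch equals an exhaustive brute-force search", {
  dict <- smallDictionary()
  basis <- smallBasis()
  target <- addPixelNoise(dictionaryImage(dict, 9), 0.05, seed = 42)
  res <- findBestMatch(dict, target, basis)
  ## oracle: preprocess identically, then loop with the ncc closed form
  tv <- extractFeatureVector(medianFilterImage(target, 5), basis)
  sb <- dict@scaleBlocks
  oracleScores <- vapply(seq_len(length(dict)), function(i) {
    mean(vapply(seq_len(nrow(sb)), function(b) {
      r <- sb$start[b]:sb$end[b]
      nccOracle(dict@vectors[i, r], featureValues(tv)[r])
    }, 0))
  }, 0)
  expect_equal(res@scores, oracleScores, tolerance = 1e-12)
  expect_equal(res@bestIndex, which.max(oracleScores))
  expect_identical(res@ranking, order(-oracleScores))
  ## deterministic total ranking
  res2 <- findBestMatch(dict, target, basis)
  expect_identical(res2@ranking, res@ranking)
})

test_that("scores are invariant under intensity scaling of the target", {
  dict <- smallDictionary()
  basis <- smallBasis()
  target <- dictionaryImage(dict, 3)
  base <- findBestMatch(dict, target, basis)
  scaled <- initialize(target, values = 0.4 * target@values)
  resS <- findBestMatch(dict, scaled, basis)
  expect_equal(resS@scores, base@scores, tolerance = 1e-9)
  ## constant shifts are invisible to the zero-mean template subset
  zm <- haarBasisSet(templates = 1:7, scales = 0:2, matchSize = c(64L, 64L))
  st <- smallStudy()
  dictZ <- buildDictionary(st$field, st$grid, st$probe, st$psf, zm,
                           keepImages = FALSE)
  tgt <- dictionaryImage(dict, 3)
  shifted <- initialize(tgt, values = tgt@values * 0.8 + 20)
  a <- findBestMatch(dictZ, tgt, zm)
  b <- findBestMatch(dictZ, shifted, zm)
  expect_equal(b@scores, a@scores, tolerance = 1e-9)
})

test_that("noisy self-targets recover their pose on the small dictionary", {
  dict <- smallDictionary()
  basis <- smallBasis()
  ok <- 0L
  for (s in 1:20) {
    noisy <- addPixelNoise(dictionaryImage(dict, 5), 0.05, seed = s)
    ok <- ok + (findBestMatch(dict, noisy, basis)@bestIndex == 5L)
  }
  expect_gte(ok, 18L)
})

test_that("match results serialize to JSON", {
  dict <- smallDictionary()
  res <- findBestMatch(dict, dictionaryImage(dict, 1), smallBasis())
  path <- tempfile(fileext = ".json")
  writeMatchResult(res, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$best_index, 1L)
  expect_equal(got$score, 1, tolerance = 1e-12)
  expect_equal(got$best_pose$label, poses(dict)[[1]]@label)
})
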