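test_that("interval membership reflects positional contiguity", {
  p <- c(1, -4, 3, 2, -5, -6)
  expect_true(isInterval(p, c(1, 3, 4)))
  expect_true(isInterval(p, c(2, 3, 4)))
  expect_false(isInterval(p, c(1, 2)))
  expect_true(isInterval(p, 1:6))          # the whole permutation
  expect_true(isInterval(p, 4))            # singletons always
  expect_error(isInterval(p, 7), "1..n")
})

test_that("overlap means intersecting with no containment", {
  expect_true(reversalsOverlap(c(1, 3, 4), c(2, 3, 4)))
  expect_false(reversalsOverlap(c(2, 3, 4, 5), c(2, 3)))   # nested
  expect_false(reversalsOverlap(1, 1))                     # equal sets
  expect_false(reversalsOverlap(1, 4))                     # disjoint
  expect_true(reversalsCommute(1, c(1, 2, 3)))
  expect_false(reversalsCommute(c(1, 2, 3), c(2, 3, 4)))
  # oracle sweep over random set pairs
  set.seed(5)
  for (k in 1:200) {
    a <- sort(sample(8, sample(3, 1)))
    b <- sort(sample(8, sample(3, 1)))
    expect_identical(reversalsOverlap(a, b), oracleOverlap(a, b))
  }
})

test_that("applying a reversal reverses and negates the block", {
  p <- SignedPermutation(c(1, -4, 3, 2, -5, -6))
  q <- applyReversal(p, c(2, 3, 4))
  expect_identical(permElements(q), c(1L, -2L, -3L, 4L, -5L, -6L))
  expect_identical(permElements(applyReversal(q, c(2, 3, 4))), permElements(p))
  expect_identical(permElements(applyReversal(c(-3, 2, 1, -4), 1)),
                   c(-3L, 2L, -1L, -4L))
  expect_error(applyReversal(p, c(1, 2)), "not an interval")
})

test_that("reversal application preserves the magnitude multiset and inverts itself", {
  set.seed(11)
  for (k in 1:50) {
    n <- sample(3:9, 1)
    p <- SignedPermutation(randomSignedPerm(n))
    i <- sample(n, 1); j <- sample(i:n, 1)
    rho <- sort(abs(permElements(p)[i:j]))
    q <- applyReversal(p, rho)
    expect_identical(sort(abs(permElements(q))), seq_len(n))
    expect_identical(permElements(applyReversal(q, rho)), permElements(p))
  }
})

test_that("words fold left to right and validate every step", {
  expect_identical(
    permElements(applyWord(c(-3, 2, 1, -4), list(1, 4, 2, c(1, 2, 3)))),
    1:4)
  expect_identical(permElements(applyWord(c(-3, 2, 1, -4), list())),
                   c(-3L, 2L, 1L, -4L))
  expect_error(applyWord(c(-3, 2, 1, -4), list(1, c(2, 4))), "step 2")
})

test_that("every linear extension of an enumerated trace sorts the Figure-2 permutation", {
  pi0 <- parsePermutation("-7,8,-3,2,6,-5,-1,4")
  tr <- traces(enumerateTraces(pi0, computeSizes = FALSE))[[1]]
  expect_identical(permElements(applyWord(pi0, tr)), 1:8)
  expect_identical(length(traceWord(tr)), 8L)
})

test_that("lexicographic order on reversals is a strict total order", {
  # all nonempty subsets of {1..5}
  subsets <- unlist(lapply(1:31, function(s) {
    list(which(bitwAnd(s, 2^(0:4)) > 0))
  }), recursive = FALSE)
  sorted <- sortReversals(subsets)
  # pairwise comparison against the reference comparator: antisymmetric,
  # transitive and total by construction of a consistent ranking
  for (i in seq_along(sorted)[-1]) {
    expect_identical(oracleLexCmp(sorted[[i - 1]], sorted[[i]]), -1L)
  }
  # spot values: prefix is smaller
  expect_identical(sorted[[which(vapply(sorted, length, 1L) == 5)]], 1:5)
  i23 <- Position(function(s) identical(s, c(2L, 3L)), sorted)
  i234 <- Position(function(s) identical(s, c(2L, 3L, 4L)), sorted)
  i24 <- Position(function(s) identical(s, c(2L, 4L)), sorted)
  expect_true(i23 < i234 && i234 < i24)
})

test_that("the random generator hits the requested distance without hurdles", {
  set.seed(17)
  for (seed in 1:25) {
    n <- sample(6:12, 1)
    d <- sample(0:min(n - 1, 8), 1)
    p <- randomPermutation(n, d, seed = seed)
    expect_identical(reversalDistance(p), d)
    expect_identical(countHurdles(p), 0L)
  }
  expect_identical(permElements(randomPermutation(10, 0, seed = 1)), 1:10)
  # determinism under a fixed seed
  expect_identical(permElements(randomPermutation(15, 12, seed = 99)),
                   permElements(randomPermutation(15, 12, seed = 99)))
  expect_error(randomPermutation(3, 9, seed = 1), "0 <= d")
})
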