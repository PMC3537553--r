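test_that("breakpoint-graph distance reproduces the worked instances", {
  expect_identical(reversalDistance(c(-3, 2, 1, -4)), 4L)
  expect_identical(reversalDistance("-7,8,-3,2,6,-5,-1,4"), 8L)
  expect_identical(reversalDistance(identityPermutation(9)), 0L)
  expect_identical(reversalDistance(c(-1)), 1L)
  # distance to an arbitrary target via relabelling
  expect_identical(reversalDistance(c(1, 2, 3), c(1, 2, 3)), 0L)
  expect_identical(reversalDistance(c(-3, 2, 1, -4), c(-3, 2, 1, -4)), 0L)
  expect_error(reversalDistance(c(1, -2), c(1, 2, 3)), "same number")
})

test_that("the identity has n+1 trivial cycles and nothing else", {
  bg <- breakpointGraph(identityPermutation(6))
  expect_identical(bg@nCycles, 7L)
  expect_identical(bg@hurdles, 0L)
  expect_identical(bg@fortress, 0L)
  expect_identical(bg@distance, 0L)
})

test_that("all-positive descending runs contain hurdles", {
  bg <- breakpointGraph(c(3, 2, 1))
  expect_gte(bg@hurdles, 1L)
  # the cycle bound (n+1) - c alone under-counts; search certifies d = 3
  expect_identical(bg@distance, 3L)
  expect_identical(searchDistance(c(3, 2, 1)), 3L)
  expect_gt(bg@distance, (3 + 1) - bg@nCycles)
})

test_that("distance changes by at most one under any reversal", {
  for (p in allSignedPerms(4)) {
    d0 <- reversalDistance(p)
    n <- length(p)
    for (i in 1:n) for (j in i:n) {
      q <- applyReversal(p, sort(abs(p[i:j])))
      expect_lte(abs(reversalDistance(q) - d0), 1)
    }
  }
})

test_that("optimal 1-sequences equal the brute-force distance-decrement set", {
  revs <- optimalOneSequences(c(-3, 2, 1, -4))
  keys <- vapply(revs, function(s) paste(s, collapse = ","), character(1))
  expect_true("1" %in% keys)
  expect_true("1,2,4" %in% keys)
  # full equality against testing every interval directly
  set.seed(23)
  for (k in 1:30) {
    n <- sample(4:8, 1)
    p <- randomSignedPerm(n)
    if (identical(p, seq_len(n))) next
    d0 <- reversalDistance(p)
    expected <- list()
    for (i in 1:n) for (j in i:n) {
      rho <- sort(abs(p[i:j]))
      if (reversalDistance(applyReversal(p, rho)) == d0 - 1)
        expected[[length(expected) + 1]] <- rho
    }
    expected <- sortReversals(expected)
    expect_identical(optimalOneSequences(p), expected)
  }
  expect_identical(optimalOneSequences(c(-1)), list(1L))
  expect_error(optimalOneSequences(identityPermutation(3)), "equals the target")
})

test_that("iterating any optimal 1-sequence reaches the target in exactly d steps", {
  set.seed(31)
  for (k in 1:20) {
    p <- SignedPermutation(randomSignedPerm(sample(4:8, 1)))
    d <- reversalDistance(p)
    cur <- p
    steps <- 0L
    while (reversalDistance(cur) > 0L) {
      ops <- optimalOneSequences(cur)
      cur <- applyReversal(cur, ops[[sample.int(length(ops), 1)]])
      steps <- steps + 1L
      expect_lte(steps, d)
    }
    expect_identical(steps, d)
  }
})

test_that("optimal 1-sequences against a non-identity target use original magnitudes", {
  p <- c(-3, 2, 1, -4)
  tgt <- applyReversal(p, c(2, 3))  # one reversal away
  ops <- optimalOneSequences(p, tgt)
  expect_identical(ops, list(c(2L, 3L)))
})
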