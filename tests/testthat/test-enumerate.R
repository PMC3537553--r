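test_that("the 4-element worked instance has exactly the two known traces", {
  ts <- enumerateTraces(c(-3, 2, 1, -4))
  expect_setequal(traceStrings(ts),
                  c("{1}{1,2,3}{2}{4}", "{1,2,4}{3}|{1,3,4}|{2,3,4}"))
  expect_true(isComplete(ts))
  expect_identical(solutionCount(ts), 28)
  expect_identical(countSolutions(c(-3, 2, 1, -4)), 28)
})

test_that("sorting an already-sorted instance yields the single empty trace", {
  ts <- enumerateTraces(identityPermutation(5))
  expect_identical(traceStrings(ts), "")
  expect_identical(solutionCount(ts), 1)
  expect_identical(countSolutions(identityPermutation(5)), 1)
  bf <- bruteForceTraces(identityPermutation(5))
  expect_identical(traceStrings(bf), "")
  expect_identical(solutionCount(bf), 1)
})

test_that("depth-first enumeration agrees with the brute-force oracle", {
  set.seed(67)
  for (k in 1:30) {
    n <- sample(4:7, 1)
    p <- randomSignedPerm(n)
    ts <- enumerateTraces(p)
    bf <- bruteForceTraces(p, maxDistance = 8L)
    expect_identical(traceStrings(ts), traceStrings(bf))
    # per-trace sizes: linear-extension DP vs direct word counting
    expect_identical(traceSizes(ts), traceSizes(bf))
    # path-count DP vs total enumerated words
    expect_identical(countSolutions(p), solutionCount(bf))
  }
})

test_that("traces are emitted exactly once and every trace is valid", {
  set.seed(71)
  for (k in 1:10) {
    p <- SignedPermutation(randomSignedPerm(sample(5:8, 1)))
    ts <- enumerateTraces(p, computeSizes = FALSE)
    d <- reversalDistance(p)
    expect_identical(anyDuplicated(traceStrings(ts)), 0L)
    for (key in traceStrings(ts)) {
      tr <- parseTrace(key)
      expect_identical(formatTrace(tr), key)        # keys are canonical
      expect_identical(length(traceWord(tr)), d)    # d reversals each
      expect_identical(permElements(applyWord(p, tr)), seq_len(length(p)))
    }
  }
})

test_that("solution conservation holds exhaustively at n <= 4", {
  for (p in allSignedPerms(4)) {
    ts <- enumerateTraces(p)
    expect_identical(solutionCount(ts), countSolutions(p))
  }
})

test_that("enumeration works against arbitrary targets", {
  set.seed(73)
  p <- randomSignedPerm(6)
  t <- randomSignedPerm(6)
  ts <- enumerateTraces(p, t)
  bf <- bruteForceTraces(p, t, maxDistance = 8L)
  expect_identical(traceStrings(ts), traceStrings(bf))
  for (key in head(traceStrings(ts), 3))
    expect_identical(permElements(applyWord(p, parseTrace(key))), t)
})

test_that("the brute-force guard refuses distances beyond its bound", {
  expect_error(bruteForceTraces(c(-3, 2, 1, -4), maxDistance = 3L), "guard")
})
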