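completeKeys <- function(p) traceStrings(enumerateTraces(p, computeSizes = FALSE))

test_that("random-walk sampling stays inside the complete set and converges on small instances", {
  p <- c(-3, 2, 1, -4)
  run <- sampleRA(p, stop = stopAfterIterations(200), seed = 5)
  expect_true(all(traceStrings(run) %in% completeKeys(p)))
  # with 200 draws over 28 words the two traces are found
  expect_setequal(traceStrings(run), completeKeys(p))
  cnt <- samplerCounters(run)
  expect_identical(unname(cnt[["wordsGenerated"]]), 200)
  expect_identical(unname(cnt[["duplicateHits"]]),
                   200 - length(traceStrings(run)))
})

test_that("random-walk sampling on the identity returns the empty trace", {
  run <- sampleRA(identityPermutation(4), stop = stopAfterIterations(10), seed = 1)
  expect_identical(traceStrings(run), "")
})

test_that("sampling is deterministic under a fixed seed", {
  p <- randomPermutation(9, 6, seed = 303)
  r1 <- sampleRA(p, stop = stopAfterIterations(30), seed = 11)
  r2 <- sampleRA(p, stop = stopAfterIterations(30), seed = 11)
  expect_identical(traceStrings(r1), traceStrings(r2))
  s1 <- sampleSWA(p, window = 3, stop = stopAfterIterations(2), seed = 13)
  s2 <- sampleSWA(p, window = 3, stop = stopAfterIterations(2), seed = 13)
  expect_identical(traceStrings(s1), traceStrings(s2))
})

test_that("unlimited DFALT is exactly the complete enumeration", {
  set.seed(79)
  for (k in 1:5) {
    p <- randomSignedPerm(sample(5:7, 1))
    run <- sampleDFALT(p)
    expect_true(isComplete(run))
    expect_identical(traceStrings(run), completeKeys(p))
  }
})

test_that("DFALT truncation obeys the deterministic prefix property", {
  p <- c(-3, 2, 1, -4)
  first <- sampleDFALT(p, stop = stopAfterTraces(1))
  # emission order is depth-first with lexicographic children: the all-
  # commuting trace starting {1} comes first
  expect_identical(traceStrings(first), "{1}{1,2,3}{2}{4}")
  q <- randomPermutation(8, 6, seed = 501)
  all <- sampleDFALT(q)
  prev <- character(0)
  for (k in seq_len(min(10L, length(traceStrings(all))))) {
    now <- traceStrings(sampleDFALT(q, stop = stopAfterTraces(k)))
    expect_identical(length(now), k)
    expect_true(all(prev %in% now))
    prev <- now
  }
  expect_setequal(traceStrings(sampleDFALT(q, stop = stopAfterTraces(1e9))),
                  traceStrings(all))
})

test_that("sliding-window output covers the full set when one window spans the distance", {
  p <- c(-3, 2, 1, -4)
  run <- sampleSWA(p, window = reversalDistance(p),
                   stop = stopAfterIterations(1), seed = 3)
  expect_setequal(traceStrings(run), completeKeys(p))
})

test_that("sliding-window samples are sound and within the complete set", {
  set.seed(83)
  for (k in 1:5) {
    p <- randomPermutation(10, 6, seed = 600 + k)
    ck <- completeKeys(p)
    run <- sampleSWA(p, window = 3, stop = stopAfterIterations(2), seed = k)
    expect_gt(length(traceStrings(run)), 0)
    expect_true(all(traceStrings(run) %in% ck))
    for (key in head(traceStrings(run), 3)) {
      tr <- parseTrace(key)
      expect_identical(length(traceWord(tr)), 6L)
      expect_identical(permElements(applyWord(p, tr)), 1:10)
    }
  }
})

test_that("RA samples of larger instances are members of the complete set", {
  set.seed(89)
  for (k in 1:5) {
    p <- randomPermutation(8, 6, seed = 700 + k)
    run <- sampleRA(p, stop = stopAfterIterations(40), seed = k)
    expect_true(all(traceStrings(run) %in% completeKeys(p)))
  }
})

test_that("max-traces stops a run as soon as the set is large enough", {
  p <- randomPermutation(10, 7, seed = 801)
  run <- sampleRA(p, stop = stopAfterTraces(5), seed = 2)
  expect_identical(length(traceStrings(run)), 5L)
  swa <- sampleSWA(p, window = 4, stop = list(stopAfterTraces(3),
                                              stopAfterIterations(50)), seed = 2)
  expect_gte(length(traceStrings(swa)), 3L)
})

test_that("window sizes outside 1..d are rejected", {
  expect_error(sampleSWA(c(-3, 2, 1, -4), window = 5,
                         stop = stopAfterIterations(1), seed = 1), "window size")
  expect_error(sampleSWA(c(-3, 2, 1, -4), window = 0,
                         stop = stopAfterIterations(1), seed = 1), "window size")
})
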