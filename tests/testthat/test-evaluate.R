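test_that("trace-set summaries count heights and lengths with unit mass", {
  ts <- enumerateTraces(c(-3, 2, 1, -4))
  sh <- summarizeTraces(ts, "height")
  expect_identical(sh$value, c(1, 3))
  expect_identical(sh$count, c(1L, 1L))
  expect_identical(sh$ratio, c(0.5, 0.5))
  expect_identical(attr(sh, "total"), 2L)
  expect_identical(sum(sh$count), length(ts))
  expect_equal(sum(sh$ratio), 1, tolerance = 1e-9)

  sl <- summarizeTraces(ts, "avgLength")
  expect_setequal(attr(sl, "rawValues"), c(1.5, 2.5))
  # binned to nearest integer by default
  expect_identical(sl$value, c(2))
  expect_identical(sl$ratio, 1)
  raw <- summarizeTraces(ts, "avgLength", bin = FALSE)
  expect_identical(raw$value, c(1.5, 2.5))

  single <- enumerateTraces(identityPermutation(3))
  expect_identical(summarizeTraces(single, "height")$ratio, 1)
})

test_that("summaries agree with per-trace statistics computed object by object", {
  p <- randomPermutation(9, 6, seed = 901)
  ts <- enumerateTraces(p, computeSizes = FALSE)
  sh <- summarizeTraces(ts, "height")
  hts <- vapply(traces(ts), traceHeight, integer(1))
  expect_identical(sh$count[match(sort(unique(hts)), sh$value)],
                   as.integer(table(hts)))
  sl <- summarizeTraces(ts, "avgLength", bin = FALSE)
  avgs <- vapply(traces(ts), avgReversalLength, numeric(1))
  expect_equal(sort(unique(avgs)), sl$value, tolerance = 1e-12)
})

test_that("ratio averaging weights permutations equally with implicit zeros", {
  a <- summarizeTraces(enumerateTraces(c(-3, 2, 1, -4)), "height")
  b <- summarizeTraces(enumerateTraces(identityPermutation(4)), "height")
  # a: {1: .5, 3: .5}; b: {0: 1}
  av <- averageRatios(list(a, b))
  expect_identical(av$value, c(0, 1, 3))
  expect_identical(av$ratio, c(0.5, 0.25, 0.25))
  expect_identical(averageRatios(list(a))$ratio, a$ratio)
  same <- averageRatios(list(a, a, a))
  expect_identical(same$ratio, a$ratio)
  expect_error(averageRatios(list(a, summarizeTraces(enumerateTraces(c(-3, 2, 1, -4)),
                                                     "avgLength"))), "mix kinds")
})

test_that("identical distributions give statistic zero; disjoint ones give one", {
  s <- summarizeTraces(enumerateTraces(c(-3, 2, 1, -4)), "height")
  same <- ksCompare(s, s, nSamples = 400, seed = 9)
  expect_identical(same$statistic, 0)
  expect_equal(same$p.value, 1, tolerance = 1e-6)
  pm1 <- data.frame(value = 1, count = 1L, ratio = 1)
  pm2 <- data.frame(value = 7, count = 1L, ratio = 1)
  apart <- ksCompare(pm1, pm2, nSamples = 100, seed = 1)
  expect_identical(apart$statistic, 1)
  expect_lt(apart$p.value, 1e-6)
})

test_that("the reported statistic matches a direct CDF max-gap computation", {
  set.seed(97)
  for (k in 1:10) {
    v1 <- sort(sample(2:9, 4))
    v2 <- sort(sample(2:9, 4))
    d1 <- data.frame(value = v1, count = 1L, ratio = runif(4))
    d2 <- data.frame(value = v2, count = 1L, ratio = runif(4))
    d1$ratio <- d1$ratio / sum(d1$ratio)
    d2$ratio <- d2$ratio / sum(d2$ratio)
    res <- ksCompare(d1, d2, nSamples = 300, seed = k)
    x <- revtraces:::.withSeed(k, revtraces:::.drawFromRatios(d1, 300, "multinomial"))
    y <- revtraces:::.withSeed(k, revtraces:::.drawFromRatios(d2, 300, "multinomial"))
    expect_equal(res$statistic, oracleKsStat(x, y), tolerance = 1e-12)
    expect_true(res$statistic >= 0 && res$statistic <= 1)
    expect_true(res$p.value >= 0 && res$p.value <= 1)
  }
})

test_that("the deterministic proportional fill reproduces the ratios", {
  d <- data.frame(value = c(2, 3, 5), count = 1L, ratio = c(0.5, 0.25, 0.25))
  x <- revtraces:::.drawFromRatios(d, 400, "proportional")
  expect_identical(as.vector(table(x)), c(200L, 100L, 100L))
  res <- ksCompare(d, d, nSamples = 400, method = "proportional")
  expect_identical(res$statistic, 0)
})
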