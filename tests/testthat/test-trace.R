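test_that("equivalent words share one normal form and inequivalent ones do not", {
  a <- normalForm(list(1, c(1, 2, 3), c(2, 3, 4)))
  b <- normalForm(list(c(1, 2, 3), 1, c(2, 3, 4)))
  expect_identical(formatTrace(a), formatTrace(b))
  c3 <- normalForm(list(1, c(2, 3, 4), c(1, 2, 3)))
  expect_false(identical(formatTrace(a), formatTrace(c3)))

  target <- "{1,2,4}{3}|{1,3,4}|{2,3,4}"
  words <- list(
    list(3, c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)),
    list(c(1, 2, 4), 3, c(1, 3, 4), c(2, 3, 4)),
    list(c(1, 2, 4), c(1, 3, 4), 3, c(2, 3, 4)),
    list(c(1, 2, 4), c(1, 3, 4), c(2, 3, 4), 3))
  for (w in words) expect_identical(formatTrace(normalForm(w)), target)

  expect_identical(formatTrace(normalForm(list(c(2, 5)))), "{2,5}")
  expect_identical(formatTrace(normalForm(list())), "")
})

test_that("normal forms satisfy the three subword conditions", {
  set.seed(41)
  for (k in 1:40) {
    m <- sample(2:7, 1)
    word <- lapply(seq_len(m), function(i) sort(sample(8, sample(3, 1))))
    tr <- normalForm(word)
    expect_true(validObject(tr))   # validity encodes the three conditions
  }
})

test_that("height counts subwords; commuting words collapse to height 1", {
  expect_identical(traceHeight(parseTrace("{1,2,4}{3}|{1,3,4}|{2,3,4}")), 3L)
  expect_identical(traceHeight(normalForm(list(1, c(1, 2, 3), 2, 4))), 1L)
  # a chain of pairwise-overlapping reversals keeps its length as height
  chain <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 5))
  expect_identical(traceHeight(normalForm(chain)), 4L)
  expect_identical(traceHeight(normalForm(list())), 0L)
})

test_that("trace size equals the cardinality of the swap-closure class", {
  expect_identical(traceSize(parseTrace("{1,2,4}{3}|{1,3,4}|{2,3,4}")), 4)
  expect_identical(traceSize(normalForm(list(1, c(1, 2, 3), 2, 4))), 24)
  chain <- list(c(1, 2), c(2, 3), c(3, 4))
  expect_identical(traceSize(normalForm(chain)), 1)
  set.seed(43)
  for (k in 1:25) {
    m <- sample(2:6, 1)
    word <- lapply(seq_len(m), function(i) sort(sample(7, sample(3, 1))))
    expect_identical(traceSize(normalForm(word)), length(wordClass(word)) * 1.0)
  }
})

test_that("the poset relation matches the worked example and its extensions restore the trace", {
  po <- tracePoset(parseTrace("{1,2,4}{3}|{1,3}|{3,4}"))
  rels <- apply(po@relation, 1, function(r)
    paste(po@labels[r[1]], po@labels[r[2]], sep = "<"))
  expect_setequal(rels, c("{1,2,4}<{1,3}", "{1,3}<{3,4}", "{1,2,4}<{3,4}"))
  # {3} is incomparable to everything
  i3 <- which(po@labels == "{3}")
  expect_false(any(po@relation == i3))
  # single-subword trace: empty relation
  expect_identical(nrow(tracePoset(normalForm(list(1, 3, 5)))@relation), 0L)
  # size equals the independent linear-extension count of the poset
  set.seed(47)
  for (k in 1:15) {
    m <- sample(2:6, 1)
    word <- lapply(seq_len(m), function(i) sort(sample(7, sample(3, 1))))
    tr <- normalForm(word)
    po <- tracePoset(tr)
    expect_identical(traceSize(tr),
                     oracleLinearExtensions(length(po@labels), po@relation) * 1.0)
  }
})

test_that("width is the maximum antichain and bounds the longest subword", {
  expect_identical(traceWidth(parseTrace("{1,2,4}{3}|{1,3}|{3,4}")), 2L)
  chain <- normalForm(list(c(1, 2), c(2, 3), c(3, 4)))
  expect_identical(traceWidth(chain), 1L)
  set.seed(53)
  for (k in 1:15) {
    m <- sample(2:6, 1)
    word <- lapply(seq_len(m), function(i) sort(sample(7, sample(3, 1))))
    tr <- normalForm(word)
    po <- tracePoset(tr)
    w <- traceWidth(tr)
    expect_identical(w, oracleWidth(length(po@labels), po@relation))
    expect_gte(w, max(lengths(tr@subwords)))
  }
})

test_that("normalization is idempotent on canonical words", {
  set.seed(59)
  for (k in 1:25) {
    m <- sample(2:7, 1)
    word <- lapply(seq_len(m), function(i) sort(sample(8, sample(3, 1))))
    tr <- normalForm(word)
    expect_identical(formatTrace(normalForm(traceWord(tr))), formatTrace(tr))
    expect_identical(formatTrace(parseTrace(formatTrace(tr))), formatTrace(tr))
  }
})

test_that("appending a reversal extends the normal form correctly", {
  empty <- normalForm(list())
  expect_identical(formatTrace(appendReversal(empty, c(2, 3))), "{2,3}")
  base <- normalForm(list(1, c(1, 2, 3)))
  expect_identical(formatTrace(appendReversal(base, c(2, 3, 4))),
                   "{1}{1,2,3}|{2,3,4}")
  # the appended reversal is last only when it closes the rendering
  expect_true(isLastAppended(base, c(2, 3, 4)))
  tr <- parseTrace("{1,2,4}")
  expect_false(isLastAppended(tr, 1))    # {1} precedes {1,2,4} in its subword
  expect_true(isLastAppended(tr, 3))     # {3} sorts after {1,2,4}
})

test_that("combining split words reproduces the full normal form", {
  set.seed(61)
  for (k in 1:20) {
    m <- sample(3:7, 1)
    word <- lapply(seq_len(m), function(i) sort(sample(8, sample(3, 1))))
    cut <- sample(m - 1, 1)
    x <- normalForm(word[seq_len(cut)])
    z <- combineTraces(x, word[(cut + 1):m])
    expect_identical(formatTrace(z), formatTrace(normalForm(word)))
  }
  expect_identical(formatTrace(combineTraces(parseTrace("{1,2}|{2,3}"), list())),
                   "{1,2}|{2,3}")
})

test_that("average reversal length is the mean cardinality", {
  expect_identical(avgReversalLength(parseTrace("{1,2,4}{3}|{1,3,4}|{2,3,4}")), 2.5)
  expect_identical(avgReversalLength(normalForm(list(c(2, 3)))), 2)
  expect_identical(avgReversalLength(parseTrace("{1}{1,2,3}{2}{4}")), 1.5)
  expect_error(avgReversalLength(normalForm(list())), "undefined")
})

test_that("repeated reversals are disambiguated as occurrences", {
  # {1,2} twice, separated by an overlapping reversal: three occurrences,
  # totally ordered, so exactly one word
  w <- list(c(1, 2), c(2, 3), c(1, 2))
  tr <- normalForm(w)
  po <- tracePoset(tr)
  expect_identical(sort(po@labels), sort(c("{1,2}", "{1,2}#2", "{2,3}")))
  expect_identical(traceSize(tr), 1)
})
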