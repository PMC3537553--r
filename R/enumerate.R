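## Complete enumeration of solution traces (depth-first), exact counting of
## optimal solutions, and the brute-force oracle.

#' Enumerate all solution traces of a sorting instance
#'
#' Depth-first traversal of the tree of solution traces. At every node the
#' optimal 1-sequences of the current intermediate permutation are listed
#' in lexicographic order, and a reversal extends the current i-trace only
#' when it is the last reversal of the extended trace (see
#' [isLastAppended()]), so every solution trace is emitted exactly once.
#' Optimal 1-sequence sets are cached per intermediate permutation, so
#' branches meeting at the same permutation share the work.
#'
#' @inheritParams reversalDistance
#' @param computeSizes also compute each trace's size (linear-extension
#'   count); needed by [solutionCount()] on the result.
#' @return A complete [TraceSet-class]. For `perm == target` it contains
#'   the single empty trace (one solution: the empty word).
#' @examples
#' ts <- enumerateTraces(c(-3, 2, 1, -4))
#' traceStrings(ts)   # the two solution traces
#' solutionCount(ts)  # 28
#' @export
setGeneric("enumerateTraces", function(perm, target = NULL, computeSizes = TRUE)
  standardGeneric("enumerateTraces"))

#' @rdname enumerateTraces
setMethod("enumerateTraces", "SignedPermutation",
          function(perm, target = NULL, computeSizes = TRUE) {
  target <- .targetOf(perm, target)
  res <- cpp_dfa(perm@elements, target@elements, -1, -1)
  keys <- res$traces
  sizes <- if (computeSizes)
    vapply(keys, function(k) cpp_linext_count(traceWord(parseTrace(k))),
           numeric(1), USE.NAMES = FALSE)
  else NULL
  .newTraceSet(perm, target, keys, sizes, complete = TRUE)
})

#' @rdname enumerateTraces
setMethod("enumerateTraces", "ANY", function(perm, target = NULL, computeSizes = TRUE)
  enumerateTraces(.asPerm(perm), target, computeSizes))

#' Count the optimal sorting scenarios of an instance
#'
#' The number of distinct optimal words sorting `perm` into `target`,
#' computed by dynamic programming on the DAG whose vertices are the
#' distinct intermediate permutations reachable by optimal 1-sequences and
#' whose edge multiplicities are path counts. This route is independent of
#' the trace enumeration, so the identity `countSolutions(p) ==
#' solutionCount(enumerateTraces(p))` is a meaningful cross-check rather
#' than a tautology.
#'
#' @inheritParams reversalDistance
#' @return Nonnegative number (exact as long as the count stays below
#'   2^53; returned as numeric because solution counts overflow integers
#'   quickly).
#' @examples
#' countSolutions(c(-3, 2, 1, -4))  # 28
#' @export
setGeneric("countSolutions", function(perm, target = NULL)
  standardGeneric("countSolutions"))

#' @rdname countSolutions
setMethod("countSolutions", "SignedPermutation", function(perm, target = NULL) {
  target <- .targetOf(perm, target)
  cpp_count_solutions(perm@elements, target@elements)
})

#' @rdname countSolutions
setMethod("countSolutions", "ANY", function(perm, target = NULL)
  countSolutions(.asPerm(perm), target))

#' Brute-force enumeration of all optimal words, grouped into traces
#'
#' Reference oracle: enumerates every optimal sorting word (no trace
#' pruning at all), normalizes each word, and groups words by their normal
#' form. The per-trace word counts are therefore obtained by direct
#' counting, independent of the linear-extension machinery, and the trace
#' set is obtained independently of the last-reversal pruning of
#' [enumerateTraces()]. Exponential in the distance; guarded.
#'
#' @inheritParams reversalDistance
#' @param maxDistance refuse instances whose distance exceeds this guard.
#' @param maxWords hard cap on enumerated words.
#' @return A complete [TraceSet-class] whose sizes are the directly counted
#'   words per trace; the total word count is `solutionCount()` of the
#'   result.
#' @export
setGeneric("bruteForceTraces",
           function(perm, target = NULL, maxDistance = 7L, maxWords = 2e7)
             standardGeneric("bruteForceTraces"))

#' @rdname bruteForceTraces
setMethod("bruteForceTraces", "SignedPermutation",
          function(perm, target = NULL, maxDistance = 7L, maxWords = 2e7) {
  target <- .targetOf(perm, target)
  res <- cpp_brute_force(perm@elements, target@elements,
                         as.integer(maxDistance), maxWords)
  .newTraceSet(perm, target, res$traces, res$sizes, complete = TRUE)
})

#' @rdname bruteForceTraces
setMethod("bruteForceTraces", "ANY",
          function(perm, target = NULL, maxDistance = 7L, maxWords = 2e7)
  bruteForceTraces(.asPerm(perm), target, maxDistance, maxWords))
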