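#' @useDynLib revtraces, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats ks.test ave
#' @importFrom utils head
NULL

## -------------------------------------------------------------------------
## Reversal helpers (reversals are plain ascending integer vectors; they are
## identified with the set of magnitudes they cover)
## -------------------------------------------------------------------------

#' Coerce and validate a reversal
#'
#' A reversal is identified with the set of element magnitudes it covers and
#' is stored as a strictly ascending vector of positive integers. Whether the
#' set actually forms an interval of a given permutation is a separate
#' question, answered by [isInterval()].
#'
#' @param x numeric vector of positive integers (any order, no duplicates).
#' @return A strictly ascending integer vector.
#' @examples
#' asReversal(c(4, 1, 2))
#' @export
asReversal <- function(x) {
  if (length(x) == 0L) stop("a reversal must be nonempty")
  x <- as.integer(x)
  if (anyNA(x) || any(x < 1L)) stop("reversal elements must be positive integers")
  if (anyDuplicated(x)) stop("reversal elements must be distinct")
  sort(x)
}

.lexKey <- function(set) paste(sprintf("%05d", set), collapse = ",")

#' Sort reversals lexicographically
#'
#' Reversals written as ascending element lists are compared position-wise;
#' when one list is a prefix of the other the shorter one is smaller, so
#' \{2,3\} < \{2,3,4\} < \{2,4\}.
#'
#' @param reversals list of reversals.
#' @return The list sorted in ascending lexicographic order.
#' @export
sortReversals <- function(reversals) {
  reversals <- lapply(reversals, asReversal)
  keys <- vapply(reversals, .lexKey, character(1))
  reversals[order(keys, method = "radix")]
}

## -------------------------------------------------------------------------
## SignedPermutation
## -------------------------------------------------------------------------

#' SignedPermutation class
#'
#' An ordering of the markers 1..n, each carrying a + or - orientation.
#' Signed permutations model the order and strandedness of homologous
#' genomic markers in one genome relative to another. Positions are 1-based.
#'
#' @slot elements integer vector; the multiset of absolute values is exactly
#'   \{1, ..., n\}.
#' @seealso [SignedPermutation()], [parsePermutation()], [applyReversal()]
#' @export
setClass("SignedPermutation", representation(elements = "integer"))

setValidity("SignedPermutation", function(object) {
  e <- object@elements
  n <- length(e)
  if (n < 1L) return("a signed permutation needs at least one element")
  if (anyNA(e) || any(e == 0L)) return("elements must be nonzero integers")
  if (!identical(sort(abs(e)), seq_len(n)))
    return("absolute values must be exactly 1..n, each once")
  TRUE
})

#' Create a signed permutation
#'
#' @param elements vector of nonzero signed integers whose magnitudes are
#'   exactly 1..n.
#' @return A [SignedPermutation-class] object.
#' @examples
#' SignedPermutation(c(-3, 2, 1, -4))
#' @export
SignedPermutation <- function(elements) {
  new("SignedPermutation", elements = as.integer(elements))
}

#' Identity permutation of size n
#'
#' @param n number of elements.
#' @return The identity permutation (+1, +2, ..., +n).
#' @export
identityPermutation <- function(n) SignedPermutation(seq_len(n))

#' @describeIn SignedPermutation-class number of elements
#' @param x a `SignedPermutation`
#' @export
setMethod("length", "SignedPermutation", function(x) length(x@elements))

#' Extract the signed elements of a permutation
#'
#' @param x a [SignedPermutation-class].
#' @return Integer vector of signed elements, 1-based positions.
#' @export
permElements <- function(x) {
  stopifnot(is(x, "SignedPermutation"))
  x@elements
}

setMethod("show", "SignedPermutation", function(object) {
  cat("SignedPermutation (n=", length(object@elements), "): ",
      formatPermutation(object), "\n", sep = "")
})

## internal: accept SignedPermutation / character / numeric
.asPerm <- function(x) {
  if (is(x, "SignedPermutation")) return(x)
  if (is.character(x)) return(parsePermutation(x))
  if (is.numeric(x)) return(SignedPermutation(x))
  stop("cannot interpret object of class ", class(x)[1], " as a signed permutation")
}

.targetOf <- function(perm, target) {
  if (is.null(target)) identityPermutation(length(perm)) else {
    t <- .asPerm(target)
    if (length(t) != length(perm))
      stop("permutation and target must have the same number of elements")
    t
  }
}

## -------------------------------------------------------------------------
## Trace
## -------------------------------------------------------------------------

#' Trace class: an equivalence class of reversal words in normal form
#'
#' Two reversal words are equivalent when one can be obtained from the other
#' by repeatedly swapping adjacent commuting reversals (reversals commute
#' when their magnitude sets do not overlap). A trace is such an equivalence
#' class; it is stored through its unique Cartier-Foata normal form
#' u1 | u2 | ... | um, where
#' \itemize{
#'   \item every pair of reversals inside a subword ui commutes,
#'   \item every reversal of ui (i > 1) overlaps at least one reversal of
#'     the previous subword u(i-1), and
#'   \item each subword is strictly ascending in lexicographic order.
#' }
#' The number m of subwords is the trace's *height*; the number of distinct
#' words the class contains is its *size*.
#'
#' @slot subwords list of subwords; each subword is a list of reversals
#'   (ascending integer vectors). May be empty (the empty trace, which
#'   represents the single empty sorting scenario).
#' @seealso [normalForm()], [traceHeight()], [traceSize()], [tracePoset()]
#' @export
setClass("Trace", representation(subwords = "list"))

setValidity("Trace", function(object) {
  sw <- object@subwords
  for (i in seq_along(sw)) {
    u <- sw[[i]]
    if (length(u) == 0L) return("subwords must be nonempty")
    keys <- vapply(u, .lexKey, character(1))
    if (is.unsorted(keys, strictly = TRUE))
      return("subwords must be strictly ascending in lexicographic order")
    for (a in seq_along(u)) for (b in seq_along(u)) {
      if (a < b && cpp_overlap(u[[a]], u[[b]]))
        return("reversals within a subword must pairwise commute")
    }
    if (i > 1L) {
      prev <- sw[[i - 1L]]
      for (rho in u) {
        ## anchored by a dependent reversal: overlapping, or an earlier
        ## occurrence of the same reversal (dependence is reflexive)
        anchored <- any(vapply(prev, function(th)
          cpp_overlap(th, rho) || identical(th, rho), logical(1)))
        if (!anchored)
          return("every reversal must depend on some reversal of the previous subword")
      }
    }
  }
  TRUE
})

setMethod("show", "Trace", function(object) {
  cat("Trace: ", formatTrace(object),
      " (height ", traceHeight(object),
      ", ", length(unlist(object@subwords, recursive = FALSE)),
      " reversals)\n", sep = "")
})

## -------------------------------------------------------------------------
## TraceSet
## -------------------------------------------------------------------------

#' TraceSet class: a set of solution traces for one sorting instance
#'
#' Holds the traces that sort a start permutation into a target, keyed by
#' their canonical normal-form rendering (see [formatTrace()]). For large
#' sets only the canonical strings and (optionally) the per-trace sizes are
#' stored; [traces()] materializes [Trace-class] objects on demand.
#'
#' @slot start,target the two [SignedPermutation-class]s.
#' @slot keys character vector of canonical renderings, lexicographically
#'   sorted, no duplicates.
#' @slot sizes numeric vector parallel to `keys` (number of words per trace;
#'   `NA` when not computed).
#' @slot complete logical; `TRUE` when the set is known to be the complete
#'   set of solution traces, `FALSE` for partial enumerations.
#' @export
setClass("TraceSet", representation(start = "SignedPermutation",
                                    target = "SignedPermutation",
                                    keys = "character",
                                    sizes = "numeric",
                                    complete = "logical"))

setValidity("TraceSet", function(object) {
  if (anyDuplicated(object@keys)) return("trace keys must be unique")
  if (length(object@sizes) != length(object@keys))
    return("sizes must be parallel to keys")
  TRUE
})

#' @describeIn TraceSet-class number of traces in the set
#' @param x a `TraceSet`
#' @export
setMethod("length", "TraceSet", function(x) length(x@keys))

setMethod("show", "TraceSet", function(object) {
  cat(if (object@complete) "Complete" else "Partial",
      " TraceSet: ", length(object@keys), " trace(s) sorting ",
      formatPermutation(object@start), " into ",
      formatPermutation(object@target), "\n", sep = "")
  if (!all(is.na(object@sizes)))
    cat("  total solutions represented: ",
        format(sum(object@sizes), big.mark = ","), "\n", sep = "")
  for (k in head(object@keys, 5L)) cat("  ", k, "\n", sep = "")
  if (length(object@keys) > 5L) cat("  ...\n")
})

#' Accessors for trace sets
#'
#' `traceStrings` returns the canonical renderings, `traceSizes` the
#' per-trace solution counts (NA when not computed), `traces` the
#' materialized [Trace-class] objects, `isComplete` whether the set is the
#' complete enumeration, and `solutionCount` the total number of sorting
#' scenarios represented (the sum of the trace sizes).
#'
#' @param x a [TraceSet-class] or [SampleRun-class].
#' @return See the individual descriptions.
#' @name traceset-accessors
NULL

#' @rdname traceset-accessors
#' @export
setGeneric("traceStrings", function(x) standardGeneric("traceStrings"))

#' @rdname traceset-accessors
#' @export
setGeneric("traceSizes", function(x) standardGeneric("traceSizes"))

#' @rdname traceset-accessors
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname traceset-accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @rdname traceset-accessors
#' @export
setGeneric("solutionCount", function(x) standardGeneric("solutionCount"))

setMethod("traceStrings", "TraceSet", function(x) x@keys)
setMethod("traceSizes", "TraceSet", function(x) x@sizes)
setMethod("traces", "TraceSet", function(x) lapply(x@keys, parseTrace))
setMethod("isComplete", "TraceSet", function(x) x@complete)
setMethod("solutionCount", "TraceSet", function(x) {
  if (anyNA(x@sizes)) stop("trace sizes were not computed for this set")
  sum(x@sizes)
})

.newTraceSet <- function(start, target, keys, sizes = NULL, complete = FALSE) {
  ord <- order(keys, method = "radix")
  keys <- keys[ord]
  sizes <- if (is.null(sizes)) rep(NA_real_, length(keys)) else sizes[ord]
  new("TraceSet", start = start, target = target, keys = keys,
      sizes = sizes, complete = complete)
}

## -------------------------------------------------------------------------
## StopCriterion and SampleRun
## -------------------------------------------------------------------------

#' StopCriterion class
#'
#' A stopping rule for the partial-enumeration (sampling) algorithms. Three
#' kinds exist: `"max-traces"` (stop once that many distinct traces have
#' been collected), `"max-iterations"` (algorithm-specific unit: words built
#' for the random walker, traces emitted for the depth-first sampler, rounds
#' for the sliding-window sampler), and `"time-limit-seconds"` (wall clock).
#' Several criteria may be combined; the first one satisfied wins. Time
#' limits make runs hardware-dependent, so iteration-based criteria are the
#' reproducible choice.
#'
#' @slot kind one of `"max-traces"`, `"max-iterations"`,
#'   `"time-limit-seconds"`.
#' @slot value positive number.
#' @seealso [stopAfterTraces()], [stopAfterIterations()], [stopAfterSeconds()]
#' @export
setClass("StopCriterion", representation(kind = "character", value = "numeric"))

setValidity("StopCriterion", function(object) {
  if (!object@kind %in% c("max-traces", "max-iterations", "time-limit-seconds"))
    return("unknown stop criterion kind")
  if (length(object@value) != 1L || !is.finite(object@value) || object@value <= 0)
    return("criterion value must be a positive number")
  TRUE
})

#' @rdname StopCriterion-class
#' @param k,s criterion value (positive).
#' @export
stopAfterTraces <- function(k) new("StopCriterion", kind = "max-traces", value = as.numeric(k))

#' @rdname StopCriterion-class
#' @export
stopAfterIterations <- function(k) new("StopCriterion", kind = "max-iterations", value = as.numeric(k))

#' @rdname StopCriterion-class
#' @export
stopAfterSeconds <- function(s) new("StopCriterion", kind = "time-limit-seconds", value = as.numeric(s))

setMethod("show", "StopCriterion", function(object) {
  cat("StopCriterion: ", object@kind, " = ", object@value, "\n", sep = "")
})

.asCriteria <- function(stop) {
  if (is.null(stop)) return(list())
  if (is(stop, "StopCriterion")) return(list(stop))
  if (is.list(stop) && all(vapply(stop, is, logical(1), "StopCriterion"))) return(stop)
  stop("`stop` must be a StopCriterion or a list of them")
}

.criterionValue <- function(criteria, kind) {
  vals <- vapply(Filter(function(c) c@kind == kind, criteria),
                 function(c) c@value, numeric(1))
  if (length(vals) == 0L) Inf else min(vals)
}

#' SampleRun class: the result of one sampling run
#'
#' @slot algorithm `"RA"`, `"DFALT"` or `"SWA"`.
#' @slot seed integer seed used (NA for the deterministic DFALT).
#' @slot criteria list of [StopCriterion-class]s.
#' @slot window window size (SWA only; NA otherwise).
#' @slot traceSet deduplicated [TraceSet-class] of sampled traces.
#' @slot counters named numeric: `wordsGenerated`, `duplicateHits`,
#'   `iterations`, `windowsProcessed` (as applicable).
#' @slot elapsed wall-clock seconds.
#' @export
setClass("SampleRun", representation(algorithm = "character",
                                     seed = "numeric",
                                     criteria = "list",
                                     window = "numeric",
                                     traceSet = "TraceSet",
                                     counters = "numeric",
                                     elapsed = "numeric"))

setMethod("show", "SampleRun", function(object) {
  cat("SampleRun [", object@algorithm, "] ",
      length(object@traceSet@keys), " distinct trace(s), ",
      sprintf("%.2fs", object@elapsed), "\n", sep = "")
  if (length(object@counters))
    cat("  counters: ",
        paste(names(object@counters), object@counters, sep = "=", collapse = ", "),
        "\n", sep = "")
})

#' @rdname traceset-accessors
#' @export
setGeneric("traceSet", function(x) standardGeneric("traceSet"))
setMethod("traceSet", "SampleRun", function(x) x@traceSet)
setMethod("traceStrings", "SampleRun", function(x) x@traceSet@keys)
setMethod("traceSizes", "SampleRun", function(x) x@traceSet@sizes)
setMethod("traces", "SampleRun", function(x) traces(x@traceSet))
setMethod("isComplete", "SampleRun", function(x) x@traceSet@complete)

#' Sampling counters
#' @param x a [SampleRun-class].
#' @return Named numeric vector of run counters.
#' @export
samplerCounters <- function(x) { stopifnot(is(x, "SampleRun")); x@counters }

## -------------------------------------------------------------------------
## BreakpointGraph
## -------------------------------------------------------------------------

#' BreakpointGraph class
#'
#' The breakpoint graph of a signed permutation framed by 0 and n+1. Each
#' element x is split into two points (2x-1, 2x), swapped when x is
#' negative; black edges join points adjacent in the permutation, gray edges
#' join points adjacent in the target. Black and gray edges alternate along
#' disjoint cycles. Gray edges whose endpoints sit at same-parity positions
#' are *oriented*; cycles sharing interleaving gray edges form components.
#' Unoriented nontrivial components that do not separate the remaining
#' unoriented components on the circle are *hurdles*; a permutation whose
#' hurdles are all protected ("super-hurdles"), odd in number, is a
#' *fortress*. The reversal distance is (n+1) - cycles + hurdles + fortress.
#'
#' @slot points framed point sequence (length 2n+2).
#' @slot cycles list; gray-edge indices (1-based, edge g joins values
#'   2(g-1) and 2g-1) per cycle.
#' @slot cycleOriented logical per cycle.
#' @slot grayComponent integer component id per gray edge (1-based).
#' @slot componentOriented,componentTrivial logical per component.
#' @slot hurdleComponents integer ids of hurdle components.
#' @slot hurdles,fortress,nCycles,distance integer summary statistics.
#' @seealso [breakpointGraph()], [reversalDistance()]
#' @export
setClass("BreakpointGraph", representation(points = "integer",
                                           cycles = "list",
                                           cycleOriented = "logical",
                                           grayComponent = "integer",
                                           componentOriented = "logical",
                                           componentTrivial = "logical",
                                           hurdleComponents = "integer",
                                           hurdles = "integer",
                                           fortress = "integer",
                                           nCycles = "integer",
                                           distance = "integer"))

setMethod("show", "BreakpointGraph", function(object) {
  n <- (length(object@points) - 2L) %/% 2L
  cat("BreakpointGraph (n=", n, "): ", object@nCycles, " cycles, ",
      object@hurdles, " hurdle(s), fortress=", object@fortress,
      "; distance ", object@distance, "\n", sep = "")
})

## -------------------------------------------------------------------------
## TracePoset
## -------------------------------------------------------------------------

#' TracePoset class
#'
#' The strict partial order underlying a trace: reversal occurrence a
#' precedes occurrence b exactly when a comes before b in every word of the
#' equivalence class. Occurrences of a repeated reversal are disambiguated
#' by an occurrence index. The number of linear extensions of this poset is
#' the trace size; its maximum antichain is the trace width.
#'
#' @slot labels character labels of the elements of P_T.
#' @slot reversals list of the underlying reversals.
#' @slot relation two-column integer matrix of (smaller, larger) index pairs;
#'   transitively closed.
#' @export
setClass("TracePoset", representation(labels = "character",
                                      reversals = "list",
                                      relation = "matrix"))

setValidity("TracePoset", function(object) {
  r <- object@relation
  if (ncol(r) != 2L) return("relation must have two columns")
  if (nrow(r)) {
    if (any(r[, 1] == r[, 2])) return("relation must be irreflexive")
    key <- paste(r[, 1], r[, 2])
    rev <- paste(r[, 2], r[, 1])
    if (any(key %in% rev)) return("relation must be antisymmetric")
  }
  TRUE
})

setMethod("show", "TracePoset", function(object) {
  cat("TracePoset with ", length(object@labels), " element(s), ",
      nrow(object@relation), " relation(s)\n", sep = "")
  if (nrow(object@relation)) {
    for (i in seq_len(min(nrow(object@relation), 10L)))
      cat("  ", object@labels[object@relation[i, 1]], " < ",
          object@labels[object@relation[i, 2]], "\n", sep = "")
  }
})
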