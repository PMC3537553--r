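## Reversal distance via the Hannenhalli-Pevzner breakpoint graph, and
## enumeration of optimal 1-sequences.

#' Reversal distance between two signed permutations
#'
#' The minimum number of reversals transforming `perm` into `target`
#' (identity by default), computed as (n+1) - cycles + hurdles + fortress on
#' the breakpoint graph of the permutation relabelled so that the target
#' becomes the identity. This is the Hannenhalli-Pevzner formula; see
#' [BreakpointGraph-class] for the graph construction and the hurdle /
#' fortress conventions used.
#'
#' @param perm a [SignedPermutation-class], a permutation string such as
#'   `"-3,2,1,-4"`, or a plain signed integer vector.
#' @param target target permutation of the same size (default identity).
#' @return Nonnegative integer distance.
#' @examples
#' reversalDistance(c(-3, 2, 1, -4))                      # 4
#' reversalDistance("-7,8,-3,2,6,-5,-1,4")                # 8
#' reversalDistance(c(1, 2, 3), c(3, 2, 1))               # distance to a target
#' @export
setGeneric("reversalDistance", function(perm, target = NULL)
  standardGeneric("reversalDistance"))

#' @rdname reversalDistance
setMethod("reversalDistance", "SignedPermutation", function(perm, target = NULL) {
  target <- .targetOf(perm, target)
  r <- cpp_relabel(perm@elements, target@elements)
  unname(cpp_hp_stats(r)[["d"]])
})

#' @rdname reversalDistance
setMethod("reversalDistance", "ANY", function(perm, target = NULL)
  reversalDistance(.asPerm(perm), target))

#' Build the breakpoint graph of a permutation
#'
#' @inheritParams reversalDistance
#' @return A [BreakpointGraph-class] with cycles, per-cycle orientation,
#'   interleaving components, hurdle and fortress classification, and the
#'   derived reversal distance.
#' @examples
#' breakpointGraph(c(3, 2, 1))   # one hurdle
#' @export
setGeneric("breakpointGraph", function(perm, target = NULL)
  standardGeneric("breakpointGraph"))

#' @rdname breakpointGraph
setMethod("breakpointGraph", "SignedPermutation", function(perm, target = NULL) {
  target <- .targetOf(perm, target)
  r <- cpp_relabel(perm@elements, target@elements)
  det <- cpp_hp_detail(r)
  new("BreakpointGraph",
      points = as.integer(det$points),
      cycles = det$cycles,
      cycleOriented = det$cycleOriented,
      grayComponent = as.integer(det$grayComponent) + 1L,
      componentOriented = det$componentOriented,
      componentTrivial = det$componentTrivial,
      hurdleComponents = as.integer(det$hurdleComponents) + 1L,
      hurdles = as.integer(det$hurdles),
      fortress = as.integer(det$fortress),
      nCycles = as.integer(det$nCycles),
      distance = as.integer(det$distance))
})

#' @rdname breakpointGraph
setMethod("breakpointGraph", "ANY", function(perm, target = NULL)
  breakpointGraph(.asPerm(perm), target))

#' Number of hurdles of a permutation
#'
#' Convenience wrapper used, among others, by the rejection step of
#' [randomPermutation()].
#'
#' @inheritParams reversalDistance
#' @return Integer hurdle count; `hasHurdles` returns a logical.
#' @export
countHurdles <- function(perm, target = NULL) {
  perm <- .asPerm(perm)
  target <- .targetOf(perm, target)
  r <- cpp_relabel(perm@elements, target@elements)
  unname(cpp_hp_stats(r)[["h"]])
}

#' @rdname countHurdles
#' @export
hasHurdles <- function(perm, target = NULL) countHurdles(perm, target) > 0L

#' Optimal 1-sequences of a permutation
#'
#' An optimal 1-sequence is a reversal that decreases the reversal distance
#' to the target by exactly one; iterating over them spans every optimal
#' sorting scenario. All n(n+1)/2 position intervals are tested with the
#' distance formula.
#'
#' @inheritParams reversalDistance
#' @return List of reversals (ascending integer vectors) in ascending
#'   lexicographic order. Errors when `perm` equals `target`, since no
#'   1-sequence exists at distance zero.
#' @examples
#' optimalOneSequences(c(-3, 2, 1, -4))
#' @export
setGeneric("optimalOneSequences", function(perm, target = NULL)
  standardGeneric("optimalOneSequences"))

#' @rdname optimalOneSequences
setMethod("optimalOneSequences", "SignedPermutation", function(perm, target = NULL) {
  target <- .targetOf(perm, target)
  if (identical(perm@elements, target@elements))
    stop("no optimal 1-sequences exist: the permutation equals the target")
  r <- cpp_relabel(perm@elements, target@elements)
  ij <- cpp_opt1_positions(r)
  revs <- lapply(seq_len(nrow(ij)), function(k)
    sort(abs(perm@elements[ij[k, 1]:ij[k, 2]])))
  sortReversals(revs)
})

#' @rdname optimalOneSequences
setMethod("optimalOneSequences", "ANY", function(perm, target = NULL)
  optimalOneSequences(.asPerm(perm), target))

#' Shortest-path reversal distance by uninformed search
#'
#' Reference oracle that computes the reversal distance as a shortest path
#' in the graph whose vertices are signed permutations and whose edges are
#' single reversals, without using the breakpoint-graph formula. For n <= 7
#' a breadth-first search over the full group from the identity is used
#' (distances to the identity are symmetric); for n of 8..10 a bidirectional
#' breadth-first search is run per query. Exponential: intended for
#' validating the analytic distance at small n, not for production use.
#'
#' @inheritParams reversalDistance
#' @return Nonnegative integer distance.
#' @export
searchDistance <- function(perm, target = NULL) {
  perm <- .asPerm(perm)
  target <- .targetOf(perm, target)
  r <- cpp_relabel(perm@elements, target@elements)
  n <- length(r)
  if (n <= 7L) {
    m <- matrix(r, nrow = 1L)
    storage.mode(m) <- "integer"
    as.integer(cpp_bfs_distances(n, m))
  } else {
    as.integer(cpp_bidir_distance(r))
  }
}
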