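## Signed permutations: intervals, overlap, reversal application, and the
## random hurdle-free permutation generator.

#' Is a set of magnitudes an interval of a permutation?
#'
#' A set rho of magnitudes is an interval of a permutation when the
#' positions its magnitudes occupy are contiguous. Only intervals can be
#' applied as reversals.
#'
#' @param perm a [SignedPermutation-class] (or anything [parsePermutation()]
#'   accepts).
#' @param rho a reversal: vector of distinct magnitudes in 1..n.
#' @return `TRUE` iff the positions of `rho`'s magnitudes are contiguous.
#' @examples
#' isInterval(c(1, -4, 3, 2, -5, -6), c(1, 3, 4))  # TRUE
#' isInterval(c(1, -4, 3, 2, -5, -6), c(1, 2))     # FALSE
#' @export
isInterval <- function(perm, rho) {
  perm <- .asPerm(perm)
  rho <- asReversal(rho)
  n <- length(perm)
  if (any(rho > n)) stop("reversal elements must lie in 1..n")
  pos <- sort(match(rho, abs(perm@elements)))
  identical(pos, pos[1L]:(pos[1L] + length(pos) - 1L))
}

#' Do two intervals overlap?
#'
#' Two intervals overlap when they intersect but neither contains the
#' other. Non-overlapping (disjoint or nested) reversals commute: applying
#' them in either order yields the same permutation, which is the relation
#' that groups sorting scenarios into traces.
#'
#' @param rho1,rho2 reversals (vectors of distinct positive magnitudes).
#' @return logical.
#' @examples
#' reversalsOverlap(c(1, 3, 4), c(2, 3, 4))   # TRUE
#' reversalsOverlap(c(2, 3, 4, 5), c(2, 3))   # FALSE (nested)
#' @export
reversalsOverlap <- function(rho1, rho2) {
  cpp_overlap(asReversal(rho1), asReversal(rho2))
}

#' @rdname reversalsOverlap
#' @details `reversalsCommute` is the negation of `reversalsOverlap`.
#' @export
reversalsCommute <- function(rho1, rho2) !reversalsOverlap(rho1, rho2)

#' Apply a reversal to a permutation
#'
#' Reverses the order and flips the signs of the contiguous block covered by
#' `rho`. Applying the same reversal twice restores the permutation.
#'
#' @inheritParams isInterval
#' @return The resulting [SignedPermutation-class].
#' @examples
#' applyReversal(c(1, -4, 3, 2, -5, -6), c(2, 3, 4))
#' @export
applyReversal <- function(perm, rho) {
  perm <- .asPerm(perm)
  rho <- asReversal(rho)
  if (!isInterval(perm, rho))
    stop("reversal {", paste(rho, collapse = ","), "} is not an interval of ",
         formatPermutation(perm))
  e <- perm@elements
  pos <- sort(match(rho, abs(e)))
  i <- pos[1L]; j <- pos[length(pos)]
  e[i:j] <- -rev(e[i:j])
  SignedPermutation(e)
}

#' Apply a word (ordered sequence of reversals)
#'
#' Left-to-right fold of [applyReversal()]; each reversal must be an
#' interval of the intermediate permutation at its turn.
#'
#' @inheritParams isInterval
#' @param word list of reversals, applied left to right. A [Trace-class] is
#'   also accepted; its canonical word is used (all words of a trace produce
#'   the same result).
#' @return The resulting [SignedPermutation-class].
#' @examples
#' applyWord(c(-3, 2, 1, -4), list(1, 4, 2, c(1, 2, 3)))  # identity
#' @export
applyWord <- function(perm, word) {
  perm <- .asPerm(perm)
  if (is(word, "Trace")) word <- traceWord(word)
  for (k in seq_along(word)) {
    rho <- asReversal(word[[k]])
    if (!isInterval(perm, rho))
      stop("step ", k, ": reversal {", paste(rho, collapse = ","),
           "} is not an interval of ", formatPermutation(perm))
    perm <- applyReversal(perm, rho)
  }
  perm
}

## run code under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a random hurdle-free permutation at a fixed reversal distance
#'
#' Starting from the identity, reversals are applied one at a time until the
#' reversal distance to the identity reaches `d`. While the current
#' permutation has more than one adjacency (a consecutive pair already in
#' target order, frame included), the endpoints of the proposed reversal are
#' drawn at two random adjacencies; otherwise two random positions are used.
#' A proposal is rejected when the resulting permutation drops in distance
#' or contains hurdles, so every returned permutation satisfies
#' `reversalDistance(perm) == d` and has a hurdle-free breakpoint graph.
#' Hurdles are vanishingly rare in random permutations, which is why
#' hurdle-free instances are the natural test bed.
#'
#' @param n number of elements.
#' @param d target reversal distance (0 <= d; unattainable combinations fail
#'   after `maxRejections` rejected proposals per step).
#' @param seed integer seed; the same (n, d, seed) always returns the same
#'   permutation. `NULL` uses the current RNG stream.
#' @param maxRejections rejection cap per step before giving up.
#' @return A [SignedPermutation-class] with reversal distance exactly `d`
#'   and no hurdles.
#' @examples
#' p <- randomPermutation(10, 6, seed = 42)
#' reversalDistance(p)  # 6
#' @export
randomPermutation <- function(n, d, seed = NULL, maxRejections = 10000L) {
  n <- as.integer(n); d <- as.integer(d)
  if (n < 1L) stop("n must be >= 1")
  if (d < 0L || d > n + 1L) stop("d must satisfy 0 <= d <= n+1")
  .withSeed(seed, {
    cur <- seq_len(n)
    dist <- 0L
    while (dist < d) {
      rejected <- 0L
      repeat {
        framed <- c(0L, cur, n + 1L)
        adj <- which(diff(framed) == 1L)  # gap indices 1..n+1 -> gap k-1
        if (length(adj) > 1L) {
          g <- sort(sample(adj, 2L)) - 1L # gaps in 0..n
          i <- g[1L] + 1L; j <- g[2L]
        } else {
          ij <- sort(sample.int(n, 2L, replace = TRUE))
          i <- ij[1L]; j <- ij[2L]
        }
        cand <- cur
        cand[i:j] <- -rev(cand[i:j])
        st <- cpp_hp_stats(cand)
        if (st[["d"]] == dist + 1L && st[["h"]] == 0L) {
          cur <- cand
          dist <- dist + 1L
          break
        }
        rejected <- rejected + 1L
        if (rejected >= maxRejections)
          stop("could not reach distance ", d, " for n = ", n, " after ",
               rejected, " rejected proposals at distance ", dist)
      }
    }
    SignedPermutation(cur)
  })
}
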