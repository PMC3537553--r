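## Trace algebra: Cartier-Foata normal form, height, size (linear-extension
## count), poset, width, average reversal length, appending and combination.

## internal: build a Trace from a word (list of reversals) and its greedy
## Cartier-Foata levels
.traceFromWord <- function(word, levels = NULL) {
  if (length(word) == 0L)
    return(new("Trace", subwords = list()))
  word <- lapply(word, asReversal)
  if (is.null(levels)) levels <- cpp_cf_levels(word)
  m <- max(levels)
  subwords <- vector("list", m)
  for (l in seq_len(m))
    subwords[[l]] <- sortReversals(word[levels == l])
  new("Trace", subwords = subwords)
}

#' Cartier-Foata normal form of a word of reversals
#'
#' Computes the unique normal form of the equivalence class of `word` under
#' swaps of adjacent commuting reversals. Each reversal drops to the
#' earliest subword in which it overlaps some member of the previous
#' subword (level 1 if it overlaps nothing placed before it); subwords are
#' then sorted lexicographically. By the Cartier-Foata theorem the result
#' is independent of which representative word was given.
#'
#' @param word list of reversals (ascending integer vectors), applied left
#'   to right; may be empty. A [Trace-class] is accepted and re-normalized.
#' @return A [Trace-class].
#' @examples
#' normalForm(list(3, c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
#' # same class, different representative:
#' normalForm(list(c(1, 2, 4), 3, c(1, 3, 4), c(2, 3, 4)))
#' @export
normalForm <- function(word) {
  if (is(word, "Trace")) word <- traceWord(word)
  .traceFromWord(word)
}

#' Canonical word of a trace
#'
#' The concatenation of the subwords of the normal form (a valid
#' representative of the class, and the representative used whenever a
#' single word is needed).
#'
#' @param trace a [Trace-class].
#' @return List of reversals.
#' @export
traceWord <- function(trace) {
  stopifnot(is(trace, "Trace"))
  unlist(trace@subwords, recursive = FALSE)
}

#' Render a trace canonically
#'
#' Subwords are joined by `|`; within a subword reversals appear in
#' ascending lexicographic order, each rendered `{e1,e2,...}` with ascending
#' elements and no spaces. This string is the identity of a trace: two
#' traces are equal exactly when their renderings are equal.
#'
#' @param trace a [Trace-class].
#' @return Character scalar (empty string for the empty trace).
#' @examples
#' formatTrace(normalForm(list(3, c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))))
#' @export
formatTrace <- function(trace) {
  stopifnot(is(trace, "Trace"))
  paste(vapply(trace@subwords, function(u)
    paste(vapply(u, function(s)
      paste0("{", paste(s, collapse = ","), "}"), character(1)), collapse = ""),
    character(1)), collapse = "|")
}

#' Parse a canonical trace rendering
#'
#' Accepts the dialect emitted by [formatTrace()]: subwords joined by `|`,
#' reversals as `{e1,e2,...}`. Whitespace is ignored. The parsed word is
#' re-normalized, so any valid rendering of a class member yields the
#' normal form.
#'
#' @param text character scalar.
#' @return A [Trace-class].
#' @examples
#' parseTrace("{1,2,4}{3}|{1,3,4}|{2,3,4}")
#' @export
parseTrace <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (text == "") return(new("Trace", subwords = list()))
  if (!grepl("^[{}0-9,|]+$", text)) stop("malformed trace rendering: ", text)
  word <- list()
  for (sub in strsplit(text, "|", fixed = TRUE)[[1]]) {
    if (sub == "") stop("empty subword in trace rendering: ", text)
    if (!grepl("^(\\{[0-9]+(,[0-9]+)*\\})+$", sub))
      stop("malformed trace rendering: ", text)
    parts <- strsplit(sub, "}", fixed = TRUE)[[1]]
    for (p in parts) {
      els <- strsplit(substring(p, 2L), ",", fixed = TRUE)[[1]]
      word[[length(word) + 1L]] <- asReversal(as.integer(els))
    }
  }
  .traceFromWord(word)
}

#' Height of a trace
#'
#' The number of subwords of the normal form. Height 0 is the empty trace;
#' a chain of pairwise-overlapping reversals has height equal to its
#' length, while a word of pairwise-commuting reversals has height 1.
#'
#' @param trace a [Trace-class] (or a canonical rendering string).
#' @return Nonnegative integer.
#' @export
setGeneric("traceHeight", function(trace) standardGeneric("traceHeight"))

#' @rdname traceHeight
setMethod("traceHeight", "Trace", function(trace) length(trace@subwords))

#' @rdname traceHeight
setMethod("traceHeight", "character", function(trace) traceHeight(parseTrace(trace)))

#' Size of a trace
#'
#' The number of distinct words in the equivalence class, equal to the
#' number of linear extensions of the trace's poset. Computed by dynamic
#' programming over the order ideals (down-sets) of the poset, which is
#' exponential only in the trace width.
#'
#' @inheritParams traceHeight
#' @return Positive number (1 for the empty trace).
#' @examples
#' traceSize(parseTrace("{1,2,4}{3}|{1,3,4}|{2,3,4}"))  # 4
#' @export
setGeneric("traceSize", function(trace) standardGeneric("traceSize"))

#' @rdname traceSize
setMethod("traceSize", "Trace", function(trace) cpp_linext_count(traceWord(trace)))

#' @rdname traceSize
setMethod("traceSize", "character", function(trace) traceSize(parseTrace(trace)))

#' Average reversal length of a trace
#'
#' The arithmetic mean, over the reversals of the trace, of the number of
#' magnitudes each reversal covers. Reversal length carries biological
#' signal: several genomes appear to evolve mainly through short or
#' intermediate reversals, so losing long-reversal traces in a sampling is
#' a relevant bias.
#'
#' @inheritParams traceHeight
#' @return Numeric; errors on the empty trace.
#' @export
setGeneric("avgReversalLength", function(trace) standardGeneric("avgReversalLength"))

#' @rdname avgReversalLength
setMethod("avgReversalLength", "Trace", function(trace) {
  w <- traceWord(trace)
  if (length(w) == 0L) stop("average reversal length is undefined for the empty trace")
  mean(lengths(w))
})

#' @rdname avgReversalLength
setMethod("avgReversalLength", "character", function(trace)
  avgReversalLength(parseTrace(trace)))

#' Poset of a trace
#'
#' Occurrence a precedes occurrence b exactly when a comes before b in
#' every word of the class; this is the transitive closure of the relation
#' "a sits at an earlier subword than b and the two do not commute".
#' Occurrences of a repeated reversal are disambiguated with an occurrence
#' suffix (`#2`, `#3`, ...).
#'
#' @inheritParams traceHeight
#' @return A [TracePoset-class].
#' @export
setGeneric("tracePoset", function(trace) standardGeneric("tracePoset"))

#' @rdname tracePoset
setMethod("tracePoset", "Trace", function(trace) {
  word <- traceWord(trace)
  m <- length(word)
  if (m == 0L)
    return(new("TracePoset", labels = character(0), reversals = list(),
               relation = matrix(integer(0), ncol = 2)))
  levels <- integer(m)
  k <- 0L
  for (l in seq_along(trace@subwords)) {
    nl <- length(trace@subwords[[l]])
    levels[k + seq_len(nl)] <- l
    k <- k + nl
  }
  base <- vapply(word, function(s) paste0("{", paste(s, collapse = ","), "}"),
                 character(1))
  labels <- base
  if (anyDuplicated(base)) {
    occ <- stats::ave(seq_len(m), base, FUN = seq_along)
    labels <- ifelse(occ > 1L, paste0(base, "#", occ), base)
  }
  ## closure: process in level order, accumulate predecessor sets
  preds <- vector("list", m)
  for (i in seq_len(m)) preds[[i]] <- integer(0)
  for (b in seq_len(m)) for (a in seq_len(m)) {
    if (levels[a] < levels[b] &&
        (cpp_overlap(word[[a]], word[[b]]) || identical(word[[a]], word[[b]])))
      preds[[b]] <- union(preds[[b]], c(a, preds[[a]]))
  }
  rel <- do.call(rbind, c(list(matrix(integer(0), ncol = 2)),
                          lapply(seq_len(m), function(b) {
                            if (length(preds[[b]]) == 0L) return(NULL)
                            cbind(sort(preds[[b]]), b)
                          })))
  storage.mode(rel) <- "integer"
  new("TracePoset", labels = labels, reversals = word, relation = rel)
})

#' @rdname tracePoset
setMethod("tracePoset", "character", function(trace) tracePoset(parseTrace(trace)))

#' Width of a trace
#'
#' The size of a maximum antichain of the trace poset (a largest set of
#' pairwise-incomparable reversal occurrences). By Dilworth's theorem this
#' equals the number of elements minus a maximum matching in the bipartite
#' comparability graph, which is how it is computed. The width is at least
#' the maximum subword length but in general not equal to it.
#'
#' @inheritParams traceHeight
#' @return Nonnegative integer (0 for the empty trace).
#' @export
setGeneric("traceWidth", function(trace) standardGeneric("traceWidth"))

#' @rdname traceWidth
setMethod("traceWidth", "Trace", function(trace) {
  po <- tracePoset(trace)
  m <- length(po@labels)
  if (m == 0L) return(0L)
  if (nrow(po@relation) == 0L) return(m)
  succ <- vector("list", m)
  for (r in seq_len(nrow(po@relation)))
    succ[[po@relation[r, 1]]] <- c(succ[[po@relation[r, 1]]], po@relation[r, 2])
  ## minimum chain cover via maximum bipartite matching (Kuhn's algorithm);
  ## max antichain = m - matching by Dilworth/Koenig on the closed relation
  matchR <- integer(m)          # left endpoint matched to each right vertex
  matched <- 0L
  for (a in seq_len(m)) {
    seen <- rep(FALSE, m)
    aug <- function(u) {
      for (b in succ[[u]]) {
        if (!seen[b]) {
          seen[b] <<- TRUE
          if (matchR[b] == 0L || aug(matchR[b])) {
            matchR[b] <<- u
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (aug(a)) matched <- matched + 1L
  }
  as.integer(m - matched)
})

#' @rdname traceWidth
setMethod("traceWidth", "character", function(trace) traceWidth(parseTrace(trace)))

#' Append a reversal to a trace
#'
#' Returns the normal form of (any word of `trace`) followed by `rho`.
#'
#' @param trace a [Trace-class].
#' @param rho a reversal.
#' @return A [Trace-class].
#' @export
appendReversal <- function(trace, rho) {
  stopifnot(is(trace, "Trace"))
  .traceFromWord(c(traceWord(trace), list(asReversal(rho))))
}

#' Is an appended reversal the last reversal of the result?
#'
#' After appending `rho` to `trace`, tests whether `rho` lands in the last
#' subword of the result and is lexicographically last within it. The
#' depth-first enumerator extends a trace by a reversal only when this
#' holds, which guarantees that every trace is generated exactly once (any
#' other extension belongs to a branch rooted elsewhere in the tree).
#'
#' @inheritParams appendReversal
#' @return logical.
#' @export
isLastAppended <- function(trace, rho) {
  stopifnot(is(trace, "Trace"))
  rho <- asReversal(rho)
  word <- traceWord(trace)
  levels <- if (length(word)) cpp_cf_levels(word) else integer(0)
  lvl <- 0L
  for (k in seq_along(word))
    if (levels[k] > lvl &&
        (cpp_overlap(word[[k]], rho) || identical(word[[k]], rho)))
      lvl <- levels[k]
  lvl <- lvl + 1L
  key <- .lexKey(rho)
  for (k in seq_along(word)) {
    if (levels[k] > lvl) return(FALSE)
    if (levels[k] == lvl && .lexKey(word[[k]]) > key) return(FALSE)
  }
  TRUE
}

#' Combine two traces (or a trace and a word) into one
#'
#' If `x` represents scenarios transforming pi^0 into pi^k and `y`
#' scenarios transforming pi^k into pi^d, folding the reversals of `y` one
#' by one onto `x` yields the trace of the concatenated scenarios, which
#' transforms pi^0 into pi^d. The caller is responsible for the two parts
#' actually chaining through a common intermediate permutation. This is
#' the combination step of the sliding-window sampler.
#'
#' @param x a [Trace-class].
#' @param y a [Trace-class] or a word (list of reversals).
#' @return A [Trace-class].
#' @export
combineTraces <- function(x, y) {
  stopifnot(is(x, "Trace"))
  wy <- if (is(y, "Trace")) traceWord(y) else lapply(y, asReversal)
  .traceFromWord(c(traceWord(x), wy))
}
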