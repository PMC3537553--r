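## Partial enumeration (sampling) of solution traces: RA (random scenario
## walks), DFALT (stoppable depth-first enumeration) and SWA (sliding-window
## trace combination).

## canonical rendering of a word without building S4 objects (hot path)
.canonKey <- function(word) {
  if (length(word) == 0L) return("")
  lv <- cpp_cf_levels(word)
  subs <- character(max(lv))
  for (l in seq_len(max(lv))) {
    sets <- word[lv == l]
    keys <- vapply(sets, .lexKey, character(1))
    sets <- sets[order(keys, method = "radix")]
    subs[l] <- paste(vapply(sets, function(s)
      paste0("{", paste(s, collapse = ","), "}"), character(1)), collapse = "")
  }
  paste(subs, collapse = "|")
}

## parse a canonical rendering into its canonical word (list of reversals)
.parseWordKey <- function(key) {
  if (key == "") return(list())
  body <- gsub("|", "", key, fixed = TRUE)
  parts <- strsplit(body, "}", fixed = TRUE)[[1]]
  lapply(parts, function(p)
    as.integer(strsplit(substring(p, 2L), ",", fixed = TRUE)[[1]]))
}

.stopHit <- function(criteria, nTraces, iterations, elapsed) {
  nTraces >= .criterionValue(criteria, "max-traces") ||
    iterations >= .criterionValue(criteria, "max-iterations") ||
    elapsed >= .criterionValue(criteria, "time-limit-seconds")
}

## memoized optimal 1-sequence positions for a permutation relative to the
## identity; memo is an environment shared across one sampling run
.opt1Memo <- function(rel, memo) {
  key <- paste(rel, collapse = ",")
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  m <- cpp_opt1_positions(rel)
  memo[[key]] <- m
  m
}

## one uniform random optimal word; returns the word (original magnitudes)
## and the full list of intermediate permutations (original labels)
.drawScenario <- function(orig, rel, d, memo) {
  word <- vector("list", d)
  perms <- vector("list", d + 1L)
  perms[[1L]] <- orig
  for (step in seq_len(d)) {
    ops <- .opt1Memo(rel, memo)
    k <- if (nrow(ops) == 1L) 1L else sample.int(nrow(ops), 1L)
    i <- ops[k, 1L]; j <- ops[k, 2L]
    word[[step]] <- sort(abs(orig[i:j]))
    orig[i:j] <- -rev(orig[i:j])
    rel[i:j] <- -rev(rel[i:j])
    perms[[step + 1L]] <- orig
  }
  list(word = word, perms = perms)
}

#' Random-walk sampling of solution traces (RA)
#'
#' Builds one optimal sorting word at a time by choosing, at each of the d
#' steps, a reversal uniformly at random among the optimal 1-sequences of
#' the current intermediate permutation; the word is normalized and
#' inserted into a deduplicated trace set. Repeats until a stop criterion
#' fires. Simple and memory-light, but biased towards traces of low height
#' and short reversals, which represent more words.
#'
#' @inheritParams reversalDistance
#' @param stop a [StopCriterion-class] or list of them; the first satisfied
#'   wins. Checked between words.
#' @param seed integer seed; same (instance, seed, iteration criteria)
#'   gives identical output.
#' @return A [SampleRun-class].
#' @examples
#' run <- sampleRA(c(-3, 2, 1, -4), stop = stopAfterIterations(50), seed = 1)
#' traceStrings(run)
#' @export
sampleRA <- function(perm, target = NULL, stop = stopAfterIterations(100L),
                     seed = NULL) {
  perm <- .asPerm(perm)
  target <- .targetOf(perm, target)
  criteria <- .asCriteria(stop)
  rel0 <- cpp_relabel(perm@elements, target@elements)
  d <- unname(cpp_hp_stats(rel0)[["d"]])
  memo <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  keys <- character(0)
  words <- 0; dups <- 0
  t0 <- proc.time()[["elapsed"]]
  .withSeed(seed, {
    repeat {
      elapsed <- proc.time()[["elapsed"]] - t0
      if (.stopHit(criteria, length(keys), words, elapsed)) break
      key <- if (d == 0L) "" else
        .canonKey(.drawScenario(perm@elements, rel0, d, memo)$word)
      words <- words + 1
      skey <- paste0("k", key)   # environments reject empty names
      if (is.null(seen[[skey]])) {
        seen[[skey]] <- TRUE
        keys <- c(keys, key)
      } else dups <- dups + 1
      if (d == 0L && words >= 1) break
    }
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  new("SampleRun", algorithm = "RA",
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      criteria = criteria, window = NA_real_,
      traceSet = .newTraceSet(perm, target, keys, complete = FALSE),
      counters = c(wordsGenerated = words, duplicateHits = dups,
                   iterations = words),
      elapsed = elapsed)
}

#' Stoppable depth-first sampling of solution traces (DFALT)
#'
#' Runs the depth-first complete enumerator and interrupts it at the first
#' satisfied stop criterion, checked between trace emissions. With no
#' criterion the output equals [enumerateTraces()] exactly; with a
#' max-traces criterion k the output is the first k traces of the
#' deterministic depth-first emission order, so results for growing k are
#' nested prefixes. The only deterministic sampler of the three.
#'
#' @inheritParams sampleRA
#' @param stop for DFALT, `max-iterations` counts emitted traces and is
#'   therefore synonymous with `max-traces`.
#' @return A [SampleRun-class]; its trace set has `isComplete(x) == TRUE`
#'   when the enumeration finished before any criterion fired.
#' @export
sampleDFALT <- function(perm, target = NULL, stop = NULL) {
  perm <- .asPerm(perm)
  target <- .targetOf(perm, target)
  criteria <- .asCriteria(stop)
  maxT <- min(.criterionValue(criteria, "max-traces"),
              .criterionValue(criteria, "max-iterations"))
  tlim <- .criterionValue(criteria, "time-limit-seconds")
  res <- cpp_dfa(perm@elements, target@elements,
                 if (is.finite(maxT)) maxT else -1,
                 if (is.finite(tlim)) tlim else -1)
  new("SampleRun", algorithm = "DFALT", seed = NA_real_,
      criteria = criteria, window = NA_real_,
      traceSet = .newTraceSet(perm, target, res$traces,
                              complete = isTRUE(res$complete)),
      counters = c(tracesEmitted = length(res$traces),
                   iterations = length(res$traces)),
      elapsed = res$elapsed)
}

#' Sliding-window sampling of solution traces (SWA)
#'
#' Each round draws one random optimal scenario pi^0, pi^1, ..., pi^d (by
#' the same step rule as [sampleRA()]) and then enumerates, with the
#' depth-first enumerator, the complete k-trace sets of a window of size w
#' sliding along the scenario: the prefixes pi^0 -> pi^k (k = 1..w), the
#' full windows pi^i -> pi^(i+w), and the shrinking suffix windows
#' pi^i -> pi^d. Window sets are then chained with [combineTraces()]: the
#' i-traces pi^0 -> pi^i are combined with the window traces
#' pi^i -> pi^min(i+w, d) for i = 1, ..., d-1, so the final set contains
#' every solution trace that passes through the drawn intermediate
#' permutations at the window boundaries. Combined d-traces accumulate in
#' a deduplicated set across rounds.
#'
#' @inheritParams sampleRA
#' @param window window size w, between 1 and the reversal distance.
#'   Larger windows enumerate more per round at a higher cost per round.
#' @param stop `max-iterations` counts rounds. The wall clock is checked
#'   between windows; a round interrupted mid-way still contributes the
#'   complete d-traces it has already combined.
#' @return A [SampleRun-class].
#' @export
sampleSWA <- function(perm, target = NULL, window,
                      stop = stopAfterIterations(10L), seed = NULL) {
  perm <- .asPerm(perm)
  target <- .targetOf(perm, target)
  criteria <- .asCriteria(stop)
  rel0 <- cpp_relabel(perm@elements, target@elements)
  d <- unname(cpp_hp_stats(rel0)[["d"]])
  window <- as.integer(window)
  if (d == 0L) stop("the permutation already equals the target; nothing to sample")
  if (window < 1L || window > d)
    stop("window size must lie between 1 and the reversal distance (", d, ")")
  memo <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  keys <- character(0)
  rounds <- 0; windows <- 0; dups <- 0; combos <- 0
  t0 <- proc.time()[["elapsed"]]
  el <- function() proc.time()[["elapsed"]] - t0
  .withSeed(seed, {
    repeat {
      if (.stopHit(criteria, length(keys), rounds, el())) break
      sc <- .drawScenario(perm@elements, rel0, d, memo)
      path <- sc$perms  # path[[i + 1]] = pi^i
      ## S[[k]]: words of the k-traces pi^0 -> pi^k found so far this round
      S <- vector("list", d)
      names(S) <- as.character(seq_len(d))
      aborted <- FALSE
      windowSet <- function(i, k) {
        ## complete set of (k-i)-trace words transforming pi^i -> pi^k
        res <- cpp_dfa(path[[i + 1L]], path[[k + 1L]], -1, -1)
        windows <<- windows + 1
        lapply(res$traces, .parseWordKey)
      }
      for (k in seq_len(min(window, d))) {
        S[[k]] <- windowSet(0L, k)
        names(S[[k]]) <- vapply(S[[k]], .canonKey, character(1))
        if (.stopHit(criteria, length(keys), rounds, el())) { aborted <- TRUE; break }
      }
      if (!aborted && d > 1L) for (i in seq_len(d - 1L)) {
        tgt <- min(i + window, d)
        if (is.null(S[[i]]) || length(S[[i]]) == 0L) next
        W <- windowSet(i, tgt)
        acc <- S[[tgt]]
        accKeys <- names(acc)
        for (x in S[[i]]) for (y in W) {
          w2 <- c(x, y)
          k2 <- .canonKey(w2)
          combos <- combos + 1
          if (!k2 %in% accKeys) {
            acc[[length(acc) + 1L]] <- w2
            accKeys <- c(accKeys, k2)
          }
        }
        names(acc) <- accKeys
        S[[tgt]] <- acc
        if (.stopHit(criteria, length(keys), rounds, el())) { aborted <- TRUE; break }
      }
      for (k2 in names(S[[d]])) {
        sk2 <- paste0("k", k2)
        if (is.null(seen[[sk2]])) {
          seen[[sk2]] <- TRUE
          keys <- c(keys, k2)
        } else dups <- dups + 1
      }
      rounds <- rounds + 1
      if (aborted) break
    }
  })
  new("SampleRun", algorithm = "SWA",
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      criteria = criteria, window = as.numeric(window),
      traceSet = .newTraceSet(perm, target, keys, complete = FALSE),
      counters = c(rounds = rounds, windowsProcessed = windows,
                   combinations = combos, duplicateHits = dups,
                   iterations = rounds),
      elapsed = el())
}
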