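## Text formats and the batch experiment driver.

#' Parse a signed permutation from text
#'
#' Accepts comma-separated signed decimal integers with optional
#' surrounding parentheses and whitespace, e.g. `"-3,2,1,-4"` or
#' `"(1, 2, 3)"` (ASCII hyphen-minus for signs). Magnitudes must be
#' exactly 1..n.
#'
#' @param text character scalar.
#' @return A [SignedPermutation-class].
#' @examples
#' parsePermutation("-3,2,1,-4")
#' @export
parsePermutation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[()[:space:]]", "", text)
  if (s == "") stop("empty permutation text")
  toks <- strsplit(s, ",", fixed = TRUE)[[1]]
  bad <- which(!grepl("^-?[0-9]+$", toks) | toks %in% c("", "-"))
  if (length(bad))
    stop("malformed token at position ", bad[1], ": '", toks[bad[1]], "'")
  e <- as.integer(toks)
  n <- length(e)
  if (any(e == 0L)) stop("0 is not a valid element")
  a <- abs(e)
  if (anyDuplicated(a))
    stop("duplicate magnitude at position ", which(duplicated(a))[1])
  if (!identical(sort(a), seq_len(n)))
    stop("magnitudes must be exactly 1..", n, " (gap detected)")
  SignedPermutation(e)
}

#' Render a signed permutation as text
#'
#' Inverse of [parsePermutation()]: comma-separated signed integers,
#' hyphen-minus for negative signs, no parentheses.
#'
#' @param perm a [SignedPermutation-class].
#' @return Character scalar.
#' @export
formatPermutation <- function(perm) {
  perm <- .asPerm(perm)
  paste(perm@elements, collapse = ",")
}

#' Read permutations from a text file
#'
#' One permutation per line in the [parsePermutation()] dialect; empty
#' lines and lines starting with `#` are skipped.
#'
#' @param file path.
#' @return List of [SignedPermutation-class]s.
#' @export
readPermutations <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parsePermutation)
}

#' Write / read a trace set as newline-delimited canonical renderings
#'
#' One canonical trace per line (lexicographically sorted), an optional
#' tab-separated size column, and a trailing summary comment
#' `# traces=N solutions=S` (solutions only when sizes are present).
#' `readTraceSet` accepts the same format; `start` and `target` must be
#' resupplied since the file stores only the traces.
#'
#' @param x a [TraceSet-class] or [SampleRun-class].
#' @param file path.
#' @param sizes include the size column (default: when available).
#' @return `writeTraceSet` returns `file` invisibly; `readTraceSet` a
#'   [TraceSet-class].
#' @export
writeTraceSet <- function(x, file, sizes = NULL) {
  ts <- if (is(x, "SampleRun")) traceSet(x) else x
  stopifnot(is(ts, "TraceSet"))
  withSizes <- if (is.null(sizes)) !anyNA(ts@sizes) else isTRUE(sizes)
  lines <- if (withSizes) paste(ts@keys, format(ts@sizes, scientific = FALSE,
                                                trim = TRUE), sep = "\t")
           else ts@keys
  summary <- if (withSizes)
    sprintf("# traces=%d solutions=%s", length(ts@keys),
            format(sum(ts@sizes), scientific = FALSE))
  else sprintf("# traces=%d", length(ts@keys))
  writeLines(c(lines, summary), file)
  invisible(file)
}

#' @rdname writeTraceSet
#' @param start,target the permutations of the instance the file belongs to.
#' @param complete whether the file holds a complete enumeration.
#' @export
readTraceSet <- function(file, start, target = NULL, complete = FALSE) {
  start <- .asPerm(start)
  target <- .targetOf(start, target)
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, character(1), 1L)
  sizes <- if (all(lengths(parts) >= 2L))
    as.numeric(vapply(parts, `[[`, character(1), 2L))
  else NULL
  ## normalize through the parser so any valid rendering maps to canonical
  keys <- vapply(keys, function(k) formatTrace(parseTrace(k)), character(1),
                 USE.NAMES = FALSE)
  .newTraceSet(start, target, keys, sizes, complete = complete)
}

#' Batch experiment driver
#'
#' Generates `count` random hurdle-free permutations at (n, d), runs the
#' requested algorithms on each, and assembles per-permutation
#' distribution summaries plus permutation-averaged ratio distributions
#' for both trace statistics. All randomness flows from `seed` through
#' per-permutation child seeds, so identical calls give identical reports
#' (with iteration-based criteria).
#'
#' @param n,d,count instance size, reversal distance and number of
#'   permutations.
#' @param algorithms subset of `"dfa"` (complete enumeration), `"ra"`,
#'   `"dfalt"`, `"swa"`.
#' @param stop criteria handed to the samplers (see
#'   [StopCriterion-class]).
#' @param window SWA window size; capped at d.
#' @param seed master seed (mandatory).
#' @param outDir optional directory: per-permutation trace files, an
#'   average-ratio TSV per (algorithm, kind), and a JSON metadata file are
#'   written there (requires the jsonlite package).
#' @return List (class `"revtracesBatch"`) with elements `perms`,
#'   `runs` (nested: algorithm, permutation), `summaries` (algorithm ->
#'   kind -> per-permutation list) and `averages` (algorithm -> kind ->
#'   averaged frame).
#' @export
runBatch <- function(n, d, count, algorithms = c("dfa", "dfalt"),
                     stop = stopAfterIterations(50L), window = 4L,
                     seed, outDir = NULL) {
  stopifnot(!missing(seed))
  algorithms <- match.arg(algorithms, c("dfa", "ra", "dfalt", "swa"),
                          several.ok = TRUE)
  if (count == 0L) {
    out <- list(perms = list(), runs = list(), summaries = list(),
                averages = list(), n = n, d = d, seed = seed)
    class(out) <- "revtracesBatch"
    return(out)
  }
  childSeeds <- .withSeed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                                  2L * count), nrow = 2L))
  perms <- lapply(seq_len(count), function(i)
    randomPermutation(n, d, seed = childSeeds[1L, i]))
  kinds <- c("height", "avgLength")
  runs <- list(); summaries <- list(); averages <- list()
  for (alg in algorithms) {
    runs[[alg]] <- lapply(seq_len(count), function(i) {
      p <- perms[[i]]
      s <- childSeeds[2L, i]
      switch(alg,
             dfa = enumerateTraces(p, computeSizes = FALSE),
             ra = sampleRA(p, stop = stop, seed = s),
             dfalt = sampleDFALT(p, stop = stop),
             swa = sampleSWA(p, window = min(window, d), stop = stop, seed = s))
    })
    summaries[[alg]] <- lapply(kinds, function(k)
      lapply(runs[[alg]], summarizeTraces, kind = k))
    names(summaries[[alg]]) <- kinds
    averages[[alg]] <- lapply(summaries[[alg]], averageRatios)
  }
  out <- list(perms = perms, runs = runs, summaries = summaries,
              averages = averages, n = n, d = d, seed = seed)
  class(out) <- "revtracesBatch"
  if (!is.null(outDir)) .writeBatch(out, outDir, algorithms)
  out
}

.writeBatch <- function(batch, outDir, algorithms) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(batch$perms))
    writeLines(formatPermutation(batch$perms[[i]]),
               file.path(outDir, sprintf("perm_%03d.txt", i)))
  for (alg in algorithms) {
    for (i in seq_along(batch$runs[[alg]]))
      writeTraceSet(batch$runs[[alg]][[i]],
                    file.path(outDir, sprintf("%s_perm_%03d.traces", alg, i)))
    for (k in names(batch$averages[[alg]])) {
      av <- batch$averages[[alg]][[k]]
      utils::write.table(av, file.path(outDir, sprintf("%s_%s_avg.tsv", alg, k)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(n = batch$n, d = batch$d, seed = batch$seed,
                 count = length(batch$perms), algorithms = algorithms)
    jsonlite::write_json(meta, file.path(outDir, "batch_meta.json"),
                         auto_unbox = TRUE)
  }
  invisible(outDir)
}
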