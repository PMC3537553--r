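## Sampling-quality statistics: height and average-reversal-length
## distributions of trace sets, permutation-averaged ratios, and the
## Kolmogorov-Smirnov comparison of sampled vs complete distributions.

## per-trace statistics straight from canonical renderings (cheap string
## arithmetic; avoids materializing Trace objects for large sets)
.traceStats <- function(keys) {
  nbrace <- nchar(gsub("[^{]", "", keys))
  ncomma <- nchar(gsub("[^,]", "", keys))
  nbar <- nchar(gsub("[^|]", "", keys))
  height <- ifelse(keys == "", 0L, nbar + 1L)
  avg <- ifelse(nbrace > 0, (ncomma + nbrace) / nbrace, NA_real_)
  data.frame(key = keys, height = height, avgLength = avg,
             stringsAsFactors = FALSE)
}

#' Distribution of a trace statistic over a trace set
#'
#' Counts the traces of a set per value of a statistic -- the trace height
#' or the average reversal length -- and the corresponding ratios
#' (count / total traces). Average reversal lengths are binned to the
#' nearest integer by default, matching the integer length classes used
#' when profiling samplings; the raw values are kept in the
#' `"rawValues"` attribute.
#'
#' @param x a [TraceSet-class] or [SampleRun-class].
#' @param kind `"height"` or `"avgLength"`.
#' @param bin bin average lengths to the nearest integer (ignored for
#'   heights).
#' @return A `data.frame` with columns `value`, `count`, `ratio`, sorted by
#'   value, with attributes `kind`, `total` and `rawValues`. Empty sets
#'   yield an empty frame with `total` 0.
#' @examples
#' summarizeTraces(enumerateTraces(c(-3, 2, 1, -4)), "height")
#' @export
summarizeTraces <- function(x, kind = c("height", "avgLength"), bin = TRUE) {
  kind <- match.arg(kind)
  keys <- traceStrings(if (is(x, "SampleRun")) traceSet(x) else x)
  if (!length(keys)) {
    out <- data.frame(value = numeric(0), count = integer(0), ratio = numeric(0))
    attr(out, "kind") <- kind; attr(out, "total") <- 0L
    attr(out, "rawValues") <- numeric(0)
    return(out)
  }
  st <- .traceStats(keys)
  raw <- if (kind == "height") st$height else st$avgLength
  vals <- if (kind == "avgLength" && bin) round(raw) else raw
  tab <- table(vals)
  out <- data.frame(value = as.numeric(names(tab)),
                    count = as.integer(tab),
                    ratio = as.integer(tab) / length(keys))
  out <- out[order(out$value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  attr(out, "total") <- length(keys)
  attr(out, "rawValues") <- raw
  out
}

#' Permutation-averaged ratio distribution
#'
#' Given one [summarizeTraces()] frame per permutation, averages the
#' ratios per statistic value across permutations (a value missing from a
#' permutation's summary counts as ratio 0 there). Every permutation
#' contributes equally regardless of how many traces it has -- the ratios
#' are formed first, then averaged.
#'
#' @param batch list of summaries of a common kind.
#' @return A `data.frame` with columns `value`, `ratio`, attributes `kind`
#'   and `nPermutations`.
#' @export
averageRatios <- function(batch) {
  if (!length(batch)) stop("empty batch")
  kinds <- unique(vapply(batch, function(s) attr(s, "kind"), character(1)))
  if (length(kinds) != 1L)
    stop("summaries mix kinds: ", paste(kinds, collapse = ", "))
  vals <- sort(unique(unlist(lapply(batch, function(s) s$value))))
  acc <- vapply(vals, function(v) {
    mean(vapply(batch, function(s) {
      i <- match(v, s$value)
      if (is.na(i)) 0 else s$ratio[i]
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(value = vals, ratio = acc)
  attr(out, "kind") <- kinds
  attr(out, "nPermutations") <- length(batch)
  out
}

## draw m values from a discrete ratio distribution
.drawFromRatios <- function(summary, m, method) {
  if (!nrow(summary)) stop("cannot draw from an empty summary")
  p <- summary$ratio / sum(summary$ratio)
  if (method == "multinomial") {
    summary$value[sample.int(nrow(summary), m, replace = TRUE, prob = p)]
  } else {
    ## deterministic proportional fill; remainders to the largest fractions
    n0 <- floor(m * p)
    rem <- m - sum(n0)
    if (rem > 0) {
      frac <- m * p - n0
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      n0[add] <- n0[add] + 1
    }
    rep(summary$value, times = n0)
  }
}

#' Kolmogorov-Smirnov comparison of two ratio distributions
#'
#' Follows the generate-then-test procedure used to judge sampling
#' quality: draws `nSamples` values from each averaged-ratio distribution
#' (seeded multinomial draw by default, deterministic proportional fill as
#' an option) and applies the two-sample Kolmogorov-Smirnov test to the
#' drawn samples. The statistic is the maximum gap between the two
#' empirical CDFs over the pooled support; the p-value is the asymptotic
#' one (the supports are discrete, so exact p-values are unavailable and
#' the p-value is approximate).
#'
#' @param reference,sampled ratio distributions of a common kind
#'   ([averageRatios()] or [summarizeTraces()] output).
#' @param nSamples values drawn per side.
#' @param seed integer seed; both draws are seeded with it, so comparing a
#'   distribution with itself gives statistic 0 exactly.
#' @param method `"multinomial"` (random draw) or `"proportional"`
#'   (deterministic fill).
#' @return List with elements `statistic`, `p.value`, `nSamples`, `kind`.
#' @examples
#' s <- summarizeTraces(enumerateTraces(c(-3, 2, 1, -4)), "height")
#' ksCompare(s, s, nSamples = 500, seed = 1)$statistic  # 0
#' @export
ksCompare <- function(reference, sampled, nSamples = 5000L, seed = NULL,
                      method = c("multinomial", "proportional")) {
  method <- match.arg(method)
  kr <- attr(reference, "kind"); ks <- attr(sampled, "kind")
  if (!is.null(kr) && !is.null(ks) && !identical(kr, ks))
    stop("cannot compare distributions of different kinds (", kr, " vs ", ks, ")")
  if (!nrow(reference) || !nrow(sampled))
    stop("cannot compare empty distributions")
  x <- .withSeed(seed, .drawFromRatios(reference, nSamples, method))
  y <- .withSeed(seed, .drawFromRatios(sampled, nSamples, method))
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value),
       nSamples = nSamples, kind = if (is.null(kr)) ks else kr)
}
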