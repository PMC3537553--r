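# revtraces

Sorting signed permutations by reversals, and compact exploration of the
*space* of optimal sorting scenarios.

When two genomes share n markers, their relative order and strandedness is
a signed permutation π of 1..n. Under the inversion model, a parsimonious
history is a shortest sequence of reversals (each reverses a contiguous
block and flips its signs) transforming π into the identity — but that
shortest sequence is almost never unique, and the number of optimal
scenarios explodes combinatorially. `revtraces` is for researchers in
genome rearrangement / comparative genomics who want the *whole* solution
space, or a principled sample of it, rather than one arbitrary scenario.

The package provides:

* **Reversal distance** by the Hannenhalli–Pevzner breakpoint-graph
  formula d(π) = (n+1) − c + h + f (cycles, hurdles, fortress), with the
  full hurdle/fortress classification, plus uninformed search oracles used
  to validate it.
* **Traces**: optimal scenarios grouped into equivalence classes under
  swapping adjacent commuting reversals (reversals commute when their
  magnitude sets are disjoint or nested), stored as Cartier–Foata normal
  forms `u1|u2|...|um`. Height, size (number of scenarios represented =
  linear extensions of the trace's poset), width, average reversal length.
* **Complete enumeration** of all solution traces (depth-first, each trace
  emitted exactly once) and an **independent exact count** of all optimal
  scenarios by path counting over intermediate permutations.
* **Sampling** for instances too large to enumerate: `sampleRA` (random
  scenario walks), `sampleDFALT` (stoppable deterministic depth-first
  enumeration), `sampleSWA` (sliding-window enumeration with trace
  combination), with composable stop criteria and full seeding.
* **Quality evaluation**: height and average-reversal-length distributions,
  permutation-averaged ratios, and a two-sample Kolmogorov–Smirnov
  comparison of sampled vs complete distributions.

## A worked example

```r
library(revtraces)

p <- parsePermutation("-3,2,1,-4")
reversalDistance(p)
#> [1] 4

ts <- enumerateTraces(p)
ts
#> Complete TraceSet: 2 trace(s) sorting -3,2,1,-4 into 1,2,3,4
#>   total solutions represented: 28
#>   {1,2,4}{3}|{1,3,4}|{2,3,4}
#>   {1}{1,2,3}{2}{4}
```

All 28 optimal 4-step scenarios fall into two traces. The trace
`{1}{1,2,3}{2}{4}` has height 1: its four reversals pairwise commute
(each is a set of marker magnitudes; nested or disjoint sets commute), so
any of the 4! = 24 orders is a valid scenario. The trace
`{1,2,4}{3}|{1,3,4}|{2,3,4}` has height 3 — reversals in later subwords
overlap earlier ones and must follow them — and represents the remaining
4 scenarios:

```r
tr <- parseTrace("{1,2,4}{3}|{1,3,4}|{2,3,4}")
traceHeight(tr); traceSize(tr); avgReversalLength(tr)
#> [1] 3
#> [1] 4
#> [1] 2.5

countSolutions(p)        # independent route: path counting, no traces
#> [1] 28

applyWord(p, tr)         # any linear extension sorts the permutation
#> SignedPermutation (n=4): 1,2,3,4
```

Sampling a larger instance and judging the sample:

```r
q <- randomPermutation(10, 7, seed = 42)   # hurdle-free, d = 7 exactly
complete <- enumerateTraces(q, computeSizes = FALSE)
run <- sampleSWA(q, window = 4, stop = stopAfterIterations(4), seed = 1)
length(traceStrings(run)) / length(complete)   # fraction recovered
ks <- ksCompare(summarizeTraces(complete, "avgLength"),
                summarizeTraces(run, "avgLength"), seed = 1)
ks$statistic
```

A thin command-line front end mirrors the library
(`inst/scripts/revtrace.R`; commands `distance`, `enumerate`, `sample`,
`randperm`, `evaluate`, `batch`):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","revtrace.R", package="revtraces"))')" \
    distance -3,2,1,-4
# 4
```

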