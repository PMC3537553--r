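---
title: "Sorting signed permutations by reversals and sampling solution traces"
author: "revtraces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting signed permutations by reversals and sampling solution traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revtraces)
```

## The model

When two genomes are described by the order and strandedness of n shared
markers, one genome can be written as a signed permutation of 1..n relative
to the other. Under the reversal (inversion) model, evolution proceeds by
operations that reverse a contiguous block of markers and flip their signs.
A parsimonious reconstruction asks for a shortest sequence of reversals
transforming one permutation into the other; its length is the reversal
distance d.

`revtraces` computes d with the Hannenhalli–Pevzner breakpoint-graph
formula

    d = (n + 1) - c + h + f

where c is the number of alternating cycles in the breakpoint graph of the
framed permutation (0, pi, n+1), h the number of hurdles and f the fortress
indicator. The hurdle conventions implemented are stated in
`?BreakpointGraph`: a component of interleaving gray edges is *unoriented*
when none of its gray edges has endpoints at same-parity positions; an
unoriented nontrivial component is a *hurdle* when the other unoriented
components lie inside a single circular gap of its position set (so it does
not separate them); a hurdle is *super* when removing it turns a
non-hurdle into a hurdle; a permutation with an odd number of hurdles, all
super, is a fortress. These conventions are validated in the test suite by
exhaustive agreement with uninformed breadth-first search over the reversal
graph for every signed permutation with n <= 5 and randomized agreement at
n in 6..8, which is the strongest guarantee available without fixing the
conventions axiomatically.

## Solution spaces and traces

A single optimal scenario is rarely unique — an 11-marker permutation used
throughout the package's tests has 6,345,019 optimal scenarios. Reversals
are identified with the set of magnitudes they cover; two reversals
*commute* when their sets are disjoint or nested. Two scenarios that differ
only by swapping adjacent commuting reversals are biologically
indistinguishable in content, and the equivalence classes of this relation
(*traces*) compress the solution space by several orders of magnitude
(the same 11-marker instance has 7,420 traces).

Each trace is stored through its Cartier–Foata normal form u1|...|um:
every reversal drops to the earliest subword in which it depends on
(overlaps) a member of the previous subword, and subwords are sorted
lexicographically. The number of subwords is the *height*; the number of
scenarios a trace represents (its *size*) equals the number of linear
extensions of its commutation poset, computed by dynamic programming over
order ideals — exponential only in the poset width, which stays small for
the instance sizes the package targets.

Two numerical conventions are worth stating because the definitions in the
field leave them open:

* **Equal occurrences are dependent.** If the same reversal occurs twice in
  a word, the two occurrences never commute with each other (the dependence
  relation is reflexive, as in standard trace monoids). Without this
  convention the normal form would not be unique for words with repeated
  letters and linear-extension counts would overcount identical words.
  Optimal scenarios cannot contain two interchangeable equal reversals, so
  the convention only matters for arbitrary words.
* **Lexicographic order with shorter-prefix-first.** Ascending element
  lists are compared position-wise and a proper prefix precedes its
  extensions, so {2,3} < {2,3,4} < {2,4}. All subword orderings, tree
  orderings and file outputs use this order, making every rendering
  canonical and byte-comparable.

## Complete enumeration

`enumerateTraces()` explores the tree of solution traces depth-first. At a
node holding an i-trace t with intermediate permutation pi^i, the optimal
1-sequences of pi^i (reversals that decrease the remaining distance by
exactly one, found by testing all n(n+1)/2 intervals against the distance
formula) are scanned in lexicographic order, and t is extended by a
reversal rho only when rho is the last reversal of the normal form of
t + rho. This guard makes every trace reachable through exactly one path —
the prefixes of its canonical word — so each trace is emitted once without
a global dedup table. Optimal 1-sequence sets are cached per intermediate
permutation.

`countSolutions()` is deliberately a second, independent route: it counts
directed paths on the DAG of distinct intermediate permutations by dynamic
programming and never touches the trace machinery. Equality between the
path count and the sum of trace sizes is therefore a meaningful
cross-check, asserted in the tests for every exhaustively enumerable
instance and for the 11-marker worked instance.

`bruteForceTraces()` keeps a third route alive for testing: it enumerates
every optimal word without pruning and groups words by normal form,
yielding per-trace sizes by direct counting. It is guarded (default
distance <= 7) because the word count grows as the product of optimal
1-sequence counts along scenarios.

## Sampling (partial enumeration)

For permutations whose trace set is out of reach, three samplers produce a
deduplicated subset of it.

* **RA** draws one scenario at a time, choosing uniformly at random among
  the optimal 1-sequences at each step, and normalizes the word. Uniform
  choice is the natural default where the selection rule is otherwise
  unspecified. RA is cheap but biased towards traces representing many
  words — low height, short reversals.
* **DFALT** is the depth-first enumerator with a stop criterion checked
  between emissions. It is deterministic, duplicate-free, and its output
  under a budget of k traces is exactly the first k traces of the
  deterministic emission order, so growing budgets give nested prefixes
  converging to the complete set.
* **SWA** draws a random scenario pi^0..pi^d, enumerates all k-traces of
  windows of size w along it (prefixes pi^0 -> pi^k for k <= w, sliding
  windows pi^i -> pi^(i+w), shrinking suffixes pi^i -> pi^d), and chains
  them with `combineTraces()`: i-traces pi^0 -> pi^i are combined with the
  window set at pi^i for i = 1..d-1. One round recovers every trace passing
  through the drawn window boundaries; a fresh scenario is drawn each round
  so that coverage diversifies across rounds (whether the original design
  reused one scenario is not documented; redrawing is this package's
  choice). Intermediate window sets are discarded at the end of each round;
  only the final d-trace set is kept, bounding memory at the cost of
  re-enumeration across rounds.

Stop criteria are composable (`stopAfterTraces`, `stopAfterIterations`,
`stopAfterSeconds`; first satisfied wins). Wall-clock limits exist for
parity with interactive use but make runs hardware-dependent, so all tests
and reproducible workflows use iteration-based criteria. Time checks
happen between atomic units (one RA word, one DFA emission, one SWA
window), never inside one, so partial traces are never emitted; an SWA
round interrupted between windows still contributes only complete
d-traces.

## Judging sampling quality

Uniform sampling over the trace space is not on offer (the underlying
counting problem is conjectured #P-complete), so quality is judged by
whether a sampler preserves distributions of two cheap, interpretable
statistics: trace height and average reversal length (mean cardinality of
a trace's reversals — relevant because several genomes appear to favour
short or intermediate reversals).

`summarizeTraces()` tabulates a trace set per statistic value (average
lengths binned to the nearest integer by default, raw values retained);
`averageRatios()` averages the per-permutation ratio distributions so each
permutation counts equally regardless of its trace count; `ksCompare()`
draws 5000 values per side from the two averaged distributions and applies
the two-sample Kolmogorov–Smirnov test. The draw is a seeded multinomial
by default; a deterministic proportional fill is available
(`method = "proportional"`) since the generation rule is underspecified in
the field ("respecting the average ratios" admits both readings). The
p-value is asymptotic — the supports are discrete and tied, so exact
p-values do not exist; the statistic itself is the exact empirical-CDF
max-gap and is what the convergence tests assert on.

## The random instance generator

`randomPermutation(n, d, seed)` emulates the standard test bed of the
field: starting from the identity it applies reversals whose endpoints are
drawn at two random adjacencies while more than one adjacency remains
(two random positions otherwise), rejecting any step that fails to
increase the distance by one or that creates hurdles. Hurdle-free
instances are the natural test bed because hurdles are vanishingly rare in
random permutations. A rejection cap (10,000 proposals per step) turns
unattainable (n, d) combinations into a clean error rather than a hang.

What the generator does *not* emulate: real gene orders are not uniform
over hurdle-free permutations at fixed distance — real genomes show length-
biased reversal usage, hotspots and constraint by gene clusters. Passing
tests on generated instances therefore validates the combinatorics and the
samplers' distributional convergence, not any claim about biological
realism of the instances themselves.

## Problem sizes used by the test suite

The suite works at desk scale, chosen so the full run stays in the range
of a few minutes: exhaustive checks over all signed permutations with
n <= 5 (distance formula vs breadth-first search) and n <= 4 (solution
conservation); 200 random permutations with n in {6,7,8} for the distance
oracle; 100 random permutations with n <= 7 for enumeration vs brute
force; and, for the convergence checks, 20 random hurdle-free permutations
with n = 10 and d in {6,7} — a scaled-down analogue of the 500-permutation
(n = 15, d = 12) profiling design, with trace- and round-based budgets in
place of wall-clock limits. On those batches the Kolmogorov–Smirnov
statistic between sampled and complete distributions decreases
monotonically in the budget for DFALT (reaching exactly zero at unlimited
budget) and for SWA across 1, 4 and 8 rounds, for both height and average
reversal length.

## Known limitations

* Linear permutations only; circular permutations and unsigned
  permutations are out of scope.
* Trace enumeration is exponential in practice; complete enumeration is
  realistic up to roughly n = 15 at moderate d, which is exactly why the
  samplers exist.
* No support for biological constraints (e.g. common intervals) during
  enumeration; the depth-first pruning is incompatible with most of them.
* `traceSize()` supports at most 25 reversals per trace (the order-ideal
  bitmask), far beyond what complete enumeration reaches anyway.
* Sampling comes with no uniformity guarantee over the trace space; the
  distributional checks above are the operative quality measure.
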