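Package: revtraces
Title: Sorting Signed Permutations by Reversals and Sampling Solution Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the solution space of the problem of sorting
    signed permutations by reversals under the Hannenhalli-Pevzner model.
    Computes reversal distances through the breakpoint graph (cycles, hurdles,
    fortress), enumerates optimal 1-sequences, and represents sets of optimal
    sorting scenarios compactly as traces (equivalence classes of reversal
    words under commutation) in Cartier-Foata normal form. Provides complete
    depth-first enumeration of solution traces, exact counting of optimal
    solutions, three partial-enumeration (sampling) strategies (random
    scenario walks, count- or time-limited depth-first enumeration, and
    sliding-window trace combination), and tools to compare sampled and
    complete trace sets by their height and average-reversal-length
    distributions, including a Kolmogorov-Smirnov comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
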