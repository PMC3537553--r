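# Independent reference implementations used as oracles. They are written
# naively (set algebra, exhaustive enumeration, rejection filters) and stay
# independent of the code paths they validate.

# overlap by plain set algebra
oracleOverlap <- function(a, b) {
  i <- intersect(a, b)
  length(i) > 0 && !all(a %in% b) && !all(b %in% a)
}

# all signed permutations of size n (2^n * n! of them)
allSignedPerms <- function(n) {
  base <- list(integer(0))
  for (k in seq_len(n)) {
    base <- unlist(lapply(base, function(p) {
      lapply(0:(k - 1), function(at) append(p, k, after = at))
    }), recursive = FALSE)
  }
  out <- list()
  for (p in base) {
    for (s in 0:(2^n - 1)) {
      signs <- ifelse(bitwAnd(s, 2^(0:(n - 1))) > 0, -1L, 1L)
      out[[length(out) + 1L]] <- as.integer(p * signs)
    }
  }
  out
}

# uniform random signed permutation
randomSignedPerm <- function(n) as.integer(sample(n) * sample(c(-1L, 1L), n, TRUE))

# the full equivalence class of a word under adjacent commuting swaps,
# as a set of word strings; also usable as a trace-size oracle
wordClass <- function(word) {
  keyOf <- function(w) paste(vapply(w, function(s) paste(s, collapse = ","),
                                    character(1)), collapse = ";")
  seen <- new.env(parent = emptyenv())
  queue <- list(word)
  assign(keyOf(word), word, envir = seen)
  while (length(queue)) {
    w <- queue[[1]]
    queue <- queue[-1]
    if (length(w) >= 2) for (i in seq_len(length(w) - 1)) {
      if (!oracleOverlap(w[[i]], w[[i + 1]])) {
        w2 <- w
        w2[[i]] <- w[[i + 1]]
        w2[[i + 1]] <- w[[i]]
        k2 <- keyOf(w2)
        if (is.null(seen[[k2]])) {
          assign(k2, w2, envir = seen)
          queue[[length(queue) + 1]] <- w2
        }
      }
    }
  }
  ls(seen)
}

# linear extensions of a relation (2-column index matrix) over m elements,
# counted by filtering all m! permutations
oracleLinearExtensions <- function(m, relation) {
  if (m == 0) return(1)
  perms <- list(integer(0))
  for (k in seq_len(m)) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(0:(k - 1), function(at) append(p, k, after = at))
    }), recursive = FALSE)
  }
  ok <- vapply(perms, function(p) {
    pos <- match(seq_len(m), p)
    all(pos[relation[, 1]] < pos[relation[, 2]])
  }, logical(1))
  sum(ok)
}

# maximum antichain by checking all subsets
oracleWidth <- function(m, relation) {
  if (m == 0) return(0)
  comparable <- matrix(FALSE, m, m)
  if (nrow(relation)) for (r in seq_len(nrow(relation))) {
    comparable[relation[r, 1], relation[r, 2]] <- TRUE
    comparable[relation[r, 2], relation[r, 1]] <- TRUE
  }
  best <- 0
  for (s in 0:(2^m - 1)) {
    idx <- which(bitwAnd(s, 2^(0:(m - 1))) > 0)
    if (length(idx) <= best) next
    good <- TRUE
    if (length(idx) >= 2) {
      pairs <- utils::combn(idx, 2)
      good <- !any(comparable[cbind(pairs[1, ], pairs[2, ])])
    }
    if (good) best <- length(idx)
  }
  best
}

# lexicographic comparison of two ascending sets, prefix-shorter-first;
# returns -1, 0, 1
oracleLexCmp <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  if (length(a) < length(b)) return(-1L)
  if (length(a) > length(b)) return(1L)
  0L
}

# empirical-CDF max-gap two-sample KS statistic
oracleKsStat <- function(x, y) {
  support <- sort(unique(c(x, y)))
  Fx <- vapply(support, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(support, function(v) mean(y <= v), numeric(1))
  max(abs(Fx - Fy))
}
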