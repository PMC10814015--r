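# Independent reference implementations used to certify the fast paths.
# These deliberately use different algorithms from the package internals.

# cycle-size counts of a successor map by iterated composition: composing the
# map with itself ceiling(log2(n)) + 1 times sends every vertex onto its
# component's cycle; the distinct cycles are then walked directly.
successor_cycle_counts <- function(succ) {
  n <- length(succ)
  s <- succ
  for (j in seq_len(ceiling(log2(n)) + 1L)) s <- s[s]
  seen <- logical(n)
  sizes <- integer(0)
  for (v in unique(s)) {
    if (seen[v]) next
    m <- 0L; u <- v
    repeat {
      seen[u] <- TRUE; m <- m + 1L; u <- succ[u]
      if (u == v) break
    }
    sizes <- c(sizes, m)
  }
  tabulate(sizes, nbins = n)[-1L]   # counts for m = 2..n
}

# exhaustive E_beta[T] for the rank-r nonlocal model (tiny n only)
bruteforce_ET <- function(brackets, r, beta, L) {
  n <- nrow(brackets)
  Y <- pnnclass:::enumerate_labels(n, L)
  Tv <- pnnclass:::enum_T(Y, brackets[, r, drop = FALSE])
  w <- exp(beta * (Tv - max(Tv)))
  sum(w * Tv) / sum(w)
}

# random labeled dataset with continuous features (no distance ties a.s.)
random_dataset <- function(n, p = 2, L = 2) {
  list(x = matrix(stats::rnorm(n * p), n, p),
       y = sample.int(L, n, replace = TRUE))
}

# brackets of a random continuous dataset
random_brackets <- function(n, p = 2) {
  nn_brackets(as.matrix(stats::dist(matrix(stats::rnorm(n * p), n, p))))
}
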