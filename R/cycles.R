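#' Count simple cycles in every rank-r neighbor digraph
#'
#' The rank-r neighbor digraph sends each unit to its r-th nearest neighbor,
#' so every vertex has outdegree one (a functional graph) and every weakly
#' connected component contains exactly one simple cycle. This routine walks
#' each digraph once with a visited set and an explicit stack: when a walk
#' reaches an already-visited vertex that lies on the current stack, the stack
#' is popped down to it and the number of elements from that vertex to the
#' stack top (inclusive) is the cycle size. Total work is O(n) per rank.
#'
#' @param brackets Neighbor brackets from \code{\link{nn_brackets}}, or any
#'   integer matrix whose column r is a self-loop-free successor map.
#' @return Integer matrix \code{counts} of dimension \code{(n-1) x (n-1)};
#'   \code{counts[r, m - 1]} is the number of simple cycles of size m
#'   (m = 2, ..., n) in the rank-r digraph. Columns are named by cycle size.
#' @examples
#' br <- nn_brackets(distance_matrix(cbind(c(0, 1, 3))))
#' count_simple_cycles(br)  # rank 1: one mutual pair, so one 2-cycle
#' @export
count_simple_cycles <- function(brackets) {
  brackets <- as.matrix(brackets)
  n <- nrow(brackets)
  R <- ncol(brackets)
  counts <- matrix(0L, R, n - 1L,
                   dimnames = list(r = seq_len(R), m = seq(2L, n)))
  walk <- integer(n)
  for (r in seq_len(R)) {
    succ <- brackets[, r]
    visited <- logical(n)
    for (j in seq_len(n)) {
      if (visited[j]) next
      i <- j
      top <- 0L
      while (!visited[i]) {
        visited[i] <- TRUE
        top <- top + 1L
        walk[top] <- i
        i <- succ[i]
      }
      # pop until the stopping vertex i is on top; if it never appears the
      # walk merged into a previously explored component (no new cycle)
      m <- 1L
      while (top > 0L) {
        if (walk[top] == i) {
          counts[r, m - 1L] <- counts[r, m - 1L] + 1L
          break
        }
        top <- top - 1L
        m <- m + 1L
      }
    }
  }
  counts
}

#' Weakly connected components of a rank-r neighbor digraph
#'
#' Partitions the units into the weakly connected components of the digraph
#' i -> r-th neighbor of i, by union-find over its n edges. Each component
#' contains exactly one simple cycle.
#'
#' @inheritParams insertion_neighborhood
#' @return A list of integer vectors, one sorted vertex set per component,
#'   ordered by smallest member.
#' @export
cycle_components <- function(brackets, r) {
  brackets <- as.matrix(brackets)
  n <- nrow(brackets)
  if (r < 1L || r > ncol(brackets))
    stop("rank r out of range", call. = FALSE)
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  for (i in seq_len(n)) {
    a <- find(i); b <- find(brackets[i, r])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), match(roots, unique(roots))))
}
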