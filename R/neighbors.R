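#' Pairwise Euclidean distance matrix
#'
#' Computes the full symmetric matrix of Euclidean distances between the rows
#' of a numeric feature matrix. This is the proximity notion underlying all
#' neighborhood structures in the package.
#'
#' @param x Numeric matrix (or data frame coercible to one), one row per unit.
#' @return An \code{n x n} numeric matrix with zero diagonal.
#' @examples
#' distance_matrix(cbind(c(0, 1, 3)))
#' @export
distance_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    stop("features must be numeric with no missing values", call. = FALSE)
  if (nrow(x) < 3L)
    stop("need at least 3 units", call. = FALSE)
  as.matrix(stats::dist(x))
}

#' Nearest-neighbor brackets
#'
#' For each unit i, orders the remaining units by increasing distance. Entry
#' (i, r) is the index of unit i's r-th nearest neighbor. Distance ties are
#' broken deterministically in favor of the smaller unit index.
#'
#' @param d Square symmetric distance matrix with zero diagonal.
#' @return Integer matrix of dimension \code{n x (n-1)}; row i is a
#'   permutation of the indices \code{setdiff(1:n, i)}.
#' @examples
#' nn_brackets(distance_matrix(cbind(c(0, 1, 3))))
#' @export
nn_brackets <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n || anyNA(d))
    stop("d must be a complete square distance matrix", call. = FALSE)
  br <- matrix(0L, n, n - 1L)
  idx <- seq_len(n)
  for (i in idx) {
    ord <- order(d[i, ], idx)        # stable: ties -> smaller unit index
    br[i, ] <- ord[ord != i]
  }
  br
}

#' Neighborhood of an inserted query point
#'
#' Determines, for a single query point at given distances from the training
#' units, (a) the index of the query's r-th nearest training unit, and (b) the
#' set of training units that would have the query as their own r-th nearest
#' neighbor once it is inserted. Equidistant training units precede the query
#' in every augmented neighbor list (the query, as the newest unit, loses
#' ties), and ties among training units go to the smaller index.
#'
#' @param d Training distance matrix (\code{n x n}).
#' @param brackets Neighbor brackets from \code{\link{nn_brackets}} (accepted
#'   for interface completeness; the rank profile is computed from \code{d}).
#' @param query_dists Numeric vector of length n: distances from the query to
#'   each training unit.
#' @param r Neighbor rank, \code{1 <= r <= n-1}.
#' @return A list with components \code{query_rth_neighbor} (integer) and
#'   \code{captured_units} (integer vector, possibly empty).
#' @export
insertion_neighborhood <- function(d, brackets, query_dists, r) {
  n <- nrow(d)
  if (length(query_dists) != n || anyNA(query_dists))
    stop("query_dists must have one finite entry per training unit", call. = FALSE)
  if (r < 1L || r > n - 1L)
    stop("rank r out of range", call. = FALSE)
  rho <- unname(insertion_ranks(d, query_dists))
  list(query_rth_neighbor = order(query_dists, seq_len(n))[r],
       captured_units = which(rho == r))
}

# Rank the query would occupy in each training unit's augmented neighbor
# list: rho[i] = 1 + #{j != i : d(i,j) <= qd[i]}. The self column d[i,i] = 0
# always counts, so the two +-1 corrections cancel.
insertion_ranks <- function(d, query_dists) {
  rowSums(d <= query_dists)
}
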