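#' Brute-force oracles for tiny instances
#'
#' These routines certify the closed-form fast path by exhaustive enumeration
#' over all L^n label vectors. They are intentionally exponential-time and
#' refuse instances with more than 2^20 enumeration terms (or n > 14).
#' \code{bruteforce_partition} sums
#' the rank-r nonlocal model's normalizing constant directly;
#' \code{bruteforce_partition_joint} does the same for the joint k-neighbor
#' model, whose exact summation at realistic n is tied to the maximum-cut
#' decision problem and hence believed intractable.
#'
#' @param brackets Neighbor brackets from \code{\link{nn_brackets}}.
#' @param r Neighbor rank (nonlocal model).
#' @param k Neighborhood size (joint model).
#' @param beta Non-negative interaction strength.
#' @param L Number of class labels.
#' @return The partition function value (not its logarithm).
#' @name bruteforce
NULL

# all L^n label vectors as an L^n x n integer matrix, built column by column
enumerate_labels <- function(n, L) {
  total <- L^n
  if (n > 14L || total > 2^20)
    stop("enumeration refused: instance too large for brute force", call. = FALSE)
  idx <- 0:(total - 1)
  Y <- vapply(seq_len(n), function(i) (idx %/% L^(i - 1)) %% L + 1L,
              numeric(total))
  storage.mode(Y) <- "integer"
  Y
}

# T(y) for every enumerated label vector under successor map(s) succ (a
# matrix with one column per rank in use)
enum_T <- function(Y, succ) {
  Tv <- 0L
  for (j in seq_len(ncol(succ)))
    Tv <- Tv + rowSums(Y == Y[, succ[, j], drop = FALSE])
  Tv
}

#' @rdname bruteforce
#' @export
bruteforce_partition <- function(brackets, r, beta, L) {
  n <- nrow(brackets)
  Y <- enumerate_labels(n, L)
  sum(exp(beta * enum_T(Y, brackets[, r, drop = FALSE])))
}

#' @rdname bruteforce
#' @export
bruteforce_partition_joint <- function(brackets, k, beta, L) {
  n <- nrow(brackets)
  Y <- enumerate_labels(n, L)
  sum(exp((beta / k) * enum_T(Y, brackets[, seq_len(k), drop = FALSE])))
}

#' Joint-model instance for the max-cut correspondence
#'
#' Builds the adjacency objects of the joint k-neighbor model on a binary
#' labelling: \code{A} with \code{a_ij = 1} iff j is among i's k nearest
#' neighbors, and the symmetrized weight matrix \code{B = A + t(A)} of the
#' associated undirected graph (weights 0, 1 or 2).
#'
#' @inheritParams bruteforce
#' @return A list with \code{A}, \code{B}, \code{n} and \code{k}.
#' @export
joint_instance <- function(brackets, k) {
  n <- nrow(brackets)
  if (k < 1L || k > n - 1L) stop("k out of range", call. = FALSE)
  A <- matrix(0L, n, n)
  A[cbind(rep(seq_len(n), k), as.vector(brackets[, seq_len(k)]))] <- 1L
  list(A = A, B = A + t(A), n = n, k = k)
}

#' Cut-size identity of the joint model
#'
#' For binary labels y, the joint-model statistic
#' \code{T(y) = sum_i sum_{r<=k} I(y_i = y_of_rth_neighbor)} and the size of
#' the graph cut induced by y (sum of B-weights across the two label groups)
#' satisfy \code{cut_size = sum(B)/2 - T(y)}. Both sides are computed
#' independently and the identity is asserted; it is the package's concrete
#' embodiment of the link between summing the joint normalizing constant and
#' the maximum-cut decision problem.
#'
#' @param instance From \code{\link{joint_instance}}.
#' @param y Binary label vector (two distinct values, e.g. 0/1).
#' @return List with \code{T}, \code{cut_size} and \code{total_weight}.
#' @export
cut_identity <- function(instance, y) {
  if (length(unique(y)) > 2L) stop("binary labels required", call. = FALSE)
  same <- outer(y, y, "==")
  T_y <- sum(instance$A[same])
  cut <- sum(instance$B[!same]) / 2
  if (cut != sum(instance$B) / 2 - T_y)
    stop("cut-size identity violated (internal error)", call. = FALSE)
  list(T = T_y, cut_size = cut, total_weight = sum(instance$B) / 2)
}

#' Polynomial coefficients of the joint partition function
#'
#' Viewing the binary-label joint partition function as the polynomial
#' \code{Z = sum_t d_t z^t} in \code{z = exp(beta/k)}, \code{d_t} counts the
#' label vectors with statistic \code{T(y) = t}.
#' \code{joint_coefficients_enum} obtains the coefficients by exhaustive
#' enumeration; \code{joint_coefficients_interp} recovers them from
#' \code{n*k + 1} evaluations of the polynomial by solving the Vandermonde
#' system in double precision and rounding to integers, mirroring the
#' polynomial-interpolation argument that links partition-function summation
#' to cut counting. Monomial-basis interpolation is severely ill-conditioned,
#' so recovery is reliable only up to degree about 16; a residual check
#' signals an error beyond that.
#'
#' @inheritParams cut_identity
#' @param brackets,k As in \code{\link{joint_instance}}.
#' @param zs Evaluation points: \code{n*k + 1} distinct positive values.
#'   Default: Chebyshev-spaced points on (0, 2).
#' @param Z_fun Function of one argument z returning the polynomial value;
#'   defaults to direct enumeration on the instance.
#' @return Integer vector \code{d} of length \code{n*k + 1} (index t + 1).
#' @export
joint_coefficients_enum <- function(brackets, k) {
  n <- nrow(brackets)
  Y <- enumerate_labels(n, 2L)
  Tv <- enum_T(Y, brackets[, seq_len(k), drop = FALSE])
  tabulate(Tv + 1L, nbins = n * k + 1L)
}

#' @rdname joint_coefficients_enum
#' @export
joint_coefficients_interp <- function(brackets, k, zs = NULL, Z_fun = NULL) {
  n <- nrow(brackets)
  N <- n * k
  if (is.null(zs)) zs <- 1 + cos(pi * (2 * (0:N) + 1) / (2 * (N + 1)))
  if (length(zs) != N + 1L || anyDuplicated(zs) || any(zs <= 0))
    stop("need n*k + 1 distinct positive evaluation points", call. = FALSE)
  if (is.null(Z_fun)) {
    Y <- enumerate_labels(n, 2L)
    Tv <- enum_T(Y, brackets[, seq_len(k), drop = FALSE])
    Z_fun <- function(z) sum(z^Tv)
  }
  V <- outer(zs, 0:N, "^")
  zv <- vapply(zs, Z_fun, numeric(1))
  d <- tryCatch(solve(V, zv), error = function(e)
    stop("Vandermonde system numerically singular", call. = FALSE))
  dr <- round(d)
  if (max(abs(d - dr)) > 0.45 || any(dr < 0) || sum(dr) != 2^n)
    stop("interpolation failed the integer residual check (degree too high)",
         call. = FALSE)
  as.integer(dr)
}

#' Exact sampler for a nonlocal model
#'
#' Draws label vectors from the rank-r nonlocal model by enumerating the
#' probabilities of all L^n outcomes. Supports the parameter-recovery
#' simulations; subject to the same enumeration guard as the other oracles.
#'
#' @inheritParams bruteforce
#' @param size Number of label vectors to draw.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return Integer matrix \code{size x n} of labels in 1..L.
#' @export
sample_nonlocal <- function(brackets, r, beta, L, size, seed = NULL) {
  n <- nrow(brackets)
  Y <- enumerate_labels(n, L)
  w <- exp(beta * (enum_T(Y, brackets[, r, drop = FALSE]) -
                     n))                      # shift for stability
  with_seed(seed, {
    rows <- sample.int(nrow(Y), size, replace = TRUE, prob = w)
    Y[rows, , drop = FALSE]
  })
}
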