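#' Sufficient statistic of the rank-r nonlocal model
#'
#' Counts the training units whose label agrees with the label of their r-th
#' nearest neighbor. This count is the sufficient statistic for the
#' interaction strength of the rank-r nonlocal model.
#'
#' @param labels Integer label vector (values in 1..L).
#' @param brackets Neighbor brackets from \code{\link{nn_brackets}}.
#' @param r Neighbor rank.
#' @return Integer in \code{0:n}.
#' @export
sufficient_statistic <- function(labels, brackets, r) {
  if (r < 1L || r > ncol(brackets))
    stop("rank r out of range", call. = FALSE)
  sum(labels == labels[brackets[, r]])
}

#' Exact log-partition function of a nonlocal model
#'
#' The rank-r nonlocal model places probability proportional to
#' \code{exp(beta * T_r(y))} on each of the L^n label vectors y, where T_r
#' counts units whose label matches their r-th neighbor's. Because the rank-r
#' digraph is a functional graph, its normalizing constant factorizes over
#' weakly connected components: every vertex outside a cycle contributes a
#' factor \code{exp(beta) + L - 1}, and every simple cycle of size m
#' contributes the transfer-matrix trace
#' \code{(exp(beta) + L - 1)^m + (L - 1) * (exp(beta) - 1)^m}.
#' The whole computation needs only the cycle-size counts, and is carried out
#' in log space (log-sum-exp for the two-term cycle factor) so it remains
#' finite for any \code{beta} up to \code{beta_max}.
#'
#' @param beta Non-negative interaction strength.
#' @param L Number of class labels (>= 2).
#' @param n Number of training units.
#' @param counts_r Integer vector of cycle counts for this rank: element
#'   \code{m - 1} is the number of simple cycles of size m (a row of the
#'   matrix returned by \code{\link{count_simple_cycles}}).
#' @return \code{log Z_r(beta)}; equals \code{n * log(L)} at \code{beta = 0}.
#' @examples
#' log_partition(log(2), L = 2, n = 2, counts_r = c(1))  # log(10)
#' @export
log_partition <- function(beta, L, n, counts_r) {
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  if (L < 2L) stop("need at least two class labels", call. = FALSE)
  ms <- which(counts_r > 0L) + 1L
  cs <- counts_r[ms - 1L]
  n_cycle <- sum(ms * cs)
  if (n_cycle > n) stop("cycle counts inconsistent with n", call. = FALSE)
  la <- beta + log1p((L - 1) * exp(-beta))   # log(e^beta + L - 1)
  lb <- beta + log1p(-exp(-beta))            # log(e^beta - 1); -Inf at beta = 0
  cyc <- vapply(seq_along(ms), function(j) {
    u <- ms[j] * la
    v <- log(L - 1) + ms[j] * lb
    u + log1p(exp(v - u))                    # log((.)^m + (L-1)(.)^m), u >= v
  }, numeric(1))
  (n - n_cycle) * la + sum(cs * cyc)
}

#' Log-likelihood of a nonlocal model
#'
#' \code{beta * T_r - log Z_r(beta)}: an exponential family in its natural
#' parameter, hence concave in \code{beta}.
#'
#' @param beta Non-negative interaction strength.
#' @param T_r Sufficient statistic from \code{\link{sufficient_statistic}}.
#' @inheritParams log_partition
#' @return The log-likelihood value.
#' @export
nonlocal_loglik <- function(beta, T_r, L, n, counts_r) {
  beta * T_r - log_partition(beta, L, n, counts_r)
}

#' Maximum-likelihood estimate of a nonlocal interaction strength
#'
#' Maximizes the concave log-likelihood over \code{[0, beta_max]} by bounded
#' scalar search. Because the expected sufficient statistic at \code{beta = 0}
#' is \code{n / L}, the score at the origin is \code{T_r - n / L}: whenever
#' \code{T_r <= n / L} the maximizer is exactly 0 and is returned without a
#' numerical search. When \code{T_r} is at (or near) its maximum the
#' likelihood can increase indefinitely; the estimate is then clipped at
#' \code{beta_max} and flagged.
#'
#' @inheritParams nonlocal_loglik
#' @param beta_max Upper bound for the estimate (default 30; e^30 dominates
#'   any finite-n likelihood).
#' @param tol Convergence tolerance on beta for the scalar search.
#' @return An object of class \code{"nonlocal_fit"}: a list with elements
#'   \code{beta_hat}, \code{T}, \code{log_Z} (log-partition at the estimate),
#'   \code{log_lik}, \code{converged}, and \code{clipped}.
#' @export
fit_beta <- function(T_r, L, n, counts_r, beta_max = 30, tol = 1e-8) {
  if (T_r < 0L || T_r > n) stop("T_r must lie in 0..n", call. = FALSE)
  if (sum(seq(2L, length.out = length(counts_r)) * counts_r) > n)
    stop("cycle counts inconsistent with n", call. = FALSE)
  if (T_r <= n / L) {
    beta_hat <- 0                 # score at 0 is T_r - n/L <= 0
  } else if (T_r >= n) {
    beta_hat <- beta_max          # T at its maximum: likelihood unbounded
  } else {
    opt <- stats::optimize(nonlocal_loglik, c(0, beta_max), maximum = TRUE,
                           tol = tol, T_r = T_r, L = L, n = n,
                           counts_r = counts_r)
    beta_hat <- opt$maximum
  }
  clipped <- beta_hat >= beta_max - 1e-4
  if (clipped) beta_hat <- beta_max
  lz <- log_partition(beta_hat, L, n, counts_r)
  structure(list(beta_hat = beta_hat, T = as.integer(T_r),
                 log_Z = lz, log_lik = beta_hat * T_r - lz,
                 converged = is.finite(lz), clipped = clipped),
            class = "nonlocal_fit")
}

#' @export
print.nonlocal_fit <- function(x, ...) {
  cat(sprintf("Nonlocal model fit: beta_hat = %.6g (T = %d%s)\n",
              x$beta_hat, x$T, if (x$clipped) ", clipped at upper bound" else ""))
  invisible(x)
}
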