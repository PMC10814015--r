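#' Probabilistic nearest neighbors classification
#'
#' Fits the aggregated nonlocal nearest-neighbor label model. For each rank
#' r = 1, ..., k_max a "nonlocal" model couples every training unit to its
#' r-th nearest neighbor only; its normalizing constant is exact and cheap
#' (see \code{\link{log_partition}}), so the interaction strength beta_r is
#' estimated by maximum likelihood. Prediction averages the per-rank
#' predictive distributions over the first k ranks, and k is chosen by
#' leave-one-out cross-validation (LOOCV) on the training sample.
#'
#' By default each beta_r is estimated once on the full training sample and
#' reused across LOOCV folds; \code{refit_loocv = TRUE} switches to the exact
#' (and much slower) variant that rebuilds the whole model without the
#' held-out unit in every fold.
#'
#' @param x Numeric feature matrix (one row per unit), or a formula.
#' @param y Response labels: any atomic vector or factor. An internal
#'   codebook maps labels to 1..L by first appearance and back on output.
#' @param k_max Largest neighborhood size considered. Defaults to
#'   \code{min(n - 1, 250)}; values above \code{n - 1} are clipped with a
#'   warning.
#' @param beta_max Upper bound for each interaction-strength estimate.
#' @param refit_loocv Logical; exact per-fold refitting during LOOCV.
#' @param data,formula A model formula and data frame, as an alternative
#'   interface: \code{pnnclass(y ~ ., data = df)}.
#' @param ... Passed between methods.
#' @return An object of class \code{"pnnclass"} with components including
#'   \code{beta} (vector of beta_hat_r), \code{fits}, \code{k} (selected
#'   neighborhood size), \code{loocv_error} (LOO misclassification per k),
#'   \code{brackets}, \code{counts}, and the training data.
#' @examples
#' sim <- ripley_like(n_train = 60, n_test = 40, seed = 7)
#' fit <- pnnclass(sim$train$x, sim$train$y, k_max = 20)
#' fit
#' mean(predict(fit, sim$test$x) != sim$test$y)
#' @seealso \code{\link{predict.pnnclass}}, \code{\link{evaluate}},
#'   \code{\link{write_pnnclass}}
#' @export
pnnclass <- function(x, ...) UseMethod("pnnclass")

#' @rdname pnnclass
#' @export
pnnclass.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  out <- pnnclass.default(x, y, ...)
  out$call <- match.call()
  out
}

#' @rdname pnnclass
#' @export
pnnclass.default <- function(x, y, k_max = NULL, beta_max = 30,
                             refit_loocv = FALSE, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  codebook <- y[!duplicated(y)]
  L <- length(codebook)
  if (L < 2L) stop("training labels contain a single class", call. = FALSE)
  yi <- match(y, codebook)
  if (is.null(k_max)) k_max <- min(n - 1L, 250L)
  if (k_max > n - 1L) {
    warning("k_max exceeds n - 1; clipped", call. = FALSE)
    k_max <- n - 1L
  }
  if (k_max < 1L) stop("k_max must be at least 1", call. = FALSE)

  core <- pnn_core(x, yi, L, k_max, beta_max)
  cv <- if (refit_loocv) pnn_loocv_refit(x, yi, L, k_max, beta_max)
        else pnn_loocv(core, yi, L)
  k_sel <- which.min(cv$error)          # ties -> smallest k

  structure(c(core,
              list(y = yi, codebook = codebook, L = L, n = n, p = ncol(x),
                   k = k_sel, loocv_error = cv$error, loo_prob = cv$prob,
                   refit_loocv = refit_loocv, beta_max = beta_max,
                   call = match.call())),
            class = "pnnclass")
}

# distances, brackets, cycle counts and per-rank MLEs (everything that does
# not involve cross-validation)
pnn_core <- function(x, yi, L, k_max, beta_max) {
  d <- as.matrix(stats::dist(x))
  brackets <- nn_brackets(d)
  counts <- count_simple_cycles(brackets)
  n <- nrow(x)
  Tr <- vapply(seq_len(k_max), function(r) sufficient_statistic(yi, brackets, r),
               numeric(1))
  fits <- lapply(seq_len(k_max), function(r)
    fit_beta(Tr[r], L, n, counts[r, ], beta_max = beta_max))
  list(x = x, d = d, brackets = brackets, counts = counts,
       T = as.integer(Tr), fits = fits,
       beta = vapply(fits, `[[`, numeric(1), "beta_hat"), k_max = k_max)
}

# per-rank predictive scores for every held-out training unit: unit i's r-th
# neighbor is brackets[i, r], and i is captured by unit j when brackets[j, r]
# = i. Returns the LOO error for every k and the aggregated LOO probabilities
# at each unit for the full k grid.
pnn_loocv <- function(core, yi, L) {
  n <- nrow(core$x)
  k_max <- core$k_max
  br <- core$brackets
  err <- numeric(k_max)
  acc <- matrix(0, n, L)
  prob <- vector("list", k_max)
  for (r in seq_len(k_max)) {
    S <- matrix(tabulate((yi - 1L) * n + br[, r], n * L), n, L)
    S[cbind(seq_len(n), yi[br[, r]])] <- S[cbind(seq_len(n), yi[br[, r]])] + 1
    P <- softmax_rows(core$beta[r] * S)
    acc <- acc + P
    pk <- acc / r
    err[r] <- mean(max.col(pk, ties.method = "first") != yi)
    prob[[r]] <- pk
  }
  list(error = err, prob = prob)
}

# exact variant: rebuild the whole model without unit i for every fold
pnn_loocv_refit <- function(x, yi, L, k_max, beta_max) {
  n <- nrow(x)
  err_mat <- matrix(0, n, k_max)
  prob <- NULL
  for (i in seq_len(n)) {
    core_i <- pnn_core(x[-i, , drop = FALSE], yi[-i], L,
                       min(k_max, n - 2L), beta_max)
    qd <- sqrt(colSums((t(x[-i, , drop = FALSE]) - x[i, ])^2))
    P <- predict_profile(core_i, yi[-i], L, qd)      # k x L per-rank probs
    pk <- apply(P, 2, cumsum) / seq_len(nrow(P))
    if (nrow(P) < k_max)                              # shrunken fold grid
      pk <- pk[c(seq_len(nrow(P)), rep(nrow(P), k_max - nrow(P))), , drop = FALSE]
    err_mat[i, ] <- max.col(pk, ties.method = "first") != yi[i]
  }
  list(error = colMeans(err_mat), prob = NULL)
}

# per-rank predictive distributions for one query given a fitted core;
# returns a k_max x L matrix of probabilities (row r = rank-r model)
predict_profile <- function(core, yi, L, qd) {
  n <- length(qd)
  rho <- insertion_ranks(core$d, qd)
  ord <- order(qd, seq_len(n))
  k <- core$k_max
  cap <- matrix(tabulate((pmin(rho, n) - 1L) * L + yi, n * L), L, n)
  S <- t(cap[, seq_len(k), drop = FALSE])             # captured-label counts
  S[cbind(seq_len(k), yi[ord[seq_len(k)]])] <-
    S[cbind(seq_len(k), yi[ord[seq_len(k)]])] + 1     # query's r-th neighbor
  softmax_rows(core$beta[seq_len(k)] * S)
}

softmax_rows <- function(M) {
  M <- exp(M - apply(M, 1, max))
  M / rowSums(M)
}

#' Aggregate per-rank predictive distributions
#'
#' Arithmetic mean of the first k rows of a stack of per-rank predictive
#' distributions.
#'
#' @param dists Numeric matrix, one per-rank distribution per row.
#' @param k Number of leading ranks to average.
#' @return A probability vector of length \code{ncol(dists)}.
#' @export
aggregate_predictive <- function(dists, k) {
  dists <- as.matrix(dists)
  if (k < 1L || k > nrow(dists)) stop("k out of range", call. = FALSE)
  colSums(dists[seq_len(k), , drop = FALSE]) / k
}

#' Predict method for pnnclass models
#'
#' For each query point the insertion neighborhoods at ranks 1..k are
#' computed against the training sample, the per-rank predictive
#' distributions are formed from the fitted interaction strengths, and their
#' average is returned.
#'
#' @param object A fitted \code{"pnnclass"} model.
#' @param newdata Numeric matrix of query features (p columns).
#' @param type \code{"class"} for labels (ties go to the earlier class in the
#'   codebook), \code{"prob"} for the aggregated probability matrix.
#' @param k Neighborhood size; defaults to the LOOCV-selected value.
#' @param ... Unused.
#' @return A label vector, or an \code{m x L} probability matrix with one
#'   column per class (columns named by the original labels).
#' @export
predict.pnnclass <- function(object, newdata, type = c("class", "prob"),
                             k = object$k, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("newdata must have ", object$p, " columns", call. = FALSE)
  if (k < 1L || k > object$k_max) stop("k out of range", call. = FALSE)
  xt <- t(object$x)
  P <- t(apply(newdata, 1, function(q) {
    prof <- predict_profile(object, object$y, object$L,
                            sqrt(colSums((xt - q)^2)))
    aggregate_predictive(prof, k)
  }))
  colnames(P) <- as.character(object$codebook)
  if (type == "prob") return(P)
  object$codebook[max.col(P, ties.method = "first")]
}

#' @export
print.pnnclass <- function(x, ...) {
  cat("Probabilistic nearest neighbors classifier\n")
  cat(sprintf("  n = %d training units, p = %d predictors, L = %d classes\n",
              x$n, x$p, x$L))
  cat(sprintf("  k selected by LOOCV: %d (LOO error %.4f); k grid 1..%d\n",
              x$k, x$loocv_error[x$k], x$k_max))
  invisible(x)
}

#' @export
summary.pnnclass <- function(object, ...) {
  structure(list(model = object,
                 class_table = table(object$codebook[object$y]),
                 n_clipped = sum(vapply(object$fits, `[[`, logical(1), "clipped"))),
            class = "summary.pnnclass")
}

#' @export
print.summary.pnnclass <- function(x, ...) {
  print(x$model)
  cat("  class counts:\n")
  print(x$class_table)
  r_show <- seq_len(min(10L, x$model$k_max))
  cat("  leading interaction strengths (beta_hat_r):\n")
  print(round(stats::setNames(x$model$beta[r_show], paste0("r=", r_show)), 4))
  if (x$n_clipped > 0)
    cat(sprintf("  %d estimate(s) clipped at beta_max = %g\n",
                x$n_clipped, x$model$beta_max))
  invisible(x)
}

#' @export
coef.pnnclass <- function(object, ...) {
  stats::setNames(object$beta, paste0("beta_", seq_along(object$beta)))
}

#' Plot the LOOCV error curve of a pnnclass model
#'
#' @param x A fitted \code{"pnnclass"} model.
#' @param ... Passed to \code{plot}.
#' @export
plot.pnnclass <- function(x, ...) {
  plot(seq_along(x$loocv_error), x$loocv_error, type = "b",
       xlab = "neighborhood size k", ylab = "LOOCV misclassification",
       ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}

#' @export
fitted.pnnclass <- function(object, ...) {
  if (is.null(object$loo_prob)) {
    warning("per-unit LOO probabilities unavailable (refit mode); returning NULL",
            call. = FALSE)
    return(NULL)
  }
  P <- object$loo_prob[[object$k]]
  colnames(P) <- as.character(object$codebook)
  P
}

#' @export
residuals.pnnclass <- function(object, ...) {
  P <- fitted(object)
  if (is.null(P)) return(NULL)
  1 - P[cbind(seq_len(object$n), object$y)]
}
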