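# run expr under a temporary RNG state when seed is given; the caller's
# stream is untouched either way
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Two-class overlapping Gaussian-mixture benchmark
#'
#' Generates a seeded two-dimensional, two-class classification problem in
#' the mold of Ripley's classic synthetic benchmark: each class is an
#' equal-weight mixture of two isotropic Gaussians, the component means
#' interleave horizontally so the class supports overlap substantially, and
#' samples are balanced. With the default geometry a well-tuned k-NN
#' classifier lands in roughly the 8-12% test-error range.
#'
#' @param n_train,n_test Sample sizes (split evenly between the classes).
#' @param means1,means0 2 x 2 matrices of component means (one row per
#'   mixture component) for class 1 and class 0.
#' @param sd Common isotropic component standard deviation
#'   (default \code{sqrt(0.03)}).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A list with \code{train} and \code{test}, each a list with
#'   feature matrix \code{x} and integer labels \code{y} in \{0, 1\}.
#' @examples
#' sim <- ripley_like(n_train = 50, n_test = 50, seed = 1)
#' table(sim$train$y)
#' @export
ripley_like <- function(n_train = 250, n_test = 1000,
                        means1 = rbind(c(-0.3, 0.7), c(0.4, 0.7)),
                        means0 = rbind(c(-0.7, 0.3), c(0.3, 0.3)),
                        sd = sqrt(0.03), seed = 1) {
  if (sd <= 0 || n_train < 2 || n_test < 2)
    stop("degenerate simulation spec", call. = FALSE)
  gen <- function(n) {
    n1 <- floor(n / 2); n0 <- n - n1
    comp1 <- sample(1:2, n1, replace = TRUE)
    comp0 <- sample(1:2, n0, replace = TRUE)
    x <- rbind(means1[comp1, ] + matrix(stats::rnorm(2 * n1, sd = sd), n1, 2),
               means0[comp0, ] + matrix(stats::rnorm(2 * n0, sd = sd), n0, 2))
    y <- c(rep(1L, n1), rep(0L, n0))
    ord <- sample.int(n)          # shuffle so class blocks are interleaved
    list(x = x[ord, , drop = FALSE], y = y[ord])
  }
  with_seed(seed, list(train = gen(n_train), test = gen(n_test)))
}

#' Multiclass Gaussian blobs
#'
#' Seeded generator of a p-dimensional classification problem with
#' \code{n_classes} isotropic Gaussian blobs. Class means are spaced evenly
#' on a circle of radius \code{separation} in the first two coordinates
#' (on the two points +-\code{separation} when p = 1), so the geometry is a
#' deterministic function of the arguments and \code{separation} directly
#' controls difficulty. \code{separation = 0} collapses all classes onto one
#' distribution.
#'
#' @param n_classes Number of classes (>= 2).
#' @param p Number of predictors.
#' @param n_train,n_test Total sample sizes (balanced across classes).
#' @param separation Distance of each class mean from the origin.
#' @param sd Within-class standard deviation.
#' @param seed Integer seed.
#' @return A list with \code{train} and \code{test} as in
#'   \code{\link{ripley_like}}; labels are integers 1..n_classes.
#' @export
multiclass_blobs <- function(n_classes = 4, p = 2, n_train = 100, n_test = 100,
                             separation = 3, sd = 1, seed = 1) {
  if (n_classes < 2L || p < 1L || n_train < n_classes || n_test < n_classes)
    stop("invalid blob sizes", call. = FALSE)
  ang <- 2 * pi * (seq_len(n_classes) - 1) / n_classes
  mu <- matrix(0, n_classes, p)
  mu[, 1] <- separation * cos(ang)
  if (p >= 2) mu[, 2] <- separation * sin(ang)
  with_seed(seed, {
    gen <- function(n) {
      y <- rep(seq_len(n_classes), length.out = n)
      x <- mu[y, , drop = FALSE] + matrix(stats::rnorm(n * p, sd = sd), n, p)
      ord <- sample.int(n)
      list(x = x[ord, , drop = FALSE], y = y[ord])
    }
    list(train = gen(n_train), test = gen(n_test))
  })
}

#' Random functional graph
#'
#' Uniform random successor map on n vertices with no self-loops: a test
#' harness for cycle counting and the partition-function oracles.
#'
#' @param n Number of vertices (>= 2).
#' @param seed Integer seed.
#' @return Integer vector \code{succ} of length n, \code{succ[i] != i}.
#' @export
random_functional_graph <- function(n, seed = NULL) {
  if (n < 2L) stop("need at least 2 vertices", call. = FALSE)
  with_seed(seed, {
    s <- sample.int(n - 1L, n, replace = TRUE)
    s + (s >= seq_len(n))
  })
}
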