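#' Read a labeled CSV feature table
#'
#' Reads a delimited feature table (one row per unit, numeric predictor
#' columns) with a designated label column. Row order is preserved; labels
#' keep their original values and are codebook-mapped inside
#' \code{\link{pnnclass}}.
#'
#' @param path CSV file path.
#' @param label_column Name of the label column; \code{NULL} for an unlabeled
#'   query table.
#' @return A list with \code{x} (numeric matrix) and \code{y} (label vector,
#'   or \code{NULL}).
#' @export
read_labeled_csv <- function(path, label_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path, call. = FALSE)
  y <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df))
      stop("label column '", label_column, "' not found in ", path, call. = FALSE)
    y <- df[[label_column]]
    df <- df[names(df) != label_column]
  }
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(df)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column '%s'", idx[1],
                 colnames(x)[idx[2]]), call. = FALSE)
  }
  list(x = x, y = y)
}

#' Evaluate a classifier on a labeled test set
#'
#' Computes the misclassification rate, the predicted-by-observed confusion
#' matrix and, for binary problems, the ROC curve with trapezoidal AUC and
#' the probability threshold maximizing sensitivity + specificity. The
#' positive class for the ROC sweep is the second entry of the model's label
#' codebook.
#'
#' @param object A fitted \code{"pnnclass"} model.
#' @param x Test feature matrix.
#' @param y Observed test labels.
#' @param ... Passed to \code{\link{predict.pnnclass}} (e.g. \code{k}).
#' @return An object of class \code{"pnnclass_eval"}: a list with
#'   \code{error_rate}, \code{confusion} (rows = predicted, columns =
#'   observed), and for binary problems \code{roc} (data frame with columns
#'   \code{threshold}, \code{fpr}, \code{tpr}), \code{auc} and
#'   \code{best_threshold}.
#' @export
evaluate <- function(object, x, y, ...) {
  P <- predict(object, x, type = "prob", ...)
  lev <- as.character(object$codebook)
  pred <- lev[max.col(P, ties.method = "first")]
  obs <- as.character(y)
  if (!all(obs %in% lev))
    warning("test labels outside the training codebook", call. = FALSE)
  confusion <- table(predicted = factor(pred, levels = lev),
                     observed = factor(obs, levels = lev))
  out <- list(error_rate = mean(pred != obs), confusion = confusion,
              n = length(obs))
  if (object$L == 2L) {
    if (length(unique(obs)) < 2L) {
      warning("single-class test set: ROC omitted", call. = FALSE)
    } else {
      out <- c(out, roc_points(P[, 2L], obs == lev[2L]))
    }
  }
  structure(out, class = "pnnclass_eval")
}

# threshold sweep over the unique predicted probabilities (plus sentinels);
# positive predicted when prob >= threshold
roc_points <- function(p, positive) {
  th <- c(Inf, sort(unique(p), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(p[positive] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(p[!positive] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- which.max(tpr - fpr)    # sensitivity + specificity - 1
  list(roc = data.frame(threshold = th, fpr = fpr, tpr = tpr),
       auc = auc, best_threshold = th[j],
       sensitivity = tpr[j], specificity = 1 - fpr[j])
}

#' @export
print.pnnclass_eval <- function(x, ...) {
  cat(sprintf("Test error rate: %.4f  (n = %d)\n", x$error_rate, x$n))
  cat("Confusion matrix (rows predicted, columns observed):\n")
  print(x$confusion)
  if (!is.null(x$auc))
    cat(sprintf("AUC: %.4f;  best threshold %.4f (sens %.3f, spec %.3f)\n",
                x$auc, x$best_threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Serialize a pnnclass model to JSON
#'
#' Writes (or reads back) a fitted model as a documented JSON file holding
#' the training features and labels, neighbor brackets, cycle counts,
#' per-rank estimates, the LOOCV curve and the label codebook. The distance
#' matrix is recomputed on read. Serialization is deterministic: identical
#' models produce byte-identical files.
#'
#' @param object A fitted \code{"pnnclass"} model.
#' @param path Output (input) file path.
#' @return \code{write_pnnclass} returns \code{path} invisibly;
#'   \code{read_pnnclass} returns the restored \code{"pnnclass"} object.
#' @export
write_pnnclass <- function(object, path) {
  stopifnot(inherits(object, "pnnclass"))
  payload <- list(
    format = "pnnclass-model",
    version = 1L,
    n = object$n, p = object$p, L = object$L,
    k_selected = object$k, k_max = object$k_max,
    beta_max = object$beta_max,
    codebook = as.character(object$codebook),
    codebook_type = class(object$codebook)[1],
    features = object$x,
    labels = object$y,
    brackets = object$brackets,
    cycle_counts = object$counts,
    T = object$T,
    beta = object$beta,
    clipped = vapply(object$fits, `[[`, logical(1), "clipped"),
    loocv_error = object$loocv_error)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_pnnclass
#' @export
read_pnnclass <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(m$format, "pnnclass-model"))
    stop("not a pnnclass model file: ", path, call. = FALSE)
  codebook <- switch(m$codebook_type,
                     integer = as.integer(m$codebook),
                     numeric = as.numeric(m$codebook),
                     factor = ,
                     character = m$codebook)
  x <- matrix(as.numeric(m$features), m$n, m$p)
  yi <- as.integer(m$labels)
  counts <- matrix(as.integer(m$cycle_counts), nrow(m$cycle_counts))
  dimnames(counts) <- list(r = seq_len(nrow(counts)),
                           m = seq(2L, ncol(counts) + 1L))
  fits <- lapply(seq_len(m$k_max), function(r)
    fit_beta(m$T[r], m$L, m$n, counts[r, ], beta_max = m$beta_max))
  structure(list(x = x, d = as.matrix(stats::dist(x)),
                 brackets = matrix(as.integer(m$brackets), m$n, m$n - 1L),
                 counts = counts, T = as.integer(m$T), fits = fits,
                 beta = as.numeric(m$beta), k_max = as.integer(m$k_max),
                 y = yi, codebook = codebook, L = as.integer(m$L),
                 n = as.integer(m$n), p = as.integer(m$p),
                 k = as.integer(m$k_selected),
                 loocv_error = as.numeric(m$loocv_error), loo_prob = NULL,
                 refit_loocv = FALSE, beta_max = as.numeric(m$beta_max),
                 call = quote(read_pnnclass(path))),
            class = "pnnclass")
}
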