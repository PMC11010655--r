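#' Modern analogue technique (MAT) transfer function
#'
#' Stores a reference set of modern assemblages (as proportions) with their
#' environment. Predictions for a new assemblage are the unweighted mean
#' environment of its `k` nearest reference samples under squared-chord
#' distance \eqn{d = \sum_j (\sqrt{p_j} - \sqrt{q_j})^2} on proportions.
#'
#' @param y reference pollen percentages (`pollen_matrix` or matrix).
#' @param x reference environment, one value per sample.
#' @param k number of analogues (>= 1; must leave at least one other
#'   reference available under leave-one-out).
#' @param variable optional variable name.
#' @return object of class `modern_analogue`.
#' @export
modern_analogue <- function(y, x, k = 5, variable = NULL) {
  Y <- pollen_values(y)
  x <- as.numeric(x)
  if (length(x) != nrow(Y)) stop("length(x) must equal nrow(y)")
  if (anyNA(x)) stop("x contains missing values")
  rs <- rowSums(Y)
  if (any(rs <= 0)) stop("reference sample(s) with zero pollen sum")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(Y))
    stop("k = ", k, " analogues exceed the ", nrow(Y),
         " references available")
  structure(list(sqrt_p = sqrt(Y / rs), x = x, k = k, taxa = colnames(Y),
                 variable = variable), class = "modern_analogue")
}

#' Predict environment by modern-analogue matching
#'
#' @param object a [modern_analogue()] model.
#' @param newdata pollen percentages over the model taxa.
#' @param exclude_self logical; when `newdata` is the reference set itself,
#'   exclude each sample from its own analogue pool (leave-one-out).
#' @param ... unused.
#' @return numeric predictions, one per row.
#' @export
predict.modern_analogue <- function(object, newdata, exclude_self = FALSE,
                                    ...) {
  Y <- pollen_values(newdata)
  miss <- setdiff(object$taxa, colnames(Y))
  if (length(miss))
    stop("newdata lacks model taxa (", paste(utils::head(miss, 5),
         collapse = ", "), "); run harmonize_taxa() first")
  Y <- Y[, object$taxa, drop = FALSE]
  rs <- rowSums(Y)
  if (any(rs <= 0)) stop("row(s) with zero abundance over the model taxa")
  sq <- sqrt(Y / rs)
  # squared chord: |p|_chord + |q|_chord - 2 * cross term
  d2 <- outer(rowSums(sq^2), rowSums(object$sqrt_p^2), "+") -
    2 * tcrossprod(sq, object$sqrt_p)
  if (exclude_self) {
    if (nrow(d2) != ncol(d2))
      stop("exclude_self requires newdata to be the reference set")
    if (object$k > ncol(d2) - 1L)
      stop("k = ", object$k, " analogues exceed the ", ncol(d2) - 1L,
           " references available under cross-validation")
    diag(d2) <- Inf
  }
  k <- object$k
  apply(d2, 1, function(d) mean(object$x[order(d)[seq_len(k)]]))
}

#' @export
print.modern_analogue <- function(x, ...) {
  cat("Modern analogue technique", if (!is.null(x$variable))
    paste0("for '", x$variable, "'"), "\n")
  cat("  ", length(x$x), "reference samples,", length(x$taxa),
      "taxa, k =", x$k, "(squared-chord distance)\n")
  invisible(x)
}
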