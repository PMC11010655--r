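#' Weighted-averaging partial least squares (WA-PLS) transfer function
#'
#' Fits the standard WA-PLS cycle relating a pollen percentage matrix to an
#' environmental variable: the environment is centred (weighted by pollen
#' sums); each component's taxon scores are the residual-weighted averages
#' over samples; sample scores are the abundance-weighted averages of taxon
#' scores; successive components are orthogonalized against earlier ones
#' under the sample-total weights and standardized; and a final weighted
#' least-squares regression of the environment on the component scores acts
#' as the deshrinking step. With `k = 1` the fitted values coincide with
#' classic weighted averaging under inverse linear deshrinking.
#'
#' @param y pollen data: a [pollen_matrix()] (percentages) or a numeric
#'   matrix of nonnegative abundances with column names.
#' @param x numeric environmental variable, one value per sample.
#' @param k number of components (>= 1).
#' @param variable optional name of the environmental variable (e.g. "mat").
#' @param warn_empty warn when all-zero taxon columns are dropped.
#' @return object of class `wapls` with taxon scores, orthogonalization and
#'   scaling constants per component, deshrinking coefficients, and fitted
#'   values.
#' @seealso [predict.wapls()], [loo_cv()], [modern_analogue()]
#' @export
wapls <- function(y, x, k = 2, variable = NULL, warn_empty = TRUE) {
  Y <- pollen_values(y)
  x <- as.numeric(x)
  n <- nrow(Y)
  if (length(x) != n) stop("length(x) must equal nrow(y)")
  if (anyNA(x)) stop("x contains missing values")
  if (stats::var(x) == 0)
    stop("environmental variable is constant: no gradient to calibrate")
  rs <- rowSums(Y)
  if (any(rs <= 0))
    stop("sample(s) with zero pollen sum: ",
         paste(rownames(Y)[rs <= 0], collapse = ", "))
  cs <- colSums(Y)
  if (any(cs == 0)) {
    if (warn_empty)
      warning("dropping all-zero taxon column(s): ",
              paste(colnames(Y)[cs == 0], collapse = ", "))
    Y <- Y[, cs > 0, drop = FALSE]
    cs <- cs[cs > 0]
  }
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (n <= k + 1) stop("need n > k + 1 samples to fit ", k, " component(s)")
  if (k > min(n - 1L, ncol(Y)))
    stop("k exceeds what ", n, " samples x ", ncol(Y), " taxa can support")

  w <- rs / sum(rs)                      # sample weights (pollen-sum shares)
  xbar <- sum(w * x)
  xc <- x - xbar
  U <- matrix(0, ncol(Y), k, dimnames = list(colnames(Y), NULL))
  P <- matrix(0, n, k)                   # standardized component scores
  alpha <- vector("list", k)             # orthogonalization coefficients
  cent <- scal <- numeric(k)
  e <- xc
  beta <- NULL
  for (a in seq_len(k)) {
    u <- colSums(Y * e) / cs             # taxon scores from current residual
    r <- drop(Y %*% u) / rs              # sample scores by weighted averaging
    if (a > 1) {
      al <- numeric(a - 1)
      for (b in seq_len(a - 1)) {
        al[b] <- sum(w * r * P[, b])
        r <- r - al[b] * P[, b]
      }
      alpha[[a]] <- al
    } else alpha[[a]] <- numeric(0)
    cent[a] <- sum(w * r)
    r <- r - cent[a]
    scal[a] <- sqrt(sum(w * r^2))
    if (scal[a] < 1e-12)
      stop("component ", a, " is degenerate (no compositional variation ",
           "left to extract)")
    r <- r / scal[a]
    P[, a] <- r
    U[, a] <- u
    fit <- stats::lm.wfit(P[, seq_len(a), drop = FALSE], xc, w)
    e <- xc - drop(P[, seq_len(a), drop = FALSE] %*% fit$coefficients)
    if (a == k) beta <- fit$coefficients
  }
  fitted <- xbar + drop(P %*% beta)
  structure(list(taxa = colnames(Y), k = k, u = U, alpha = alpha,
                 cent = cent, scal = scal, beta = beta, xbar = xbar,
                 scores = P, fitted.values = fitted,
                 residuals = fitted - x, observed = x,
                 variable = variable, call = match.call()),
            class = "wapls")
}

# extract the abundance matrix from pollen_matrix or plain matrix input
pollen_values <- function(y) {
  if (inherits(y, "pollen_matrix")) return(y$values)
  Y <- as.matrix(y)
  storage.mode(Y) <- "double"
  if (is.null(colnames(Y))) stop("pollen matrix must have taxon column names")
  Y
}

#' Predict environment for new pollen assemblages from a WA-PLS model
#'
#' @param object a [wapls()] fit.
#' @param newdata pollen percentages (`pollen_matrix` or matrix) containing
#'   every taxon retained by the model.
#' @param ... unused.
#' @return numeric vector of predictions, one per row of `newdata`.
#' @export
predict.wapls <- function(object, newdata, ...) {
  Y <- pollen_values(newdata)
  miss <- setdiff(object$taxa, colnames(Y))
  if (length(miss))
    stop("newdata lacks model taxa (", paste(utils::head(miss, 5),
         collapse = ", "), "); run harmonize_taxa() first")
  Y <- Y[, object$taxa, drop = FALSE]
  rs <- rowSums(Y)
  if (any(rs <= 0))
    stop("row(s) with zero abundance over the model taxa: weighted average ",
         "undefined (rows ", paste(which(rs <= 0), collapse = ", "), ")")
  k <- object$k
  P <- matrix(0, nrow(Y), k)
  for (a in seq_len(k)) {
    r <- drop(Y %*% object$u[, a]) / rs
    if (a > 1)
      for (b in seq_len(a - 1)) r <- r - object$alpha[[a]][b] * P[, b]
    P[, a] <- (r - object$cent[a]) / object$scal[a]
  }
  object$xbar + drop(P %*% object$beta)
}

#' @export
print.wapls <- function(x, ...) {
  cat("WA-PLS transfer function", if (!is.null(x$variable))
    paste0("for '", x$variable, "'"), "\n")
  cat("  ", length(x$observed), "samples,", length(x$taxa), "taxa,",
      x$k, "component(s)\n")
  cat("  in-sample RMSE:",
      format(sqrt(mean(x$residuals^2)), digits = 4), "\n")
  invisible(x)
}

#' @export
coef.wapls <- function(object, ...) object$beta

#' @export
fitted.wapls <- function(object, ...) object$fitted.values

#' @export
residuals.wapls <- function(object, ...) object$residuals
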