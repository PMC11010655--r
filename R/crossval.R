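#' Leave-one-out cross-validation of a transfer function
#'
#' For every sample the model is refit (WA-PLS) or the analogue pool formed
#' (MAT) without that sample, which is then predicted. Residuals are stored
#' signed as `predicted - observed`.
#'
#' @param y a [modern_dataset()], [pollen_matrix()] or abundance matrix.
#' @param x the environmental variable: for a `modern_dataset` give the
#'   variable name via `variable`; otherwise a numeric vector.
#' @param variable `"mat"` or `"map"` (used with a `modern_dataset`).
#' @param method `"wapls"` or `"analogue"`.
#' @param k components (WA-PLS, default 2) or analogues (MAT, default 5).
#' @param ... unused.
#' @return data.frame of class `cv_result` with columns `sample_id`,
#'   `observed`, `predicted`, `residual`, and attributes `method`,
#'   `variable`, `k`.
#' @export
loo_cv <- function(y, x = NULL, variable = NULL,
                   method = c("wapls", "analogue"), k = NULL, ...) {
  method <- match.arg(method)
  if (inherits(y, "modern_dataset")) {
    variable <- match.arg(variable, c("mat", "map"))
    x <- switch(variable, mat = y$meta$mat_c, map = y$meta$map_mm)
    y <- y$pollen
  }
  Y <- pollen_values(y)
  x <- as.numeric(x)
  n <- nrow(Y)
  if (n < 10) stop("leave-one-out validation needs at least 10 samples")
  if (length(x) != n) stop("length(x) must equal nrow(y)")
  ids <- rownames(Y)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(k)) k <- if (method == "wapls") 2L else 5L

  pred <- numeric(n)
  if (method == "wapls") {
    for (i in seq_len(n)) {
      m <- tryCatch(
        wapls(Y[-i, , drop = FALSE], x[-i], k = k, warn_empty = FALSE),
        error = function(e)
          stop("leave-one-out refit failed for sample '", ids[i], "': ",
               conditionMessage(e)))
      pred[i] <- predict(m, Y[i, , drop = FALSE])
    }
  } else {
    m <- modern_analogue(Y, x, k = k)
    pred <- predict(m, Y, exclude_self = TRUE)
  }
  out <- data.frame(sample_id = ids, observed = x, predicted = pred,
                    residual = pred - x, stringsAsFactors = FALSE)
  structure(out, class = c("cv_result", "data.frame"),
            method = method, variable = variable, k = k)
}

#' Validation statistics of a cross-validated transfer function
#'
#' @param cv a `cv_result` from [loo_cv()], or any data.frame with
#'   `observed` and `predicted` columns.
#' @return list of class `performance_stats`: `rmsep` (root mean square
#'   error of prediction), `r2` (squared Pearson correlation of observed vs
#'   predicted), `n`, plus the method/variable labels.
#' @export
performance_stats <- function(cv) {
  if (nrow(cv) < 3) stop("need at least 3 samples for performance statistics")
  res <- cv$predicted - cv$observed
  if (stats::sd(cv$observed) == 0)
    stop("observed values have zero variance: r2 undefined")
  structure(list(rmsep = sqrt(mean(res^2)),
                 r2 = stats::cor(cv$observed, cv$predicted)^2,
                 n = nrow(cv),
                 method = attr(cv, "method"), variable = attr(cv, "variable"),
                 k = attr(cv, "k")),
            class = "performance_stats")
}

#' @export
print.performance_stats <- function(x, ...) {
  cat("Transfer-function performance (", x$method %||% "?", ", ",
      x$variable %||% "?", ", n = ", x$n, ")\n", sep = "")
  cat("  RMSEP:", format(x$rmsep, digits = 5),
      " R2:", format(x$r2, digits = 4), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parsimony rule: smallest K whose RMSEP is within 5% of the global minimum
choose_k <- function(rmsep) {
  which(rmsep <= 1.05 * min(rmsep))[1]
}

#' Choose the number of WA-PLS components by the 5% parsimony rule
#'
#' Runs leave-one-out validation for each candidate number of components and
#' returns the smallest K whose RMSEP is within 5% of the global minimum
#' over `1..k_max`.
#'
#' @param y pollen data (see [loo_cv()]).
#' @param x environment vector, or use `variable` with a `modern_dataset`.
#' @param variable `"mat"` or `"map"` for `modern_dataset` input.
#' @param k_max largest number of components considered.
#' @return list of class `component_selection`: `k` (chosen) and `table`
#'   (per-K RMSEP and R2).
#' @export
select_components <- function(y, x = NULL, variable = NULL, k_max = 5) {
  k_max <- as.integer(k_max)
  if (k_max < 1) stop("k_max must be >= 1")
  tab <- data.frame(k = seq_len(k_max), rmsep = NA_real_, r2 = NA_real_)
  for (kk in seq_len(k_max)) {
    cv <- loo_cv(y, x, variable = variable, method = "wapls", k = kk)
    ps <- performance_stats(cv)
    tab$rmsep[kk] <- ps$rmsep
    tab$r2[kk] <- ps$r2
  }
  structure(list(k = choose_k(tab$rmsep), table = tab),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat("Selected K =", x$k, "component(s) (5% parsimony rule)\n")
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}
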