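#' Cumulative probability curve of cross-validated error against HII
#'
#' Builds the curve whose linear segments on the probit
#' (probability-percentage) scale mark the HII ranges of distinct
#' vegetation systems. Three statistics are available:
#' \describe{
#'   \item{error_level (default)}{For each integer HII bin h, the mean
#'     absolute cross-validated residual \eqn{\bar e(h)} is placed within
#'     the fitted normal error model:
#'     \eqn{F(h) = \Phi((\bar e(h) - m)/s)} with m, s the mean and sd of
#'     the per-sample absolute residuals. Its probit is the standardized
#'     bin error level, so systems with distinct (normal) error regimes
#'     plot as straight segments and the segment intersections fall where
#'     the error regime changes.}
#'   \item{error_mass}{Grain-size-style cumulative weight:
#'     \eqn{F(h) = \sum_{i: hii_i \le h} |r_i| / \sum_i |r_i|}; each sample
#'     contributes its absolute residual as mass at its HII.}
#'   \item{count}{Cumulative sample fraction
#'     \eqn{F(h) = \#\{hii_i \le h\}/n}.}
#' }
#' The HII grid is the set of integer-rounded HII values present (the HII
#' raster is effectively integer-valued). For the cumulative statistics F
#' is nondecreasing and reaches 1 at the top of the grid; the terminal
#' F = 1 point is excluded from segment fitting (infinite probit).
#'
#' @param cv a `cv_result` from [loo_cv()].
#' @param meta a [site_meta()] providing `hii` per sample (matched by id).
#' @param weighting `"error_level"`, `"error_mass"` or `"count"`.
#' @param eps probit clipping bound: probit values are only used where
#'   `eps <= F <= 1 - eps`.
#' @return data.frame of class `error_curve` with columns `hii`, `f`,
#'   `probit`, `include` (usable for fitting), plus attributes
#'   `weighting`, `variable`, `method`.
#' @export
error_curve <- function(cv, meta,
                        weighting = c("error_level", "error_mass", "count"),
                        eps = 0.001) {
  weighting <- match.arg(weighting)
  idx <- match(cv$sample_id, meta$sample_id)
  if (anyNA(idx))
    stop("cv samples missing from metadata: ",
         paste(utils::head(cv$sample_id[is.na(idx)], 5), collapse = ", "))
  hii <- meta$hii[idx]
  curve <- error_curve_core(hii, abs(cv$residual), weighting, eps)
  attr(curve, "variable") <- attr(cv, "variable")
  attr(curve, "method") <- attr(cv, "method")
  curve
}

# core construction from raw (hii, |residual|) pairs; also used by the
# bootstrap in estimate_ips()
error_curve_core <- function(hii, abs_res, weighting, eps = 0.001,
                             check = TRUE) {
  if (check) {
    if (length(hii) < 30)
      stop("error curve needs at least 30 samples")
    if (length(unique(round(hii))) < 10)
      stop("error curve needs samples spanning at least 10 distinct HII ",
           "values")
  }
  h <- round(hii)
  if (weighting == "error_level") {
    if (stats::sd(abs_res) == 0)
      stop("all cross-validated residuals are equal; use weighting = ",
           "'count'")
    em <- rowsum(abs_res, h) / as.vector(table(h))
    grid <- as.numeric(rownames(em))
    o <- order(grid)
    z <- (em[o] - mean(abs_res)) / stats::sd(abs_res)
    f <- stats::pnorm(z)
    include <- rep(TRUE, length(f))
    probit <- stats::qnorm(pmin(pmax(f, eps), 1 - eps))
  } else {
    mass <- switch(weighting, error_mass = abs_res,
                   count = rep(1, length(hii)))
    if (weighting == "error_mass" && sum(mass) == 0)
      stop("all cross-validated residuals are zero; use weighting = ",
           "'count'")
    agg <- rowsum(mass, h)
    grid <- as.numeric(rownames(agg))
    o <- order(grid)
    f <- cumsum(agg[o]) / sum(mass)
    include <- f >= eps & f <= 1 - eps
    probit <- ifelse(include, stats::qnorm(pmin(pmax(f, eps), 1 - eps)),
                     NA_real_)
  }
  structure(data.frame(hii = grid[o], f = f, probit = probit,
                       include = include),
            class = c("error_curve", "data.frame"),
            weighting = weighting, eps = eps)
}

#' @export
print.error_curve <- function(x, ...) {
  cat("Cumulative error curve (", attr(x, "weighting"), " statistic): ",
      nrow(x), " HII grid points, ", sum(x$include),
      " usable on the probit scale\n", sep = "")
  invisible(x)
}

#' Probability-paper plot of an error curve and its segmented fit
#'
#' @param x an `error_curve`.
#' @param fit optional `segmented_fit` to overlay.
#' @param ... passed to `plot()`.
#' @export
plot.error_curve <- function(x, fit = NULL, ...) {
  pts <- x[x$include, ]
  pr <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  graphics::plot(pts$hii, pts$probit, xlab = "HII",
                 ylab = "cumulative probability (%)", yaxt = "n",
                 pch = 19, col = "firebrick", ...)
  graphics::axis(2, at = stats::qnorm(pr), labels = 100 * pr)
  if (!is.null(fit)) {
    xx <- seq(min(pts$hii), max(pts$hii), length.out = 200)
    graphics::lines(xx, predict_segments(fit, xx), col = "grey30")
    graphics::abline(v = fit$breakpoints, lty = 3)
  }
  invisible(x)
}
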