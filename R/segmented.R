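#' Continuous piecewise-linear (segmented) fit of a probit error curve
#'
#' Fits `n_segments` straight lines meeting at `n_segments - 1` breakpoints
#' to the (HII, probit) points of an [error_curve()] by least squares. The
#' hinge parameterization `y = b0 + b1*x + sum_j c_j * (x - bp_j)_+`
#' enforces continuity at the breakpoints. Breakpoints are located by
#' exhaustive grid search over candidate HII values (default 0.5-HII
#' resolution, ties broken toward the leftmost breakpoints), optionally
#' followed by coordinate-wise golden-section refinement. Each segment must
#' contain at least two curve points.
#'
#' The breakpoints are the inflection points (IPs) of the error
#' inflection-point method: the HII values where the error regime changes
#' between vegetation systems.
#'
#' @param curve an `error_curve`, or any data.frame with columns `hii`,
#'   `probit` (and optionally a logical `include`).
#' @param n_segments 1, 2 or 3.
#' @param grid_res breakpoint grid resolution in HII units.
#' @param refine golden-section refinement of the grid optimum.
#' @return object of class `segmented_fit`: `n_segments`, `breakpoints`,
#'   `coef` (hinge-basis coefficients), `slopes`, `intercepts` (per
#'   segment), `rss`, `bic`, and the fitted points.
#' @export
fit_segments <- function(curve, n_segments, grid_res = 0.5, refine = TRUE) {
  pts <- curve_points(curve)
  x <- pts$x; y <- pts$y
  n_segments <- as.integer(n_segments)
  if (!n_segments %in% 1:3) stop("n_segments must be 1, 2 or 3")
  if (length(x) < 4 * n_segments)
    stop("need at least ", 4 * n_segments, " usable curve points for ",
         n_segments, " segment(s); have ", length(x))

  rss_at <- function(bp) {
    X <- cbind(1, x)
    for (b in bp) X <- cbind(X, pmax(x - b, 0))
    sum(stats::.lm.fit(X, y)$residuals^2)
  }
  seg_ok <- function(bp) {
    cnt <- tabulate(findInterval(x, c(-Inf, bp, Inf)),
                    nbins = length(bp) + 1)
    all(cnt >= 2) && all(diff(bp) > 0)
  }

  if (n_segments == 1L) {
    bp <- numeric(0)
  } else {
    cand <- seq(ceiling(min(x) / grid_res) * grid_res,
                floor(max(x) / grid_res) * grid_res, by = grid_res)
    cand <- cand[cand > min(x) & cand < max(x)]
    if (n_segments == 2L) {
      ok <- vapply(cand, function(b) seg_ok(b), logical(1))
      cand <- cand[ok]
      if (!length(cand)) stop("no admissible breakpoint candidates")
      rss <- vapply(cand, rss_at, numeric(1))
      bp <- cand[which.min(rss)]          # which.min: leftmost tie
    } else {
      best <- Inf; bp <- NULL
      for (i in seq_along(cand)) {
        for (j in seq_along(cand)) {
          if (cand[j] <= cand[i]) next
          b <- c(cand[i], cand[j])
          if (!seg_ok(b)) next
          r <- rss_at(b)
          if (r < best - 1e-15) { best <- r; bp <- b }
        }
      }
      if (is.null(bp)) stop("no admissible breakpoint pair")
    }
    if (refine) bp <- refine_breakpoints(bp, rss_at, seg_ok, grid_res)
  }
  seg_model(x, y, bp, n_segments)
}

# coordinate-wise golden-section refinement around the grid optimum
refine_breakpoints <- function(bp, rss_at, seg_ok, grid_res,
                               passes = 2, tol = 1e-6) {
  for (p in seq_len(passes)) {
    for (j in seq_along(bp)) {
      f <- function(b) {
        cand <- bp; cand[j] <- b
        if (!seg_ok(cand)) return(Inf)
        rss_at(cand)
      }
      bp[j] <- golden_min(f, bp[j] - grid_res, bp[j] + grid_res, tol)
    }
  }
  bp
}

golden_min <- function(f, lo, hi, tol = 1e-6) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    }
  }
  m <- (a + b) / 2
  if (f(m) <= min(f(lo), f(hi))) m else c(lo, hi)[which.min(c(f(lo), f(hi)))]
}

seg_model <- function(x, y, bp, n_segments) {
  X <- cbind(1, x)
  for (b in bp) X <- cbind(X, pmax(x - b, 0))
  fit <- stats::.lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  co <- fit$coefficients
  slopes <- cumsum(co[-1])
  # intercept of segment j+1 such that segments meet at bp_j:
  # a_{j+1} = a_j + (s_j - s_{j+1}) * bp_j
  intercepts <- co[1]
  for (j in seq_along(bp))
    intercepts <- c(intercepts,
                    intercepts[j] + bp[j] * (slopes[j] - slopes[j + 1]))
  structure(list(n_segments = n_segments, breakpoints = bp,
                 coef = co, slopes = unname(slopes),
                 intercepts = unname(intercepts), rss = rss,
                 bic = seg_bic(rss, length(x), n_segments),
                 n = length(x), x = x, y = y,
                 fitted.values = drop(X %*% co)),
            class = "segmented_fit")
}

# BIC with parameters = 2*nseg + (nseg - 1) + 1 (segment lines, breakpoints,
# error variance); RSS floored to avoid -Inf on noiseless constructions
seg_bic <- function(rss, n, nseg) {
  p <- 2 * nseg + (nseg - 1) + 1
  n * log(max(rss, 1e-12) / n) + p * log(n)
}

# evaluate a segmented fit at new HII values
predict_segments <- function(fit, xnew) {
  X <- cbind(1, xnew)
  for (b in fit$breakpoints) X <- cbind(X, pmax(xnew - b, 0))
  drop(X %*% fit$coef)
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented fit:", x$n_segments, "segment(s) on", x$n, "curve points\n")
  if (length(x$breakpoints))
    cat("  breakpoints (HII):",
        paste(format(x$breakpoints, digits = 4), collapse = ", "), "\n")
  cat("  RSS:", format(x$rss, digits = 4),
      " BIC:", format(x$bic, digits = 5), "\n")
  invisible(x)
}

#' @export
coef.segmented_fit <- function(object, ...) object$coef

#' Select the number of segments of an error curve by BIC
#'
#' Fits 1, 2 and 3 continuous linear segments (where the curve has enough
#' points) and returns the BIC-minimizing model. The segment count is
#' region-dependent: curves from regions without an artificial-vegetation
#' system show fewer segments.
#'
#' @inheritParams fit_segments
#' @param max_segments cap on the number of segments (default 3).
#' @return the winning `segmented_fit`, with a `candidates` element listing
#'   RSS and BIC per segment count.
#' @export
select_n_segments <- function(curve, max_segments = 3, grid_res = 0.5,
                              refine = TRUE) {
  pts <- curve_points(curve)
  fits <- list()
  for (ns in seq_len(max_segments)) {
    if (length(pts$x) < 4 * ns) break
    fits[[ns]] <- fit_segments(curve, ns, grid_res = grid_res,
                               refine = refine)
  }
  if (!length(fits)) stop("too few curve points to fit any segments")
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  best$candidates <- data.frame(n_segments = seq_along(fits),
                                rss = vapply(fits, `[[`, numeric(1), "rss"),
                                bic = bics)
  best
}

curve_points <- function(curve) {
  if (!all(c("hii", "probit") %in% names(curve)))
    stop("curve must have 'hii' and 'probit' columns")
  keep <- if ("include" %in% names(curve)) curve$include else
    !is.na(curve$probit)
  list(x = curve$hii[keep], y = curve$probit[keep])
}
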