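#' Estimate HII inflection points from transfer-function errors
#'
#' Runs the full error inflection-point procedure: for every radius in the
#' ladder and every climate variable, leave-one-out cross-validate a
#' transfer function, build the probit-scale cumulative error curve over
#' HII, and fit 1-3 continuous linear segments selecting the count by BIC.
#' The fitted breakpoints are pooled across radii and variables:
#' `ip1` (native/secondary threshold) is the mean of the first breakpoints
#' of all multi-segment base fits, and `ip2` (secondary/artificial
#' threshold) is reported only when a majority of base fits select three
#' segments. Standard deviations pool the base fits with bootstrap
#' replicates in which the per-sample (HII, |residual|) pairs are resampled
#' with replacement and the curve and segmented model refit at the selected
#' segment count.
#'
#' @param ds a [modern_dataset()].
#' @param spec a [radius_spec()] (centre + radius ladder).
#' @param variables climate variables to use (default both MAT and MAP).
#' @param method transfer-function method for the errors (default WA-PLS).
#' @param k components (WA-PLS) or analogues (MAT).
#' @param weighting error-curve weighting, see [error_curve()].
#' @param n_boot bootstrap replicates per radius x variable.
#' @param seed RNG seed for the bootstrap (mandatory when `n_boot > 0`).
#' @param max_segments cap on segment count (default 3).
#' @return object of class `ip_estimate`: `ip1`, `ip1_sd`, `ip2`, `ip2_sd`
#'   (`ip2` is `NA` when absent), `n_boot`, `fits` (per radius x variable
#'   table of selected segment counts and breakpoints), and `boot`
#'   (bootstrap breakpoints).
#' @export
estimate_ips <- function(ds, spec, variables = c("mat", "map"),
                         method = "wapls", k = NULL,
                         weighting = "error_level", n_boot = 200,
                         seed = NULL, max_segments = 3) {
  stopifnot(inherits(ds, "modern_dataset"), inherits(spec, "radius_spec"))
  if (n_boot > 0) {
    if (is.null(seed)) stop("a seed is required for the bootstrap")
    set.seed(seed)
  }
  fits <- data.frame()
  boot <- data.frame()
  for (r in spec$radii_km) {
    sub <- subset_by_radius(ds, spec, r, quiet = TRUE)
    for (v in variables) {
      cv <- loo_cv(sub, variable = v, method = method, k = k)
      curve <- error_curve(cv, sub$meta, weighting = weighting)
      sm <- select_n_segments(curve, max_segments = max_segments)
      bp <- sm$breakpoints
      fits <- rbind(fits, data.frame(
        radius_km = r, variable = v, n = nrow(sub$meta),
        n_segments = sm$n_segments,
        bp1 = if (length(bp) >= 1) bp[1] else NA_real_,
        bp2 = if (length(bp) >= 2) bp[2] else NA_real_))
      if (n_boot > 0 && sm$n_segments > 1) {
        hii <- sub$meta$hii[match(cv$sample_id, sub$meta$sample_id)]
        ar <- abs(cv$residual)
        nn <- length(ar)
        for (b in seq_len(n_boot)) {
          idx <- sample.int(nn, replace = TRUE)
          bfit <- tryCatch({
            bc <- error_curve_core(hii[idx], ar[idx], weighting,
                                   check = FALSE)
            fit_segments(bc, sm$n_segments, grid_res = 1, refine = FALSE)
          }, error = function(e) NULL)
          if (is.null(bfit)) next
          bbp <- bfit$breakpoints
          boot <- rbind(boot, data.frame(
            radius_km = r, variable = v, rep = b,
            bp1 = bbp[1],
            bp2 = if (length(bbp) >= 2) bbp[2] else NA_real_))
        }
      }
    }
  }
  multi <- fits[fits$n_segments > 1, , drop = FALSE]
  three <- fits$n_segments == 3
  ip1 <- if (nrow(multi)) mean(multi$bp1) else NA_real_
  ip1_sd <- stats::sd(c(multi$bp1, boot$bp1))
  has_ip2 <- sum(three) > nrow(fits) / 2
  ip2 <- if (has_ip2) mean(fits$bp2[three]) else NA_real_
  ip2_sd <- if (has_ip2)
    stats::sd(c(fits$bp2[three], boot$bp2[!is.na(boot$bp2)])) else NA_real_
  if (length(unique(fits$n_segments)) > 1)
    message("segment counts disagree across fits: ",
            paste(fits$n_segments, collapse = ", "))
  structure(list(ip1 = ip1, ip1_sd = ip1_sd, ip2 = ip2, ip2_sd = ip2_sd,
                 n_boot = n_boot, fits = fits, boot = boot,
                 weighting = weighting, method = method),
            class = "ip_estimate")
}

#' @export
print.ip_estimate <- function(x, ...) {
  cat("HII inflection points (", nrow(x$fits), " radius x variable fits, ",
      x$n_boot, " bootstrap reps each)\n", sep = "")
  cat("  ip1 (native/secondary):  ",
      format(x$ip1, digits = 3), " +/- ", format(x$ip1_sd, digits = 2),
      "\n", sep = "")
  if (!is.na(x$ip2))
    cat("  ip2 (secondary/artificial): ",
        format(x$ip2, digits = 3), " +/- ", format(x$ip2_sd, digits = 2),
        "\n", sep = "")
  else
    cat("  ip2: absent (majority of fits did not select 3 segments)\n")
  print(x$fits, row.names = FALSE, digits = 4)
  invisible(x)
}
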