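#' Compare transfer functions trained on HII-thresholded subsets
#'
#' Builds the full grid of leave-one-out performance for calibration sets
#' restricted to `hii <= ip1` ("native"), `hii <= ip2` (when present) and
#' all samples, across the radius ladder and climate variables. The winner
#' per variable is the cell with the lowest RMSEP (ties broken by higher
#' R2, then smaller subset). Cells retaining fewer than `min_n` samples are
#' marked unavailable rather than fitted.
#'
#' @param ds a [modern_dataset()].
#' @param ips an `ip_estimate` or numeric `c(ip1, ip2)`.
#' @param spec a [radius_spec()].
#' @param variables climate variables (default both).
#' @param method,k transfer-function settings (see [loo_cv()]).
#' @param min_n minimum subset size fitted (default 30).
#' @return object of class `training_comparison` with the grid (`table`)
#'   and per-variable `winners`.
#' @export
compare_training_sets <- function(ds, ips, spec,
                                  variables = c("mat", "map"),
                                  method = "wapls", k = NULL, min_n = 30) {
  rule <- ip_rule(ips)
  subsets <- list(native = rule[["ip1"]])
  if (!is.na(rule[["ip2"]])) subsets$up_to_ip2 <- rule[["ip2"]]
  subsets$all <- Inf
  tab <- data.frame()
  for (r in spec$radii_km) {
    geo <- subset_by_radius(ds, spec, r, quiet = TRUE)
    for (s in names(subsets)) {
      keep <- which(geo$meta$hii <= subsets[[s]])
      row_base <- data.frame(subset = s, hii_max = subsets[[s]],
                             radius_km = r, n = length(keep),
                             stringsAsFactors = FALSE)
      for (v in variables) {
        row <- row_base
        row$variable <- v
        if (length(keep) < min_n) {
          row$rmsep <- NA_real_; row$r2 <- NA_real_
          row$available <- FALSE
        } else {
          ps <- performance_stats(
            loo_cv(ds_subset(geo, keep), variable = v, method = method,
                   k = k))
          row$rmsep <- ps$rmsep; row$r2 <- ps$r2
          row$available <- TRUE
        }
        tab <- rbind(tab, row)
      }
    }
  }
  winners <- do.call(rbind, lapply(variables, function(v) {
    cand <- tab[tab$variable == v & tab$available, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand <- cand[order(cand$rmsep, -cand$r2, cand$n), , drop = FALSE]
    cand[1, ]
  }))
  structure(list(table = tab, winners = winners),
            class = "training_comparison")
}

#' @export
print.training_comparison <- function(x, ...) {
  cat("Training-set comparison (", nrow(x$table), " cells)\n", sep = "")
  cat("Winners:\n")
  print(x$winners[, c("variable", "subset", "radius_km", "n", "rmsep",
                      "r2")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Reconstruct past climate from fossil pollen with reliability flags
#'
#' Predicts the climate variable(s) for every fossil sample from fitted
#' transfer function(s) and attaches the native/nonnative reliability flag
#' from the discriminant classification. Nothing is deleted: samples from
#' nonnative phases keep their estimates but are flagged unreliable (the
#' convention of plotting them dotted).
#'
#' @param fossil a [fossil_record()] or percentage `pollen_matrix`
#'   harmonized to the models' taxa.
#' @param fc a [classify_fossil()] result aligned to the fossil samples.
#' @param mat_model,map_model fitted [wapls()] (or [modern_analogue()])
#'   models; either may be omitted.
#' @param mat_err,map_err optional per-sample errors from
#'   [bootstrap_errors()] (recycled if length 1).
#' @return data.frame of class `reconstructed_climate` with `sample_id`,
#'   `age_calbp` (when available), `mat_c`/`mat_err`, `map_mm`/`map_err`
#'   and `reliable`.
#' @export
reconstruct_climate <- function(fossil, fc, mat_model = NULL,
                                map_model = NULL, mat_err = NULL,
                                map_err = NULL) {
  pm <- if (inherits(fossil, "fossil_record")) fossil$pollen else fossil
  ids <- if (inherits(pm, "pollen_matrix")) pm$sample_ids else
    rownames(pollen_values(pm))
  if (!identical(as.character(fc$sample_id), as.character(ids)))
    stop("fossil classification is not aligned with the fossil samples")
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (inherits(fossil, "fossil_record")) out$age_calbp <- fossil$age_calbp
  add_var <- function(out, model, err, est_col, err_col) {
    if (is.null(model)) return(out)
    out[[est_col]] <- predict(model, pm)
    if (is.null(err)) err <- NA_real_
    if (any(err < 0, na.rm = TRUE)) stop("errors must be >= 0")
    out[[err_col]] <- rep_len(err, nrow(out))
    out
  }
  out <- add_var(out, mat_model, mat_err, "mat_c", "mat_err")
  out <- add_var(out, map_model, map_err, "map_mm", "map_err")
  out$reliable <- fc$call == "native"
  structure(out, class = c("reconstructed_climate", "data.frame"))
}

#' Bootstrap sample-specific reconstruction errors
#'
#' Resamples the calibration set with replacement `n_boot` times, refits
#' the transfer function and predicts the fossil samples each time. The
#' per-sample error is the standard deviation of the bootstrap predictions
#' combined in quadrature with the model's leave-one-out RMSEP. Degenerate
#' bootstrap draws (refit failure) are redrawn up to 10 times.
#'
#' @param ds calibration [modern_dataset()] (already subset to the winning
#'   training set).
#' @param variable `"mat"` or `"map"`.
#' @param fossil fossil percentages harmonized to the calibration taxa.
#' @param method,k transfer-function settings.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed RNG seed (mandatory).
#' @return list with `err` (per fossil sample), `boot_sd`, `rmsep` and
#'   `n_boot`.
#' @export
bootstrap_errors <- function(ds, variable = c("mat", "map"), fossil,
                             method = "wapls", k = NULL, n_boot = 500,
                             seed = NULL) {
  variable <- match.arg(variable)
  if (is.null(seed)) stop("a seed is required for the bootstrap")
  set.seed(seed)
  x <- switch(variable, mat = ds$meta$mat_c, map = ds$meta$map_mm)
  Y <- ds$pollen$values
  fossil_Y <- if (inherits(fossil, "fossil_record"))
    fossil$pollen else fossil
  rmsep <- performance_stats(
    loo_cv(ds, variable = variable, method = method, k = k))$rmsep
  if (is.null(k)) k <- if (method == "wapls") 2L else 5L
  n <- nrow(Y)
  preds <- matrix(NA_real_, if (inherits(fossil_Y, "pollen_matrix"))
    length(fossil_Y$sample_ids) else nrow(fossil_Y), n_boot)
  for (b in seq_len(n_boot)) {
    for (attempt in 1:10) {
      idx <- sample.int(n, replace = TRUE)
      fit <- tryCatch({
        m <- if (method == "wapls")
          wapls(Y[idx, , drop = FALSE], x[idx], k = k, warn_empty = FALSE)
        else modern_analogue(Y[idx, , drop = FALSE], x[idx], k = k)
        predict(m, fossil_Y)
      }, error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("bootstrap draw remained degenerate after 10 attempts")
    preds[, b] <- fit
  }
  boot_sd <- if (n_boot > 1) apply(preds, 1, stats::sd) else
    rep(0, nrow(preds))
  list(err = sqrt(boot_sd^2 + rmsep^2), boot_sd = boot_sd, rmsep = rmsep,
       n_boot = n_boot)
}
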