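#' Run the full error inflection point-discriminant workflow
#'
#' Orchestrates the pipeline end to end: (1) read/validate the modern and
#' fossil tables and convert to percentages; (2) estimate the HII
#' inflection points from transfer-function errors across the radius
#' ladder; (3) assign a priori groups, fit the discriminant rule on the
#' largest-radius modern subset and cross-validate it; (4) classify the
#' fossil spectra native/nonnative and merge calls into phases; (5) compare
#' HII-thresholded training sets, fit the winning calibrations, attach
#' bootstrap errors and reconstruct MAT and MAP with reliability flags.
#' Every artifact is written as a tab-separated table plus a JSON manifest
#' recording inputs, seeds and parameters; the run is byte-deterministic
#' under a fixed config.
#'
#' @param config list (or path to an R file evaluating to a list) with
#'   elements: `modern_pollen`, `modern_meta`, `fossil` (paths, or
#'   in-memory objects via `modern_dataset` / `fossil_record`),
#'   `center_lon`, `center_lat`, `radii_km`, `variables`, `method`, `k`,
#'   `weighting`, `n_boot_ip`, `n_boot_recon`, `min_run`, `seed`,
#'   `out_dir`. Missing entries fall back to module defaults.
#' @return list of class `eipdt_run` with all intermediate objects,
#'   invisibly; artifacts are written under `config$out_dir` when set.
#' @export
run_eipdt <- function(config) {
  cfg <- utils::modifyList(list(
    variables = c("mat", "map"), method = "wapls", k = NULL,
    weighting = "error_level", radii_km = c(800, 1000, 1200, 1400),
    n_boot_ip = 200, n_boot_recon = 500, min_run = 2, seed = NULL,
    out_dir = NULL), config)
  if (is.null(cfg$seed)) stop("config error: a seed is required")

  # --- inputs ---------------------------------------------------------
  ds <- if (!is.null(cfg$modern_dataset)) cfg$modern_dataset else {
    for (f in c("modern_pollen", "modern_meta"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop("config error: missing input '", f, "'")
    modern_dataset(read_table(cfg$modern_pollen, "pollen"),
                   read_table(cfg$modern_meta, "meta"))
  }
  fossil <- if (!is.null(cfg$fossil_record)) cfg$fossil_record else {
    if (is.null(cfg$fossil) || !file.exists(cfg$fossil))
      stop("config error: missing input 'fossil'")
    read_table(cfg$fossil, "fossil")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ds$pollen <- to_percentages(ds$pollen)
  ds <- modern_dataset(ds$pollen, ds$meta)
  fossil_pct <- to_percentages(fossil$pollen)
  spec <- radius_spec(cfg$center_lon, cfg$center_lat, cfg$radii_km)

  # --- inflection points ----------------------------------------------
  ips <- stage("detect-ip",
    estimate_ips(ds, spec, variables = cfg$variables, method = cfg$method,
                 k = cfg$k, weighting = cfg$weighting,
                 n_boot = cfg$n_boot_ip, seed = cfg$seed))

  # --- discriminant on the largest-radius subset ----------------------
  sub <- stage("classify",
    subset_by_radius(ds, spec, max(spec$radii_km), quiet = TRUE))
  harm <- stage("classify", harmonize_taxa(sub$pollen, fossil_pct))
  labels <- assign_groups(sub$meta, ips)
  lda_fit <- stage("classify", pollen_lda(harm$modern, labels))
  confusion <- stage("classify", loo_confusion(harm$modern, labels))
  fc <- stage("classify", classify_fossil(lda_fit, harm$fossil))
  phases <- call_phases(fc, fossil$age_calbp, min_run = cfg$min_run)

  # --- training-set comparison and reconstruction ---------------------
  comparison <- stage("compare",
    compare_training_sets(ds, ips, spec, variables = cfg$variables,
                          method = cfg$method, k = cfg$k))
  models <- errs <- list()
  for (v in cfg$variables) {
    win <- comparison$winners[comparison$winners$variable == v, ]
    geo <- subset_by_radius(ds, spec, win$radius_km, quiet = TRUE)
    train <- ds_subset(geo, which(geo$meta$hii <= win$hii_max))
    harm_t <- harmonize_taxa(to_percentages(train$pollen), fossil_pct)
    train <- modern_dataset(harm_t$modern, train$meta)
    x <- switch(v, mat = train$meta$mat_c, map = train$meta$map_mm)
    models[[v]] <- stage("reconstruct",
      wapls(train$pollen, x, k = cfg$k %||% 2, variable = v,
            warn_empty = FALSE))
    errs[[v]] <- stage("reconstruct",
      bootstrap_errors(train, v, harm_t$fossil, method = "wapls",
                       k = cfg$k, n_boot = cfg$n_boot_recon,
                       seed = cfg$seed + 1))
    models[[paste0(v, "_fossil")]] <- harm_t$fossil
  }
  recon <- stage("reconstruct", reconstruct_climate(
    fossil = models[["mat_fossil"]] %||% models[["map_fossil"]], fc = fc,
    mat_model = models[["mat"]], map_model = models[["map"]],
    mat_err = if (!is.null(errs[["mat"]])) errs[["mat"]]$err,
    map_err = if (!is.null(errs[["map"]])) errs[["map"]]$err))
  recon$age_calbp <- fossil$age_calbp

  run <- structure(list(ips = ips, labels = labels, lda = lda_fit,
                        confusion = confusion, classification = fc,
                        phases = phases, comparison = comparison,
                        models = models[cfg$variables],
                        reconstruction = recon, config = cfg),
                   class = "eipdt_run")
  if (!is.null(cfg$out_dir)) write_run_artifacts(run, cfg, spec)
  invisible(run)
}

write_run_artifacts <- function(run, cfg, spec) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$out_dir, name)
  write_eipdt_table(run$ips$fits, out("ip_fits.tsv"))
  write_eipdt_table(data.frame(ip1 = run$ips$ip1, ip1_sd = run$ips$ip1_sd,
                               ip2 = run$ips$ip2, ip2_sd = run$ips$ip2_sd),
                    out("ip_estimate.tsv"))
  write_eipdt_table(run$labels, out("group_labels.tsv"))
  write_eipdt_table(as.data.frame(run$confusion$counts),
                    out("confusion.tsv"))
  write_eipdt_table(run$classification, out("fossil_classification.tsv"))
  write_eipdt_table(run$phases, out("phases.tsv"))
  write_eipdt_table(run$comparison$table, out("training_comparison.tsv"))
  write_eipdt_table(run$reconstruction, out("reconstruction.tsv"))
  manifest <- list(
    package = "eipdt",
    package_version = as.character(utils::packageVersion("eipdt")),
    r_version = R.version.string,
    inputs = cfg[intersect(names(cfg),
                           c("modern_pollen", "modern_meta", "fossil"))],
    parameters = cfg[c("center_lon", "center_lat", "radii_km", "variables",
                       "method", "weighting", "n_boot_ip", "n_boot_recon",
                       "min_run")],
    seed = cfg$seed,
    n_modern = length(run$labels$sample_id),
    group_sizes = as.list(table(run$labels$group)),
    ip1 = run$ips$ip1, ip2 = run$ips$ip2)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(run)
}

#' @export
print.eipdt_run <- function(x, ...) {
  cat("EIPDT run\n=========\n")
  print(x$ips)
  print(x$confusion)
  print(x$comparison)
  cat("Fossil phases:\n")
  print(x$phases, row.names = FALSE)
  invisible(x)
}
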