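#' Pollen assemblage matrix
#'
#' Container for a rectangular samples-by-taxa table of pollen counts or
#' percentages. Values must be nonnegative and complete; sample ids and taxon
#' names must be unique. Percentage matrices must have rows summing to 100
#' (over the pollen-sum taxa, see [to_percentages()]) within 1e-6.
#'
#' @param values numeric matrix (samples x taxa), nonnegative, no missing cells.
#' @param sample_ids character vector of unique sample identifiers; defaults to
#'   `rownames(values)`.
#' @param taxa character vector of unique taxon names; defaults to
#'   `colnames(values)`.
#' @param basis `"counts"` or `"percentages"`.
#' @param sum_taxa taxa over which percentage rows are closed to 100; defaults
#'   to all taxa. Only consulted when `basis = "percentages"`.
#' @return An object of class `pollen_matrix`: a list with elements `values`
#'   (matrix with dimnames), `sample_ids`, `taxa`, `basis`, `sum_taxa`.
#' @export
pollen_matrix <- function(values, sample_ids = rownames(values),
                          taxa = colnames(values),
                          basis = c("counts", "percentages"),
                          sum_taxa = NULL) {
  basis <- match.arg(basis)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(taxa)) stop("taxa names are required")
  sample_ids <- as.character(sample_ids)
  taxa <- as.character(taxa)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) != nrow(values)")
  if (length(taxa) != ncol(values))
    stop("length(taxa) != ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxa))
    stop("duplicate taxon names: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyNA(values)) stop("pollen matrix contains missing cells")
  if (any(values < 0)) stop("pollen matrix contains negative values")
  dimnames(values) <- list(sample_ids, taxa)
  if (is.null(sum_taxa)) sum_taxa <- taxa
  if (!all(sum_taxa %in% taxa)) stop("sum_taxa must be a subset of taxa")
  if (basis == "percentages") {
    rs <- rowSums(values[, sum_taxa, drop = FALSE])
    bad <- abs(rs - 100) > 1e-6
    if (any(bad))
      stop("percentage rows do not sum to 100 (first offender: ",
           sample_ids[which(bad)[1]], ", sum = ",
           format(rs[which(bad)[1]]), ")")
  }
  structure(list(values = values, sample_ids = sample_ids, taxa = taxa,
                 basis = basis, sum_taxa = sum_taxa),
            class = "pollen_matrix")
}

#' @export
print.pollen_matrix <- function(x, ...) {
  cat("Pollen matrix:", length(x$sample_ids), "samples x",
      length(x$taxa), "taxa (", x$basis, ")\n")
  invisible(x)
}

#' @export
dim.pollen_matrix <- function(x) dim(x$values)

# row subset preserving class
pm_subset <- function(pm, idx) {
  pollen_matrix(pm$values[idx, , drop = FALSE],
                sample_ids = pm$sample_ids[idx], taxa = pm$taxa,
                basis = pm$basis, sum_taxa = pm$sum_taxa)
}

#' Site metadata table
#'
#' Per-sample geographic, climatic and human-influence metadata for a modern
#' pollen training set. The Human Influence Index (HII) is constrained to its
#' defined range 0-64.
#'
#' @param df data.frame with columns `sample_id`, `lon`, `lat`, `mat_c`
#'   (mean annual temperature, deg C), `map_mm` (mean annual precipitation,
#'   mm, >= 0), `hii` (0-64); optional `elev` (m) and `veg_label`.
#' @return data.frame of class `site_meta`.
#' @export
site_meta <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("sample_id", "lon", "lat", "mat_c", "map_mm", "hii")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("site metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  for (col in c("lon", "lat", "mat_c", "map_mm", "hii")) {
    if (!is.numeric(df[[col]])) stop("column '", col, "' must be numeric")
    if (anyNA(df[[col]])) stop("column '", col, "' contains missing values")
  }
  if (any(df$lon < -180 | df$lon > 180)) stop("lon outside [-180, 180]")
  if (any(df$lat < -90 | df$lat > 90)) stop("lat outside [-90, 90]")
  if (any(df$map_mm < 0)) stop("map_mm must be >= 0")
  if (any(df$hii < 0 | df$hii > 64))
    stop("hii outside [0, 64] for sample(s): ",
         paste(utils::head(df$sample_id[df$hii < 0 | df$hii > 64], 5),
               collapse = ", "))
  if (!"veg_label" %in% names(df)) df$veg_label <- NA_character_
  class(df) <- c("site_meta", "data.frame")
  df
}

#' Modern calibration dataset
#'
#' Bundles a [pollen_matrix()] with a [site_meta()] table, row-aligned by
#' sample id (the metadata is reordered to match the pollen matrix).
#'
#' @param pollen a `pollen_matrix`.
#' @param meta a `site_meta` (or data.frame coercible to one).
#' @return list of class `modern_dataset` with elements `pollen` and `meta`.
#' @export
modern_dataset <- function(pollen, meta) {
  stopifnot(inherits(pollen, "pollen_matrix"))
  if (!inherits(meta, "site_meta")) meta <- site_meta(meta)
  if (!setequal(pollen$sample_ids, meta$sample_id))
    stop("pollen and metadata sample ids do not match one-to-one")
  meta <- meta[match(pollen$sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  class(meta) <- c("site_meta", "data.frame")
  structure(list(pollen = pollen, meta = meta), class = "modern_dataset")
}

#' @export
print.modern_dataset <- function(x, ...) {
  cat("Modern pollen dataset:", length(x$pollen$sample_ids), "samples,",
      length(x$pollen$taxa), "taxa\n")
  cat("  HII range:", paste(round(range(x$meta$hii), 1), collapse = " - "),
      "| MAT:", paste(round(range(x$meta$mat_c), 1), collapse = " - "),
      "degC | MAP:", paste(round(range(x$meta$map_mm)), collapse = " - "),
      "mm\n")
  invisible(x)
}

# row subset preserving alignment
ds_subset <- function(ds, idx) {
  modern_dataset(pm_subset(ds$pollen, idx), ds$meta[idx, , drop = FALSE])
}

#' Fossil pollen record
#'
#' A stratigraphic pollen sequence with strictly increasing depth and ages
#' nondecreasing with depth (row 1 = shallowest/youngest).
#'
#' @param pollen a `pollen_matrix` for the fossil samples.
#' @param depth_cm numeric, strictly increasing.
#' @param age_calbp numeric ages (cal yr BP), finite, nondecreasing with depth.
#' @return list of class `fossil_record`.
#' @export
fossil_record <- function(pollen, depth_cm, age_calbp) {
  stopifnot(inherits(pollen, "pollen_matrix"))
  n <- length(pollen$sample_ids)
  depth_cm <- as.numeric(depth_cm)
  age_calbp <- as.numeric(age_calbp)
  if (length(depth_cm) != n || length(age_calbp) != n)
    stop("depth/age length must match the number of fossil samples")
  if (anyNA(depth_cm) || any(!is.finite(age_calbp)))
    stop("depths and ages must be finite")
  if (any(diff(depth_cm) <= 0))
    stop("depth_cm must be strictly increasing down-core")
  if (any(diff(age_calbp) < 0))
    stop("age_calbp must be nondecreasing with depth")
  structure(list(pollen = pollen, depth_cm = depth_cm, age_calbp = age_calbp),
            class = "fossil_record")
}

#' @export
print.fossil_record <- function(x, ...) {
  cat("Fossil pollen record:", length(x$pollen$sample_ids), "samples,",
      length(x$pollen$taxa), "taxa\n")
  cat("  age:", paste(round(range(x$age_calbp)), collapse = " - "),
      "cal yr BP | depth:", paste(round(range(x$depth_cm), 1),
                                  collapse = " - "), "cm\n")
  invisible(x)
}
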