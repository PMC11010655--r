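#' Convert pollen counts to percentages
#'
#' Each row is closed to 100% of its pollen sum. By default the sum runs over
#' all taxa; a subset (e.g. terrestrial taxa only) can be supplied, in which
#' case taxa outside the sum are still reported as a percentage of that sum
#' (so rows need not total 100 over all columns). Percentage input is passed
#' through unchanged (idempotent no-op).
#'
#' @param pm a [pollen_matrix()].
#' @param sum_taxa optional character vector of taxa defining the pollen sum.
#' @return a `pollen_matrix` with `basis = "percentages"`.
#' @export
to_percentages <- function(pm, sum_taxa = NULL) {
  stopifnot(inherits(pm, "pollen_matrix"))
  if (pm$basis == "percentages") return(pm)
  if (is.null(sum_taxa)) sum_taxa <- pm$taxa
  if (!all(sum_taxa %in% pm$taxa))
    stop("sum_taxa not present in the matrix: ",
         paste(setdiff(sum_taxa, pm$taxa), collapse = ", "))
  s <- rowSums(pm$values[, sum_taxa, drop = FALSE])
  if (any(s <= 0))
    stop("zero pollen sum for sample(s): ",
         paste(pm$sample_ids[s <= 0], collapse = ", "))
  pollen_matrix(100 * pm$values / s, sample_ids = pm$sample_ids,
                taxa = pm$taxa, basis = "percentages", sum_taxa = sum_taxa)
}

# trim + casefold key used for taxon matching
taxon_key <- function(x) tolower(trimws(x))

#' Harmonize taxa between a modern and a fossil pollen matrix
#'
#' Restricts both percentage matrices to their common taxa (matched by exact
#' string identity after trimming and case-folding; no synonym dictionary)
#' and re-closes every row to 100%. The report records which taxa were
#' dropped from each side and how much percentage mass each sample lost.
#'
#' @param modern,fossil `pollen_matrix` objects with `basis = "percentages"`.
#' @return list with elements `modern`, `fossil` (harmonized matrices) and
#'   `report` (dropped taxa and per-sample percentage mass dropped).
#' @export
harmonize_taxa <- function(modern, fossil) {
  stopifnot(inherits(modern, "pollen_matrix"),
            inherits(fossil, "pollen_matrix"))
  if (modern$basis != "percentages" || fossil$basis != "percentages")
    stop("both matrices must be percentages; see to_percentages()")
  km <- taxon_key(modern$taxa)
  kf <- taxon_key(fossil$taxa)
  common <- intersect(km, kf)
  if (!length(common))
    stop("no taxa in common between the modern and fossil matrices")
  im <- match(common, km)
  jf <- match(common, kf)
  close_rows <- function(pm, idx) {
    sub <- pm$values[, idx, drop = FALSE]
    s <- rowSums(sub)
    if (any(s <= 0))
      stop("sample(s) with no pollen among the shared taxa: ",
           paste(pm$sample_ids[s <= 0], collapse = ", "))
    pollen_matrix(100 * sub / s, sample_ids = pm$sample_ids,
                  taxa = pm$taxa[idx], basis = "percentages")
  }
  report <- list(
    dropped_modern = modern$taxa[-im],
    dropped_fossil = fossil$taxa[-jf],
    mass_dropped_modern = 100 - rowSums(modern$values[, im, drop = FALSE]) /
      rowSums(modern$values) * 100,
    mass_dropped_fossil = 100 - rowSums(fossil$values[, jf, drop = FALSE]) /
      rowSums(fossil$values) * 100)
  list(modern = close_rows(modern, im), fossil = close_rows(fossil, jf),
       report = report)
}
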