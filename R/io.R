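#' Read a pollen, metadata or fossil table from delimited text
#'
#' Tables are UTF-8 delimited text (comma or tab, sniffed from the header
#' line) with a header row. Schemas:
#' \describe{
#'   \item{pollen}{first column sample id, remaining columns taxa (numeric).}
#'   \item{meta}{columns `sample_id, lon, lat, elev (optional), mat_c,
#'     map_mm, hii, veg_label (optional)`.}
#'   \item{fossil}{columns `sample_id, depth_cm, age_calbp`, then taxa.}
#' }
#'
#' @param path file path.
#' @param schema one of `"pollen"`, `"meta"`, `"fossil"`.
#' @param basis for pollen/fossil tables: `"auto"` (percentages if every row
#'   sums to 100 within 1e-6, else counts), `"counts"` or `"percentages"`.
#' @return a [pollen_matrix()], [site_meta()] or [fossil_record()].
#' @export
read_table <- function(path, schema = c("pollen", "meta", "fossil"),
                       basis = c("auto", "counts", "percentages")) {
  schema <- match.arg(schema)
  basis <- match.arg(basis)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", fileEncoding = "UTF-8")
  switch(schema,
         pollen = parse_pollen_df(df, basis, path),
         meta = site_meta(check_numeric_cols(
           df, setdiff(names(df), c("sample_id", "veg_label")), path)),
         fossil = parse_fossil_df(df, basis, path))
}

# coerce listed columns to numeric, reporting row/column of any bad cell
check_numeric_cols <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("non-numeric cell in ", path, ": row ", bad[1],
             ", column '", col, "' (value '", v[bad[1]], "')")
      df[[col]] <- num
    }
  }
  df
}

df_to_pollen <- function(df, id_col, taxa_cols, basis, path) {
  df <- check_numeric_cols(df, taxa_cols, path)
  values <- as.matrix(df[, taxa_cols, drop = FALSE])
  if (basis == "auto") {
    rs <- rowSums(values)
    basis <- if (all(abs(rs - 100) <= 1e-6)) "percentages" else "counts"
  }
  pollen_matrix(values, sample_ids = df[[id_col]], taxa = taxa_cols,
                basis = basis)
}

parse_pollen_df <- function(df, basis, path) {
  if (ncol(df) < 2)
    stop("pollen table needs a sample-id column plus at least one taxon")
  df_to_pollen(df, names(df)[1], names(df)[-1], basis, path)
}

parse_fossil_df <- function(df, basis, path) {
  req <- c("sample_id", "depth_cm", "age_calbp")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("fossil table is missing required column(s): ",
         paste(miss, collapse = ", "))
  taxa_cols <- setdiff(names(df), req)
  if (!length(taxa_cols)) stop("fossil table has no taxon columns")
  df <- check_numeric_cols(df, c("depth_cm", "age_calbp"), path)
  pm <- df_to_pollen(df, "sample_id", taxa_cols, basis, path)
  fossil_record(pm, df$depth_cm, df$age_calbp)
}

#' Write a package object back to delimited text
#'
#' Writers emit tab-separated UTF-8 text with numbers at full precision, in
#' the same layouts accepted by [read_table()].
#'
#' @param x a `pollen_matrix`, `site_meta`, `fossil_record`, or data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eipdt_table <- function(x, path) {
  df <- if (inherits(x, "pollen_matrix")) {
    cbind(data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE),
          as.data.frame(x$values, check.names = FALSE))
  } else if (inherits(x, "fossil_record")) {
    cbind(data.frame(sample_id = x$pollen$sample_ids,
                     depth_cm = x$depth_cm, age_calbp = x$age_calbp,
                     stringsAsFactors = FALSE),
          as.data.frame(x$pollen$values, check.names = FALSE))
  } else {
    as.data.frame(x)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
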