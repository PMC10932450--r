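#' Summed electrolyte features of one spectrum
#'
#' Collapses a per-bin peak-area vector to the three element sums used by
#' every downstream statistic: `ca_sum` over the Ca-tagged bins, `k_sum`
#' over the K-tagged bins, `na_sum` over the Na-tagged bins. Bins tagged
#' `other` are ignored. The element tags live on the catalog, never on
#' hard-coded wavelengths.
#'
#' @param pav a `peak_area_vector` from [integrate_bins()].
#' @param catalog the [bin_catalog()] the vector was computed against.
#' @return list of class `electrolyte_features` with fields `spectrum_id`,
#'   `tissue`, `ca_sum`, `k_sum`, `na_sum` (AU).
#' @export
electrolyte_sums <- function(pav, catalog) {
  labels <- catalog_labels(catalog)
  missing_bins <- setdiff(labels, names(pav$areas))
  if (length(missing_bins)) {
    stop("peak-area vector is missing bin(s): ",
         paste(missing_bins, collapse = ", "))
  }
  el <- catalog_elements(catalog)
  a <- pav$areas[labels]
  structure(list(spectrum_id = pav$spectrum_id, tissue = pav$tissue,
                 ca_sum = sum(a[el == "Ca"]),
                 k_sum = sum(a[el == "K"]),
                 na_sum = sum(a[el == "Na"])),
            class = "electrolyte_features")
}

#' Electrolyte feature table
#'
#' Order-preserving, vectorized [electrolyte_sums()] over a peak-area table.
#'
#' @param areas a peak-area table from [preprocess_all()] (columns
#'   `spectrum_id`, `tissue`, then one column per bin label).
#' @param catalog the [bin_catalog()] the areas were computed against.
#' @return data.frame with columns `spectrum_id`, `tissue`, `ca_sum`,
#'   `k_sum`, `na_sum`.
#' @export
features_table <- function(areas, catalog) {
  stopifnot(is.data.frame(areas), nrow(areas) >= 1L)
  labels <- catalog_labels(catalog)
  missing_bins <- setdiff(labels, names(areas))
  if (length(missing_bins)) {
    stop("peak-area table is missing bin column(s): ",
         paste(missing_bins, collapse = ", "))
  }
  el <- catalog_elements(catalog)
  X <- as.matrix(areas[, labels, drop = FALSE])
  sum_over <- function(tag) {
    cols <- which(el == tag)
    if (length(cols) == 0L) return(rep(0, nrow(X)))
    rowSums(X[, cols, drop = FALSE])
  }
  data.frame(spectrum_id = areas$spectrum_id, tissue = areas$tissue,
             ca_sum = sum_over("Ca"), k_sum = sum_over("K"),
             na_sum = sum_over("Na"), stringsAsFactors = FALSE)
}

#' Write / read a feature table as CSV
#'
#' Full-precision round trip (values written with 17 significant digits).
#'
#' @param features a feature table from [features_table()].
#' @param path file path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the feature table.
#' @export
write_features <- function(features, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- features
  for (col in c("ca_sum", "k_sum", "na_sum")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = 1:2),
                          showProgress = FALSE)
  df <- data.table::setDF(dt)
  df$tissue[!nzchar(df$tissue)] <- NA_character_
  df
}
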