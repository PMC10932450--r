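#' Read spectra from a long-format CSV file
#'
#' Expects a comma-delimited UTF-8 file with header columns `spectrum_id`,
#' `tissue`, `wavelength_nm`, `intensity` (one row per wavelength sample).
#' Rows are grouped by `spectrum_id` and sorted by wavelength, so the on-disk
#' row order does not matter. Tissue labels are parsed case-insensitively;
#' empty labels give unlabelled spectra; unknown labels are an error.
#'
#' @param path file path.
#' @param catalog optional [bin_catalog()]; when supplied, each spectrum is
#'   checked with [validate_against_catalog()] and failures raise an error.
#' @return named list of [spectrum()] objects (names are the ids, in order of
#'   first appearance).
#' @export
read_spectra <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::setDF(
    data.table::fread(path, sep = ",", header = TRUE,
                      colClasses = list(character = 1:2),
                      showProgress = FALSE))
  need <- c("spectrum_id", "tissue", "wavelength_nm", "intensity")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("wavelength_nm", "intensity")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric ", col, " in ", path, " at line ",
             bad[1L] + 1L)  # +1 for the header line
      }
      data.table::set(dt, j = col, value = num)
    }
  }
  ids <- unique(dt$spectrum_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    rows <- dt[dt$spectrum_id == id, , drop = FALSE]
    rows <- rows[order(rows$wavelength_nm), , drop = FALSE]
    tis <- unique(rows$tissue)
    if (length(tis) > 1L) {
      stop("spectrum ", id, ": inconsistent tissue labels")
    }
    tis <- as_tissue_class(tis)
    sp <- tryCatch(
      spectrum(id, rows$wavelength_nm, rows$intensity, tissue = tis),
      error = function(e) stop("while parsing spectrum ", id, ": ",
                               conditionMessage(e), call. = FALSE))
    if (!is.null(catalog) && !validate_against_catalog(sp, catalog)) {
      stop("spectrum ", id, ": grid does not cover the catalog windows")
    }
    out[[id]] <- sp
  }
  out
}

#' Write spectra to a long-format CSV file
#'
#' Deterministic output: rows ordered by id then wavelength, wavelengths
#' formatted with 4 decimals, intensities with 6 significant digits. Writing
#' the same collection twice yields byte-identical files. Metadata (`meta`)
#' is not serialized.
#'
#' @param spectra nonempty list of [spectrum()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("spectra must be a nonempty list")
  }
  ids <- vapply(spectra, `[[`, character(1), "id")
  ord <- order(ids, method = "radix")
  parts <- lapply(spectra[ord], function(sp) {
    data.table::data.table(
      spectrum_id = sp$id,
      tissue = if (is.na(sp$tissue)) "" else sp$tissue,
      wavelength_nm = sprintf("%.4f", sp$wavelengths),
      intensity = sprintf("%.6g", sp$intensities)
    )
  })
  dt <- data.table::rbindlist(parts)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}
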