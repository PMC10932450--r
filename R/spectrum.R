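#' Single-shot spectrum
#'
#' One laser shot yields one spectrum: an intensity reading per wavelength on
#' a strictly increasing, uniform grid. Spectra are recorded without
#' averaging, so the natural shot-to-shot inhomogeneity of the tissue is kept.
#'
#' @param id text identifier, unique within a collection.
#' @param wavelengths strictly increasing nm values on a uniform grid.
#' @param intensities nonnegative arbitrary-unit values, same length.
#' @param tissue optional tissue label (see [as_tissue_class()]).
#' @param meta optional named list of free metadata (patient, position, seed).
#' @param validate skip invariant checks when `FALSE` (internal fast path for
#'   generated spectra that are correct by construction).
#' @return a list of class `libs_spectrum`.
#' @export
spectrum <- function(id, wavelengths, intensities, tissue = NA_character_,
                     meta = list(), validate = TRUE) {
  if (validate) {
    stopifnot(is.character(id), length(id) == 1L, nzchar(id))
    wavelengths <- as.numeric(wavelengths)
    intensities <- as.numeric(intensities)
    if (length(wavelengths) != length(intensities)) {
      stop("spectrum ", id, ": wavelengths and intensities differ in length")
    }
    if (length(wavelengths) < 2L) {
      stop("spectrum ", id, ": needs at least two samples")
    }
    d <- diff(wavelengths)
    if (any(d <= 0)) stop("spectrum ", id, ": wavelengths must be strictly increasing")
    step <- d[1L]
    if (any(abs(d - step) > 1e-9 * step)) {
      stop("spectrum ", id, ": wavelength grid must be uniform ",
           "(relative step tolerance 1e-9)")
    }
    if (any(!is.finite(intensities)) || any(intensities < 0)) {
      stop("spectrum ", id, ": intensities must be finite and nonnegative")
    }
    if (!is.na(tissue)) tissue <- as_tissue_class(tissue)
  }
  structure(list(id = id, tissue = tissue, wavelengths = wavelengths,
                 intensities = intensities, meta = meta),
            class = "libs_spectrum")
}

#' @export
print.libs_spectrum <- function(x, ...) {
  cat("<libs_spectrum> ", x$id,
      if (!is.na(x$tissue)) paste0(" [", x$tissue, "]"),
      ": ", length(x$wavelengths), " samples, ",
      sprintf("%.4f-%.4f nm", x$wavelengths[1L],
              x$wavelengths[length(x$wavelengths)]), "\n", sep = "")
  invisible(x)
}

#' Uniform grid step of a spectrum
#' @param spectrum a [spectrum()].
#' @return the grid step in nm.
#' @export
grid_step <- function(spectrum) {
  (spectrum$wavelengths[length(spectrum$wavelengths)] - spectrum$wavelengths[1L]) /
    (length(spectrum$wavelengths) - 1L)
}

#' Check that a spectrum's grid covers a catalog
#'
#' Pure predicate: `TRUE` iff the wavelength grid contains at least
#' `min_samples` samples inside every window of the catalog. Extending the
#' grid (same step, wider range) can therefore never turn a `TRUE` into a
#' `FALSE`.
#'
#' @param spectrum a [spectrum()].
#' @param catalog a [bin_catalog()].
#' @param min_samples minimum in-window sample count per bin.
#' @return logical scalar.
#' @export
validate_against_catalog <- function(spectrum, catalog, min_samples = 5L) {
  wl <- spectrum$wavelengths
  for (b in catalog$bins) {
    if (sum(wl >= b$lo_nm & wl <= b$hi_nm) < min_samples) return(FALSE)
  }
  TRUE
}
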