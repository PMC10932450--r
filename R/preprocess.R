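#' Subtract the spectrometer baseline
#'
#' The baseline is modelled as one constant per spectrum, estimated as the
#' 5th percentile of the intensities at all grid samples lying outside every
#' catalog window and outside the reference-peak window. Negatives after
#' subtraction are clipped to 0. The percentile (rather than the minimum)
#' keeps the estimate robust to line tails that leak out of the windows; one
#' constant per spectrum matches a flat spectrometer offset, and the
#' estimator sits behind this single function so a different baseline model
#' can be swapped in.
#'
#' @param spectrum a [spectrum()].
#' @param catalog a [bin_catalog()].
#' @param ref_center_nm center of the reference peak to exclude, nm.
#' @param ref_halfwidth_nm half width of the excluded reference window, nm.
#' @param probs percentile used for the estimate.
#' @return a copy of `spectrum` with the baseline removed; the estimate is
#'   recorded in `meta$baseline`.
#' @export
subtract_baseline <- function(spectrum, catalog = default_catalog(),
                              ref_center_nm = 800.0, ref_halfwidth_nm = 2.0,
                              probs = 0.05) {
  mask <- out_of_window_mask(spectrum$wavelengths, catalog,
                             ref_center_nm, ref_halfwidth_nm)
  if (!any(mask)) {
    stop("no out-of-window samples to estimate the baseline from ",
         "(catalog windows cover the whole grid)")
  }
  b <- unname(stats::quantile(spectrum$intensities[mask], probs, type = 7))
  out <- spectrum
  out$intensities <- pmax(spectrum$intensities - b, 0)
  out$meta$baseline <- b
  out
}

# logical mask of grid samples outside every catalog window and outside the
# reference-peak window
out_of_window_mask <- function(wl, catalog, ref_center_nm, ref_halfwidth_nm) {
  mask <- abs(wl - ref_center_nm) > ref_halfwidth_nm
  for (b in catalog$bins) {
    mask <- mask & (wl < b$lo_nm | wl > b$hi_nm)
  }
  mask
}

#' Normalize to the base peak intensity
#'
#' Divides every intensity by the spectrum's maximum, so the tallest feature
#' (the base peak) equals exactly 1. Removes the per-shot gain: applied after
#' baseline subtraction, the result is invariant to any positive rescaling of
#' the raw spectrum.
#'
#' @param spectrum a baseline-subtracted [spectrum()].
#' @return normalized copy; `meta$normalized` is set to `TRUE`.
#' @export
normalize_base_peak <- function(spectrum) {
  m <- max(spectrum$intensities)
  if (!is.finite(m) || m <= 0) {
    stop("spectrum ", spectrum$id, ": all-zero spectrum has no base peak")
  }
  out <- spectrum
  out$intensities <- spectrum$intensities / m
  out$meta$normalized <- TRUE
  out
}

#' Per-bin peak areas
#'
#' The area of a bin is the plain sum of the (baseline-subtracted,
#' normalized) intensities at the grid samples falling inside the bin's
#' closed window -- a discrete sample-sum without a wavelength-step factor.
#' With the base peak at 1 and about one hundred samples per window, these
#' dimensionless areas reach the tens-of-AU magnitudes of the published
#' per-class summaries.
#'
#' @param spectrum a preprocessed [spectrum()].
#' @param catalog a [bin_catalog()].
#' @return list of class `peak_area_vector` with fields `spectrum_id`,
#'   `tissue`, `areas` (named by bin label) and `normalized`.
#' @export
integrate_bins <- function(spectrum, catalog) {
  if (!validate_against_catalog(spectrum, catalog)) {
    stop("spectrum ", spectrum$id,
         ": grid does not cover the catalog windows (>= 5 samples each)")
  }
  wl <- spectrum$wavelengths
  areas <- vapply(catalog$bins, function(b) {
    sum(spectrum$intensities[wl >= b$lo_nm & wl <= b$hi_nm])
  }, numeric(1))
  names(areas) <- catalog_labels(catalog)
  structure(list(spectrum_id = spectrum$id, tissue = spectrum$tissue,
                 areas = areas,
                 normalized = isTRUE(spectrum$meta$normalized)),
            class = "peak_area_vector")
}

#' Preprocess a collection of spectra
#'
#' Applies [subtract_baseline()], [normalize_base_peak()] and
#' [integrate_bins()] to every spectrum, preserving order. Spectra that fail
#' any stage (for example all-zero shots with no base peak) are skipped with
#' a message; if every spectrum fails, that is an error.
#'
#' @param spectra nonempty list of [spectrum()] objects.
#' @param catalog a [bin_catalog()].
#' @param ref_center_nm,ref_halfwidth_nm reference-peak window passed to
#'   [subtract_baseline()].
#' @return a peak-area table: data.frame with columns `spectrum_id`,
#'   `tissue`, then one column per bin label. The number of skipped spectra
#'   is attached as attribute `n_skipped`.
#' @export
preprocess_all <- function(spectra, catalog = default_catalog(),
                           ref_center_nm = 800.0, ref_halfwidth_nm = 2.0) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("spectra must be a nonempty list")
  }
  labels <- catalog_labels(catalog)
  rows <- vector("list", length(spectra))
  skipped <- 0L
  mask_cache <- NULL
  bin_idx_cache <- NULL
  cache_key <- NULL
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    res <- tryCatch({
      wl <- sp$wavelengths
      key <- c(length(wl), wl[1L], wl[length(wl)])
      if (is.null(cache_key) || !identical(cache_key, key)) {
        cache_key <- key
        mask_cache <- out_of_window_mask(wl, catalog, ref_center_nm,
                                         ref_halfwidth_nm)
        if (!any(mask_cache)) stop("no out-of-window samples")
        bin_idx_cache <- lapply(catalog$bins, function(b) {
          which(wl >= b$lo_nm & wl <= b$hi_nm)
        })
        if (any(lengths(bin_idx_cache) < 5L)) {
          stop("grid does not cover the catalog windows")
        }
      }
      b <- unname(stats::quantile(sp$intensities[mask_cache], 0.05, type = 7))
      v <- pmax(sp$intensities - b, 0)
      m <- max(v)
      if (m <= 0) stop("all-zero spectrum has no base peak")
      v <- v / m
      areas <- vapply(bin_idx_cache, function(ix) sum(v[ix]), numeric(1))
      c(list(spectrum_id = sp$id, tissue = sp$tissue),
        as.list(stats::setNames(areas, labels)))
    }, error = function(e) {
      message("skipping spectrum ", sp$id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) skipped <- skipped + 1L else rows[[i]] <- res
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("all ", length(spectra), " spectra failed preprocessing")
  }
  if (skipped > 0L) {
    message("preprocess_all: skipped ", skipped, " of ", length(spectra),
            " spectra")
  }
  out <- data.table::setDF(data.table::rbindlist(rows))
  attr(out, "n_skipped") <- skipped
  out
}

#' Select representative spectra per class
#'
#' For each tissue class, computes the class median over every bin column
#' and returns the `k` rows closest (Euclidean distance over all bins) to
#' that median vector -- the reproducible reading of picking the shots that
#' best carry the tissue-specific median profile. Ties are broken by lexical
#' `spectrum_id` order.
#'
#' @param areas a peak-area table from [preprocess_all()].
#' @param k number of spectra to keep per class.
#' @return subset of `areas` (row order: class, then increasing distance).
#' @export
select_representative <- function(areas, k) {
  stopifnot(is.data.frame(areas), k >= 1L)
  bin_cols <- setdiff(names(areas), c("spectrum_id", "tissue"))
  if (anyNA(areas$tissue)) stop("all rows must carry a tissue label")
  pieces <- list()
  for (cl in unique(areas$tissue)) {
    sub <- areas[areas$tissue == cl, , drop = FALSE]
    if (nrow(sub) < k) {
      stop("class ", cl, " has ", nrow(sub), " spectra but k = ", k)
    }
    X <- as.matrix(sub[, bin_cols, drop = FALSE])
    med <- apply(X, 2L, stats::median)
    d <- sqrt(rowSums(sweep(X, 2L, med)^2))
    ord <- order(d, sub$spectrum_id, method = "radix")
    pieces[[cl]] <- sub[ord[seq_len(k)], , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
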