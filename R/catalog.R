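#' Emission-line bin
#'
#' A labelled integration window around one emission line. Peak areas are
#' computed per bin and later summed per element, so each bin carries the
#' element tag (`Ca`, `K`, `Na`, or `other`) as the single source of truth for
#' the electrolyte sums.
#'
#' @param label bin label (unique within a catalog).
#' @param element one of `"Ca"`, `"K"`, `"Na"`, `"other"`.
#' @param center_nm line center wavelength in nm.
#' @param lo_nm,hi_nm closed window bounds in nm; must bracket `center_nm`.
#' @return a list of class `emission_bin`.
#' @export
emission_bin <- function(label, element, center_nm, lo_nm, hi_nm) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  element <- match.arg(element, c("Ca", "K", "Na", "other"))
  center_nm <- as.numeric(center_nm)
  lo_nm <- as.numeric(lo_nm)
  hi_nm <- as.numeric(hi_nm)
  if (!(lo_nm < center_nm && center_nm < hi_nm)) {
    stop("bin ", label, ": window [", lo_nm, ", ", hi_nm,
         "] must strictly contain center ", center_nm)
  }
  structure(list(label = label, element = element, center_nm = center_nm,
                 lo_nm = lo_nm, hi_nm = hi_nm),
            class = "emission_bin")
}

#' Bin catalog
#'
#' An ordered collection of [emission_bin()]s with pairwise-disjoint windows.
#'
#' @param bins list of [emission_bin()] objects.
#' @return a list of class `bin_catalog`.
#' @export
bin_catalog <- function(bins) {
  stopifnot(is.list(bins), length(bins) >= 1L)
  ok <- vapply(bins, inherits, logical(1), "emission_bin")
  if (!all(ok)) stop("all elements must be emission_bin objects")
  labels <- vapply(bins, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate bin labels in catalog")
  lo <- vapply(bins, `[[`, numeric(1), "lo_nm")
  hi <- vapply(bins, `[[`, numeric(1), "hi_nm")
  ord <- order(lo)
  if (any(lo[ord][-1] <= hi[ord][-length(hi)])) {
    stop("catalog windows must be pairwise disjoint")
  }
  structure(list(bins = bins), class = "bin_catalog")
}

# the 15 named emission lines: 11 Ca (CaO/CaOH band region), 2 K, 2 Na
.default_lines <- list(
  Ca = c(547.89, 554.52, 560.01, 596.05, 604.21, 610.08, 616.66,
         625.88, 635.58, 643.38, 650.8),
  K  = c(765.86, 770.76),
  Na = c(589.14, 819.42)
)

#' Default bin catalog
#'
#' The catalog of the 15 discriminative emission lines used throughout the
#' pipeline: 11 Ca-associated lines (547.89--650.8 nm), the K doublet at
#' 765.86/770.76 nm, and the Na lines at 589.14/819.42 nm. Windows are
#' symmetric `center_nm +- half_width_nm`; the default +-1.0 nm keeps all 15
#' windows disjoint (the closest centers are 4.90 nm apart).
#'
#' @param half_width_nm half width of every integration window, in nm.
#' @return a [bin_catalog()].
#' @export
default_catalog <- function(half_width_nm = 1.0) {
  stopifnot(half_width_nm > 0)
  bins <- list()
  for (el in names(.default_lines)) {
    for (c_nm in .default_lines[[el]]) {
      bins[[length(bins) + 1L]] <- emission_bin(
        label = sprintf("%s_%.2f", el, c_nm), element = el,
        center_nm = c_nm,
        lo_nm = c_nm - half_width_nm, hi_nm = c_nm + half_width_nm)
    }
  }
  bin_catalog(bins)
}

#' @export
print.bin_catalog <- function(x, ...) {
  cat("<bin_catalog> ", length(x$bins), " bins (",
      paste(sprintf("%s:%d", names(table(catalog_elements(x))),
                    as.integer(table(catalog_elements(x)))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Catalog accessors
#'
#' @param catalog a [bin_catalog()].
#' @return `catalog_labels()` the bin labels; `catalog_elements()` the element
#'   tag per bin; `catalog_windows()` a data.frame with one row per bin.
#' @name catalog-accessors
#' @export
catalog_labels <- function(catalog) {
  vapply(catalog$bins, `[[`, character(1), "label")
}

#' @rdname catalog-accessors
#' @export
catalog_elements <- function(catalog) {
  vapply(catalog$bins, `[[`, character(1), "element")
}

#' @rdname catalog-accessors
#' @export
catalog_windows <- function(catalog) {
  data.frame(
    label = catalog_labels(catalog),
    element = catalog_elements(catalog),
    center_nm = vapply(catalog$bins, `[[`, numeric(1), "center_nm"),
    lo_nm = vapply(catalog$bins, `[[`, numeric(1), "lo_nm"),
    hi_nm = vapply(catalog$bins, `[[`, numeric(1), "hi_nm"),
    stringsAsFactors = FALSE
  )
}
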