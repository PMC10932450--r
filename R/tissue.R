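#' Tissue class vocabulary
#'
#' The pipeline distinguishes four study tissue classes observed in mandibular
#' cross-sections of bone-infiltrating head and neck cancer -- fibrosis,
#' inferior alveolar nerve, tumor stroma, and cell-rich tumor -- plus two
#' reference classes (healthy bone and bone-infiltrating tumor from prior
#' work) that are used only to anchor ("fix") the PCA view.
#'
#' @format `tissue_classes()` returns a character vector of the six canonical
#'   class names; `study_classes()` the four study classes;
#'   `reference_classes()` the two PCA reference classes.
#' @name tissue-classes
NULL

#' @rdname tissue-classes
#' @export
tissue_classes <- function() {
  c("fibrosis", "nerve", "tumor_stroma", "cell_rich_tumor",
    "healthy_bone_ref", "tumor_ref")
}

#' @rdname tissue-classes
#' @export
study_classes <- function() {
  c("fibrosis", "nerve", "tumor_stroma", "cell_rich_tumor")
}

#' @rdname tissue-classes
#' @export
reference_classes <- function() {
  c("healthy_bone_ref", "tumor_ref")
}

# alias table: normalized spelling -> canonical class name
.tissue_aliases <- c(
  fibrosis          = "fibrosis",
  nerve             = "nerve",
  nerve_tissue      = "nerve",
  tumor_stroma      = "tumor_stroma",
  tumour_stroma     = "tumor_stroma",
  stroma            = "tumor_stroma",
  cell_rich_tumor   = "cell_rich_tumor",
  cell_rich_tumour  = "cell_rich_tumor",
  healthy_bone_ref  = "healthy_bone_ref",
  healthy_bone      = "healthy_bone_ref",
  tumor_ref         = "tumor_ref",
  tumour_ref        = "tumor_ref"
)

#' Parse tissue labels
#'
#' Maps free-text tissue labels onto the canonical class names. Matching is
#' case-insensitive and tolerant of spaces and hyphens ("Cell-rich tumor" ->
#' `cell_rich_tumor`). Empty strings and `NA` stay `NA` (unlabelled spectra
#' are allowed); any other unknown label is an error.
#'
#' @param x character vector of labels.
#' @return character vector of canonical class names (or `NA`).
#' @export
as_tissue_class <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  nonempty <- !is.na(x) & nzchar(trimws(x))
  if (!any(nonempty)) return(out)
  key <- tolower(trimws(x[nonempty]))
  key <- gsub("[ -]+", "_", key)
  hit <- .tissue_aliases[key]
  if (anyNA(hit)) {
    bad <- unique(x[nonempty][is.na(hit)])
    stop("unknown tissue label(s): ", paste(shQuote(bad), collapse = ", "))
  }
  out[nonempty] <- unname(hit)
  out
}
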