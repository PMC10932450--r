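#' PCA on the discriminative Ca + K bins
#'
#' Mean-centered, unscaled (covariance) principal component analysis of the
#' 13 Ca- and K-tagged bin areas. Covariance PCA is deliberate: scaling all
#' bins to unit variance would preclude any single element from dominating
#' the loadings, which is exactly the structure of interest here (set
#' `scale. = TRUE` for correlation PCA). When `include_reference` is `TRUE`
#' (the default) rows of the two reference classes enter the fit, anchoring
#' ("fixing") the axes with healthy-bone and tumor reference spectra so
#' repeated fits are oriented comparably; set it to `FALSE` to fit on the
#' study classes alone. A deterministic sign convention is applied: the
#' largest-magnitude loading of each component is positive.
#'
#' @param areas a peak-area table from [preprocess_all()] (or any data.frame
#'   holding the 13 bin columns).
#' @param catalog the [bin_catalog()] naming the bins.
#' @param include_reference keep reference-class rows in the fit?
#' @param scale. unit-scale the bins (correlation PCA)?
#' @return list of class `libs_pca` with fields `center`, `rotation`
#'   (13 x q loadings, column-orthonormal), `sdev`, `explained`
#'   (variance fractions), `scale`, `bins`.
#' @export
fit_pca <- function(areas, catalog, include_reference = TRUE,
                    scale. = FALSE) {
  bins <- ca_k_bins(catalog)
  missing_bins <- setdiff(bins, names(areas))
  if (length(missing_bins)) {
    stop("peak-area table is missing bin column(s): ",
         paste(missing_bins, collapse = ", "))
  }
  if (!include_reference && "tissue" %in% names(areas)) {
    areas <- areas[!(areas$tissue %in% reference_classes()), , drop = FALSE]
  }
  if (nrow(areas) < 3L) stop("need at least 3 spectra to fit a PCA")
  X <- as.matrix(areas[, bins, drop = FALSE])
  fit <- stats::prcomp(X, center = TRUE, scale. = scale.)
  tol <- max(fit$sdev) * 1e-9
  if (sum(fit$sdev > tol) < 2L) {
    stop("peak-area matrix has rank < 2; PCA view undefined")
  }
  rotation <- fit$rotation
  # sign convention: largest-magnitude loading per component positive
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) rotation[, j] <- -rotation[, j]
  }
  structure(list(center = fit$center, rotation = rotation, sdev = fit$sdev,
                 explained = fit$sdev^2 / sum(fit$sdev^2),
                 scale = if (isTRUE(scale.)) fit$scale else NULL,
                 bins = bins),
            class = "libs_pca")
}

# labels of the Ca- and K-tagged bins, in catalog order
ca_k_bins <- function(catalog) {
  catalog_labels(catalog)[catalog_elements(catalog) %in% c("Ca", "K")]
}

#' Project peak-area vectors onto a fitted PCA
#'
#' @param model a [fit_pca()] result.
#' @param areas a peak-area table holding the model's bin columns.
#' @param n_components number of score columns to return.
#' @return data.frame with `spectrum_id` and `tissue` (when present) and
#'   score columns `PC1..PCq`.
#' @export
project <- function(model, areas, n_components = 2L) {
  missing_bins <- setdiff(model$bins, names(areas))
  if (length(missing_bins)) {
    stop("peak-area table is missing bin column(s): ",
         paste(missing_bins, collapse = ", "))
  }
  n_components <- min(n_components, ncol(model$rotation))
  X <- as.matrix(areas[, model$bins, drop = FALSE])
  Xc <- sweep(X, 2L, model$center)
  if (!is.null(model$scale)) Xc <- sweep(Xc, 2L, model$scale, "/")
  scores <- Xc %*% model$rotation[, seq_len(n_components), drop = FALSE]
  out <- as.data.frame(scores)
  rownames(out) <- NULL
  if ("tissue" %in% names(areas)) out <- cbind(tissue = areas$tissue, out)
  if ("spectrum_id" %in% names(areas)) {
    out <- cbind(spectrum_id = areas$spectrum_id, out)
  }
  out
}

#' Ranked loading report
#'
#' Bins ranked by absolute loading within each component -- which emission
#' bins drive each axis of the separation.
#'
#' @param model a [fit_pca()] result.
#' @param n_components number of components to report.
#' @return data.frame with columns `component`, `rank`, `bin`, `loading`.
#' @export
loading_report <- function(model, n_components = 2L) {
  n_components <- min(n_components, ncol(model$rotation))
  rows <- list()
  for (j in seq_len(n_components)) {
    v <- model$rotation[, j]
    ord <- order(-abs(v))
    rows[[j]] <- data.frame(component = paste0("PC", j),
                            rank = seq_along(v), bin = model$bins[ord],
                            loading = unname(v[ord]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
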