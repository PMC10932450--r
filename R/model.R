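#' Per-class intensity model for the synthetic generator
#'
#' Describes, for each tissue class, the log-normal distributions of the
#' summed Ca, K and Na peak areas, together with the spectral rendering
#' parameters shared by all classes: how each element's sum is split across
#' its bins (weight vectors), the Gaussian line width, the constant
#' spectrometer baseline, the additive noise level, the reference peak used
#' as the base peak for normalization, the quantile at which draws are
#' truncated, and the distribution of the per-shot gain.
#'
#' @param classes named list (one entry per tissue class) of lists with
#'   fields `ca`, `k`, `na`, each a [calibrate_lognormal()] result.
#' @param w_ca,w_k,w_na nonnegative weight vectors summing to 1 that split an
#'   element's drawn sum across its catalog bins (lengths must match the bin
#'   counts of the catalog in use; 11/2/2 for the default catalog).
#' @param fwhm_nm full width at half maximum of every emission line, nm.
#' @param baseline constant spectrometer baseline, AU (pre-gain).
#' @param noise_sd additive Gaussian noise standard deviation, AU (pre-gain).
#' @param ref_center_nm center of the reference peak; must lie outside every
#'   catalog window so base-peak normalization never mixes with an analyte
#'   line.
#' @param ref_height reference peak height, AU (pre-gain); every analyte line
#'   must stay below it.
#' @param trunc_q truncation quantile for the log-normal draws, in (0.9, 1].
#' @param gain_meanlog,gain_sdlog log-normal parameters of the random
#'   positive per-shot gain.
#' @return list of class `class_intensity_model`.
#' @export
class_intensity_model <- function(classes, w_ca, w_k, w_na,
                                  fwhm_nm = 1.0, baseline = 0.02,
                                  noise_sd = 2e-5,
                                  ref_center_nm = 800.0, ref_height = 1.0,
                                  trunc_q = 0.995,
                                  gain_meanlog = 0.5, gain_sdlog = 0.3) {
  stopifnot(is.list(classes), length(classes) >= 1L,
            !is.null(names(classes)))
  bad <- setdiff(names(classes), tissue_classes())
  if (length(bad)) stop("unknown tissue class(es): ", paste(bad, collapse = ", "))
  for (cl in names(classes)) {
    entry <- classes[[cl]]
    if (!all(c("ca", "k", "na") %in% names(entry))) {
      stop("class ", cl, ": needs ca, k and na parameter entries")
    }
  }
  for (w in list(w_ca, w_k, w_na)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop("bin weight vectors must be nonnegative and sum to 1")
    }
  }
  stopifnot(fwhm_nm > 0, baseline >= 0, noise_sd >= 0, ref_height > 0)
  if (!(trunc_q > 0.9 && trunc_q <= 1)) {
    stop("trunc_q must lie in (0.9, 1]")
  }
  structure(list(classes = classes, w_ca = w_ca, w_k = w_k, w_na = w_na,
                 fwhm_nm = fwhm_nm, baseline = baseline, noise_sd = noise_sd,
                 ref_center_nm = ref_center_nm, ref_height = ref_height,
                 trunc_q = trunc_q, gain_meanlog = gain_meanlog,
                 gain_sdlog = gain_sdlog),
            class = "class_intensity_model")
}

# published per-class (median, IQR) of the summed Ca and K peak areas, AU
.table1 <- list(
  fibrosis        = list(ca = c(4.973, 8.369), k = c(3.339, 1.31)),
  nerve           = list(ca = c(63.64, 15.07), k = c(1.738, 1.652)),
  tumor_stroma    = list(ca = c(30.04, 40.46), k = c(5.669, 2.812)),
  cell_rich_tumor = list(ca = c(1.974, 6.47),  k = c(6.498, 1.75))
)

# Na medians are not published (Na was not useful for discrimination); these
# encode only the qualitative profile: high Na in fibrosis and cell-rich
# tumor, low in nerve and stroma. IQR = 0.3 * median throughout.
.na_medians <- c(fibrosis = 6.0, nerve = 1.5, tumor_stroma = 2.0,
                 cell_rich_tumor = 6.0)

# reference classes for PCA fixation: qualitative stand-ins for prior-work
# spectra (healthy bone: high Ca / low K; bone-infiltrating tumor: low Ca /
# high K); synthetic values, not published ones. IQR = 0.3 * median.
.reference_levels <- list(
  healthy_bone_ref = list(ca = 80, k = 1, na = 1),
  tumor_ref        = list(ca = 2,  k = 7, na = 1)
)

#' Default calibrated model
#'
#' The four study classes are calibrated from the eight published (median,
#' IQR) pairs of summed Ca and K peak areas; Na levels and the two PCA
#' reference classes are qualitative defaults (see
#' [class_intensity_model()]). Bin weights split each element's sum uniformly
#' across its bins.
#'
#' @param catalog the [bin_catalog()] the model will be rendered against
#'   (sets the weight-vector lengths).
#' @return a [class_intensity_model()].
#' @export
default_model <- function(catalog = default_catalog()) {
  cal2 <- function(mi) calibrate_lognormal(mi[1], mi[2])
  classes <- list()
  for (cl in names(.table1)) {
    na_m <- .na_medians[[cl]]
    classes[[cl]] <- list(ca = cal2(.table1[[cl]]$ca),
                          k  = cal2(.table1[[cl]]$k),
                          na = calibrate_lognormal(na_m, 0.3 * na_m))
  }
  for (cl in names(.reference_levels)) {
    lv <- .reference_levels[[cl]]
    classes[[cl]] <- list(ca = calibrate_lognormal(lv$ca, 0.3 * lv$ca),
                          k  = calibrate_lognormal(lv$k,  0.3 * lv$k),
                          na = calibrate_lognormal(lv$na, 0.3 * lv$na))
  }
  el <- catalog_elements(catalog)
  n_ca <- sum(el == "Ca"); n_k <- sum(el == "K"); n_na <- sum(el == "Na")
  stopifnot(n_ca >= 1, n_k >= 1, n_na >= 1)
  class_intensity_model(classes,
                        w_ca = rep(1 / n_ca, n_ca),
                        w_k  = rep(1 / n_k,  n_k),
                        w_na = rep(1 / n_na, n_na))
}

#' Draw summed electrolyte areas for one class
#'
#' Samples the per-spectrum target sums (ca, k, na) from the class's
#' calibrated log-normal distributions, symmetrically truncated to the
#' model's truncation mass. Within a class the draws are stratified
#' (quantile-balanced) so the cohort's empirical medians and IQRs track the
#' calibration at the study's class sizes; the three element sums are drawn
#' independently of each other (no joint information is available for
#' them). Uses the current RNG stream.
#'
#' @param model a [class_intensity_model()].
#' @param tissue class name present in the model.
#' @param n number of draws.
#' @return numeric matrix `n x 3` with columns `ca`, `k`, `na` (AU).
#' @export
sample_sums <- function(model, tissue, n) {
  entry <- model$classes[[tissue]]
  if (is.null(entry)) stop("no model entry for tissue class ", tissue)
  cbind(ca = rlognormal_trunc(n, entry$ca, model$trunc_q),
        k  = rlognormal_trunc(n, entry$k,  model$trunc_q),
        na = rlognormal_trunc(n, entry$na, model$trunc_q))
}

#' Dataset specification for the generator
#'
#' Default class sizes are the published spectrum counts: fibrosis 254,
#' nerve 516, tumor stroma 821, cell-rich tumor 1458 (3049 in total).
#'
#' @param counts named nonnegative integer vector of spectra per class.
#' @param seed integer seed driving all generator randomness.
#' @return list of class `dataset_spec`.
#' @export
dataset_spec <- function(counts = c(fibrosis = 254, nerve = 516,
                                    tumor_stroma = 821,
                                    cell_rich_tumor = 1458),
                         seed = 42L) {
  stopifnot(!is.null(names(counts)), all(counts >= 0),
            all(counts == round(counts)))
  bad <- setdiff(names(counts), tissue_classes())
  if (length(bad)) stop("unknown tissue class(es): ", paste(bad, collapse = ", "))
  structure(list(counts = counts, seed = as.integer(seed)),
            class = "dataset_spec")
}
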