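#' Pipeline configuration
#'
#' One plain-text hierarchical (YAML) configuration carries everything the
#' pipeline needs: the wavelength grid, the bin catalog, the generator model
#' (per-class median/IQR calibration inputs plus rendering parameters) and
#' the default class counts and seed. A versioned default ships with the
#' package (`system.file("extdata", "default_config.yaml", package =
#' "libstissue")`); `default_config()` returns the same structure as a list.
#'
#' @return `default_config()` returns the configuration list.
#' @export
default_config <- function() {
  catalog <- default_catalog()
  win <- catalog_windows(catalog)
  bins <- lapply(seq_len(nrow(win)), function(i) {
    list(label = win$label[i], element = win$element[i],
         center_nm = win$center_nm[i], lo_nm = win$lo_nm[i],
         hi_nm = win$hi_nm[i])
  })
  classes <- list()
  for (cl in names(.table1)) {
    na_m <- .na_medians[[cl]]
    classes[[cl]] <- list(
      ca = list(median = .table1[[cl]]$ca[1], iqr = .table1[[cl]]$ca[2]),
      k  = list(median = .table1[[cl]]$k[1],  iqr = .table1[[cl]]$k[2]),
      na = list(median = na_m, iqr = 0.3 * na_m))
  }
  for (cl in names(.reference_levels)) {
    lv <- .reference_levels[[cl]]
    classes[[cl]] <- list(
      ca = list(median = lv$ca, iqr = 0.3 * lv$ca),
      k  = list(median = lv$k,  iqr = 0.3 * lv$k),
      na = list(median = lv$na, iqr = 0.3 * lv$na))
  }
  list(
    version = 1L,
    grid = list(lo_nm = 500.0, hi_nm = 850.0, step_nm = 0.02),
    catalog = list(bins = bins),
    model = list(classes = classes, fwhm_nm = 1.0, baseline = 0.02,
                 noise_sd = 2e-5, ref_center_nm = 800.0, ref_height = 1.0,
                 trunc_q = 0.995, gain_meanlog = 0.5, gain_sdlog = 0.3),
    counts = list(fibrosis = 254L, nerve = 516L, tumor_stroma = 821L,
                  cell_rich_tumor = 1458L),
    seed = 42L
  )
}

#' @rdname default_config
#' @param path file path of a YAML configuration.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname default_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' Build pipeline objects from a configuration
#'
#' @param config a configuration list (see [default_config()]).
#' @return `catalog_from_config()` a [bin_catalog()]; `grid_from_config()` a
#'   wavelength grid; `model_from_config()` a [class_intensity_model()].
#' @name config-objects
#' @export
catalog_from_config <- function(config) {
  bins <- lapply(config$catalog$bins, function(b) {
    emission_bin(b$label, b$element, b$center_nm, b$lo_nm, b$hi_nm)
  })
  bin_catalog(bins)
}

#' @rdname config-objects
#' @export
grid_from_config <- function(config) {
  g <- config$grid
  default_grid(g$lo_nm, g$hi_nm, g$step_nm)
}

#' @rdname config-objects
#' @export
model_from_config <- function(config) {
  m <- config$model
  catalog <- catalog_from_config(config)
  classes <- lapply(m$classes, function(entry) {
    list(ca = calibrate_lognormal(entry$ca$median, entry$ca$iqr),
         k  = calibrate_lognormal(entry$k$median,  entry$k$iqr),
         na = calibrate_lognormal(entry$na$median, entry$na$iqr))
  })
  el <- catalog_elements(catalog)
  class_intensity_model(
    classes,
    w_ca = rep(1 / sum(el == "Ca"), sum(el == "Ca")),
    w_k  = rep(1 / sum(el == "K"),  sum(el == "K")),
    w_na = rep(1 / sum(el == "Na"), sum(el == "Na")),
    fwhm_nm = m$fwhm_nm, baseline = m$baseline, noise_sd = m$noise_sd,
    ref_center_nm = m$ref_center_nm, ref_height = m$ref_height,
    trunc_q = m$trunc_q, gain_meanlog = m$gain_meanlog,
    gain_sdlog = m$gain_sdlog)
}
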