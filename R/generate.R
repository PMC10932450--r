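#' Default wavelength grid
#'
#' 500--850 nm at 0.02 nm step (17501 samples), covering all catalog windows
#' with margin. The step is chosen jointly with the sample-sum area
#' convention of [integrate_bins()]: a line of discrete-sum area A has peak
#' amplitude about A * step / (1.0645 * FWHM), and at 0.02 nm the largest
#' area reachable under the default truncated calibration stays below the
#' unit reference peak (worst case about 0.58).
#'
#' @param lo_nm,hi_nm grid range in nm.
#' @param step_nm grid step in nm.
#' @return numeric vector of wavelengths.
#' @export
default_grid <- function(lo_nm = 500.0, hi_nm = 850.0, step_nm = 0.02) {
  stopifnot(lo_nm < hi_nm, step_nm > 0)
  n <- floor((hi_nm - lo_nm) / step_nm + 1e-9)
  lo_nm + step_nm * (0:n)
}

# Gaussian line shapes evaluated on the grid, one column per catalog bin plus
# the reference peak (last column). Also returns each bin's in-window
# discrete profile sum S_b, used to convert a target discrete-sum area into a
# line amplitude (amplitude = area / S_b), which makes the generator an exact
# inverse of the measurement when noise is off.
line_basis <- function(grid, catalog, model) {
  s <- model$fwhm_nm / (2 * sqrt(2 * log(2)))
  nb <- length(catalog$bins)
  basis <- matrix(0, nrow = length(grid), ncol = nb + 1L)
  S <- numeric(nb)
  for (j in seq_len(nb)) {
    b <- catalog$bins[[j]]
    prof <- exp(-((grid - b$center_nm)^2) / (2 * s^2))
    basis[, j] <- prof
    S[j] <- sum(prof[grid >= b$lo_nm & grid <= b$hi_nm])
  }
  if (any(S <= 0)) stop("grid does not sample some catalog window")
  basis[, nb + 1L] <- exp(-((grid - model$ref_center_nm)^2) / (2 * s^2))
  list(basis = basis, S = S)
}

# order in which element weights map onto catalog bins
.element_weights <- function(model, catalog) {
  el <- catalog_elements(catalog)
  w <- numeric(length(el))
  for (tag in c("Ca", "K", "Na")) {
    wt <- switch(tag, Ca = model$w_ca, K = model$w_k, Na = model$w_na)
    idx <- which(el == tag)
    if (length(idx) != length(wt)) {
      stop("weight vector for ", tag, " has length ", length(wt),
           " but the catalog has ", length(idx), " ", tag, " bins")
    }
    w[idx] <- wt
  }
  w
}

# Render n spectra of one class. Draw order per class: sums (ca, k, na),
# gains, then noise, all on the current RNG stream.
render_class <- function(model, tissue, n, catalog, grid, lb) {
  el <- catalog_elements(catalog)
  w <- .element_weights(model, catalog)
  sums <- sample_sums(model, tissue, n)
  gains <- exp(stats::rnorm(n, model$gain_meanlog, model$gain_sdlog))
  # per-bin target areas: element sum times the bin's weight
  areas <- matrix(0, nrow = n, ncol = length(el))
  areas[, el == "Ca"] <- sums[, "ca"] %o% model$w_ca
  areas[, el == "K"]  <- sums[, "k"]  %o% model$w_k
  areas[, el == "Na"] <- sums[, "na"] %o% model$w_na
  amps <- sweep(areas, 2L, lb$S, "/")
  if (any(amps >= model$ref_height)) {
    stop("internal consistency error: drawn line amplitude reaches the ",
         "reference-peak height for class ", tissue,
         " (increase the grid density or lower the truncation quantile)")
  }
  amps <- cbind(amps, rep(model$ref_height, n))
  intens <- tcrossprod(amps, lb$basis) + model$baseline
  if (model$noise_sd > 0) {
    intens <- intens + matrix(stats::rnorm(n * length(grid), 0, model$noise_sd),
                              nrow = n)
  }
  intens <- pmax(intens * gains, 0)
  list(intensities = intens, sums = sums, gains = gains)
}

#' Generate one synthetic single-shot spectrum
#'
#' Draws the class's target summed Ca/K/Na peak areas from the calibrated,
#' truncated log-normal distributions, splits each sum across the element's
#' bins by the model weight vector, places a Gaussian line of the required
#' discrete-sum area at each bin center, adds the unit-height reference peak,
#' the constant baseline and additive Gaussian noise, and scales the whole
#' shot by a random positive gain. The generator inverts the measurement: on
#' a noise-free spectrum, baseline subtraction, base-peak normalization and
#' bin integration recover the drawn sums to near machine precision.
#'
#' @param model a [class_intensity_model()].
#' @param tissue tissue class present in the model.
#' @param catalog a [bin_catalog()].
#' @param grid wavelength grid (see [default_grid()]).
#' @param seed optional integer; when supplied the RNG is seeded so the same
#'   seed reproduces the same spectrum.
#' @param id spectrum identifier.
#' @return a [spectrum()] whose `meta` records the drawn sums and gain.
#' @export
sample_spectrum <- function(model, tissue, catalog = default_catalog(),
                            grid = default_grid(), seed = NULL,
                            id = paste0(tissue, "_0001")) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  lb <- line_basis(grid, catalog, model)
  r <- render_class(model, tissue, 1L, catalog, grid, lb)
  spectrum(id, grid, r$intensities[1L, ], tissue = tissue,
           meta = list(ca_target = unname(r$sums[1L, "ca"]),
                       k_target = unname(r$sums[1L, "k"]),
                       na_target = unname(r$sums[1L, "na"]),
                       gain = r$gains[1L]),
           validate = FALSE)
}

#' Generate a labelled synthetic dataset
#'
#' Renders `spec$counts[cl]` independent spectra per class. Each class uses
#' its own RNG substream derived from `spec$seed` and the class name, so
#' changing one class's count never perturbs the other classes' draws.
#'
#' @param model a [class_intensity_model()].
#' @param spec a [dataset_spec()].
#' @param catalog a [bin_catalog()].
#' @param grid wavelength grid.
#' @return named list of [spectrum()] objects (class order as in
#'   `spec$counts`, ids `<class>_<index>`).
#' @export
generate_dataset <- function(model = default_model(), spec = dataset_spec(),
                             catalog = default_catalog(),
                             grid = default_grid()) {
  lb <- line_basis(grid, catalog, model)
  out <- list()
  for (cl in names(spec$counts)) {
    n <- as.integer(spec$counts[[cl]])
    if (n == 0L) next
    cl_seed <- derive_seed(spec$seed, cl)
    set.seed(cl_seed)
    r <- render_class(model, cl, n, catalog, grid, lb)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%04d", cl, i)
      out[[id]] <- spectrum(id, grid, r$intensities[i, ], tissue = cl,
                            meta = list(ca_target = unname(r$sums[i, "ca"]),
                                        k_target = unname(r$sums[i, "k"]),
                                        na_target = unname(r$sums[i, "na"]),
                                        gain = r$gains[i],
                                        class_seed = cl_seed),
                            validate = FALSE)
    }
  }
  out
}

# Deterministic per-stage / per-class substream seed below 2^31.
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) %% 97651) * 21001 + h * 7 + 13) %% 2147483629L
}
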