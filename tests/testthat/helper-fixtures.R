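# Shared fixtures: a small 4-bin catalog with a matching model and a coarse
# grid, so generator/preprocessing tests run in milliseconds, plus random
# spectrum builders for the I/O round trips.

toy_catalog <- function(half_width_nm = 1.0) {
  bin_catalog(list(
    emission_bin("Ca_600.00", "Ca", 600.0, 600 - half_width_nm, 600 + half_width_nm),
    emission_bin("Ca_610.00", "Ca", 610.0, 610 - half_width_nm, 610 + half_width_nm),
    emission_bin("K_700.00",  "K",  700.0, 700 - half_width_nm, 700 + half_width_nm),
    emission_bin("Na_750.00", "Na", 750.0, 750 - half_width_nm, 750 + half_width_nm)
  ))
}

toy_grid <- function(step_nm = 0.05) default_grid(580, 780, step_nm)

# two-class model on the toy catalog; line amplitudes stay far below the
# reference peak for any truncated draw
toy_model <- function(noise_sd = 0, gain_sdlog = 0.3,
                      classes = list(
                        fibrosis = list(ca = calibrate_lognormal(3, 1),
                                        k  = calibrate_lognormal(1.2, 0.4),
                                        na = calibrate_lognormal(2, 0.6)),
                        nerve    = list(ca = calibrate_lognormal(8, 2),
                                        k  = calibrate_lognormal(0.6, 0.2),
                                        na = calibrate_lognormal(1, 0.3)))) {
  class_intensity_model(classes,
                        w_ca = c(0.5, 0.5), w_k = 1, w_na = 1,
                        noise_sd = noise_sd, gain_sdlog = gain_sdlog,
                        ref_center_nm = 770.0)
}

toy_pipeline <- function(spectra, catalog = toy_catalog()) {
  features_table(preprocess_all(spectra, catalog, ref_center_nm = 770.0),
                 catalog)
}

# random uniform-grid spectrum whose values survive the CSV formatting
# (wavelengths on a 4-decimal grid, intensities at 6 significant digits)
random_spectrum <- function(id, n = 20L, tissue = NA_character_) {
  start <- round(stats::runif(1, 400, 600), 2)
  step <- sample(c(0.05, 0.1, 0.25, 0.5), 1L)
  spectrum(id, start + step * (0:(n - 1L)),
           signif(stats::runif(n, 0, 10), 6), tissue = tissue)
}

# feature table drawn straight from a model's class distributions (no
# spectral rendering) -- the fast path for statistics-level tests
feature_draws <- function(model, counts, seed) {
  rows <- list()
  for (cl in names(counts)) {
    set.seed(seed + match(cl, tissue_classes()))
    s <- sample_sums(model, cl, counts[[cl]])
    rows[[cl]] <- data.frame(
      spectrum_id = sprintf("%s_%04d", cl, seq_len(counts[[cl]])),
      tissue = cl, ca_sum = s[, "ca"], k_sum = s[, "k"], na_sum = s[, "na"],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
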