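test_that("baseline subtraction removes a constant offset", {
  g <- toy_grid()
  flat <- spectrum("flat", g, rep(0.37, length(g)))
  out <- subtract_baseline(flat, toy_catalog(), ref_center_nm = 770)
  expect_true(all(out$intensities == 0))
  expect_equal(out$meta$baseline, 0.37)
  # shift invariance: adding a constant changes nothing downstream
  set.seed(14)
  base <- pmax(rnorm(length(g), 1, 0.2), 0)
  a <- subtract_baseline(spectrum("a", g, base), toy_catalog(),
                         ref_center_nm = 770)
  b <- subtract_baseline(spectrum("b", g, base + 5), toy_catalog(),
                         ref_center_nm = 770)
  expect_equal(a$intensities, b$intensities, tolerance = 1e-12)
})

test_that("baseline estimate matches the generator's ground truth", {
  cfg <- default_config(); cfg$model$noise_sd <- 0; cfg$model$gain_sdlog <- 0
  m <- model_from_config(cfg); m$gain_meanlog <- 0  # gain = 1
  sp <- sample_spectrum(m, "fibrosis", default_catalog(), default_grid(),
                        seed = 8)
  out <- subtract_baseline(sp, default_catalog())
  expect_equal(out$meta$baseline, 0.02, tolerance = 1e-6)
})

test_that("baseline estimation needs out-of-window samples", {
  # catalog window swallowing the whole grid (plus the reference window)
  cat_ <- bin_catalog(list(emission_bin("wide", "Ca", 600, 580, 769)))
  g <- toy_grid()
  expect_error(subtract_baseline(spectrum("s", g, rep(1, length(g))), cat_,
                                 ref_center_nm = 775,
                                 ref_halfwidth_nm = 10),
               "no out-of-window")
})

test_that("base-peak normalization scales the maximum to exactly 1", {
  sp <- spectrum("s", c(1, 2, 3, 4), c(0.5, 2.0, 1.0, 0))
  out <- normalize_base_peak(sp)
  expect_equal(out$intensities, c(0.25, 1, 0.5, 0))
  expect_identical(max(out$intensities), 1)
  # idempotence
  expect_equal(normalize_base_peak(out)$intensities, out$intensities)
  expect_error(normalize_base_peak(spectrum("z", 1:3, c(0, 0, 0))),
               "base peak")
})

test_that("preprocessing is invariant to the per-shot gain", {
  cfg <- default_config(); cfg$model$noise_sd <- 0; cfg$model$gain_sdlog <- 0
  m <- model_from_config(cfg)
  sp <- sample_spectrum(m, "tumor_stroma", default_catalog(), default_grid(),
                        seed = 12)
  scaled <- sp
  scaled$intensities <- sp$intensities * 13.7
  pp <- function(s) {
    normalize_base_peak(subtract_baseline(s, default_catalog()))$intensities
  }
  expect_equal(pp(scaled), pp(sp), tolerance = 1e-9)
})

test_that("bin integration counts in-window samples", {
  cat1 <- bin_catalog(list(emission_bin("Ca_600.00", "Ca", 600, 599, 601)))
  g <- 590 + (0:200) / 10  # exact decimals so window edges land on samples
  # all-zero spectrum
  z <- spectrum("z", g, rep(0, length(g)))
  z$meta$normalized <- TRUE
  expect_true(all(integrate_bins(z, cat1)$areas == 0))
  # unit-height rectangular pulse spanning exactly the 2 nm window
  pulse <- as.numeric(g >= 599 & g <= 601)
  expect_equal(unname(integrate_bins(spectrum("p", g, pulse), cat1)$areas),
               21)
})

test_that("Gaussian line area matches a quadrature oracle", {
  fwhm <- 1.0
  s <- fwhm / (2 * sqrt(2 * log(2)))
  gauss <- function(x) exp(-(x - 600)^2 / (2 * s^2))
  step <- 0.1
  g <- 590 + (0:200) / 10
  sp <- spectrum("g", g, gauss(g))
  # dense quadrature oracle over the default +-1 nm window; a sample-sum
  # carries the two edge samples at full weight, so the continuum limit is
  # the integral/step plus half an edge sample at each end (Euler-Maclaurin)
  cat1 <- bin_catalog(list(emission_bin("Ca_600.00", "Ca", 600, 599, 601)))
  integral <- integrate(gauss, 599, 601, rel.tol = 1e-12)$value
  oracle <- integral / step + (gauss(599) + gauss(601)) / 2
  got <- unname(integrate_bins(sp, cat1)$areas)
  expect_lt(abs(got - oracle) / oracle, 0.005)
  expect_lt(abs(got - integral / step) / (integral / step), 0.01)
  # over a wide window the closed form 1.0645 FWHM / step applies
  cat2 <- bin_catalog(list(emission_bin("Ca_600.00", "Ca", 600, 597.5,
                                        602.5)))
  got_wide <- unname(integrate_bins(sp, cat2)$areas)
  expect_lt(abs(got_wide - 1.0645 * fwhm / step) / (1.0645 * fwhm / step),
            0.005)
})

test_that("sample-sum equals trapezoid/step up to one boundary sample", {
  cat1 <- bin_catalog(list(emission_bin("Ca_600.00", "Ca", 600, 599, 601)))
  g <- 590 + (0:200) / 10
  set.seed(3)
  v <- runif(length(g))
  sp <- spectrum("r", g, v)
  inw <- g >= 599 & g <= 601
  x <- g[inw]; y <- v[inw]
  trap <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2) / 0.1
  got <- unname(integrate_bins(sp, cat1)$areas)
  expect_lte(abs(got - trap), max(y[1], y[length(y)]) + 1e-12)
})

test_that("integration requires catalog coverage", {
  cat1 <- bin_catalog(list(emission_bin("Ca_600.00", "Ca", 600, 599, 601)))
  sp <- spectrum("s", default_grid(620, 640, 0.1), rep(1, 201))
  expect_error(integrate_bins(sp, cat1), "does not cover")
})

test_that("preprocess_all preserves order and skips broken shots", {
  m <- toy_model(noise_sd = 0)
  g <- toy_grid()
  d <- generate_dataset(m, dataset_spec(c(fibrosis = 4, nerve = 3), seed = 6),
                        toy_catalog(), g)
  areas <- preprocess_all(d, toy_catalog(), ref_center_nm = 770)
  expect_equal(nrow(areas), 7L)
  expect_equal(areas$spectrum_id, names(d))
  expect_equal(attr(areas, "n_skipped"), 0L)
  # an all-zero shot among them is skipped with a message
  d$dead <- spectrum("dead", g, rep(0, length(g)), validate = FALSE)
  expect_message(
    areas2 <- preprocess_all(d, toy_catalog(), ref_center_nm = 770),
    "skipp")
  expect_equal(nrow(areas2), 7L)
  expect_equal(attr(areas2, "n_skipped"), 1L)
  # every shot failing is an error
  dead <- list(spectrum("d1", g, rep(0, length(g)), validate = FALSE))
  expect_error(suppressMessages(
    preprocess_all(dead, toy_catalog(), ref_center_nm = 770)), "all 1")
})

test_that("representative selection is nearest-to-class-median", {
  mk <- function(id, tissue, a, b) {
    data.frame(spectrum_id = id, tissue = tissue, Ca_600.00 = a,
               Ca_610.00 = b, check.names = FALSE)
  }
  # identical vectors: lexical tie-break
  df <- rbind(mk("b", "nerve", 1, 1), mk("a", "nerve", 1, 1),
              mk("c", "nerve", 1, 1))
  expect_equal(select_representative(df, 1)$spectrum_id, "a")
  # one outlier among duplicates is dropped at k = n - 1
  df2 <- rbind(mk("s1", "nerve", 1, 1), mk("s2", "nerve", 1, 1),
               mk("s3", "nerve", 1, 1), mk("out", "nerve", 9, 9))
  expect_false("out" %in% select_representative(df2, 3)$spectrum_id)
  expect_error(select_representative(df2, 5), "k = 5")
})

test_that("representative selection agrees with brute-force ranking", {
  set.seed(55)
  df <- data.frame(spectrum_id = sprintf("s%02d", 1:20), tissue = "fibrosis",
                   A = runif(20), B = runif(20), C = runif(20))
  k <- 7
  got <- select_representative(df, k)$spectrum_id
  X <- as.matrix(df[, c("A", "B", "C")])
  med <- apply(X, 2, median)
  d <- sqrt(colSums((t(X) - med)^2))
  want <- df$spectrum_id[order(d, df$spectrum_id)][1:k]
  expect_equal(got, want)
})
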