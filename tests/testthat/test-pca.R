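# random peak-area table over the 13 Ca+K bins of the default catalog
random_areas <- function(n, seed = 1) {
  set.seed(seed)
  cat_ <- default_catalog()
  bins <- catalog_labels(cat_)[catalog_elements(cat_) %in% c("Ca", "K")]
  df <- as.data.frame(matrix(rlnorm(n * 13, 0, 1), n,
                             dimnames = list(NULL, bins)))
  cbind(data.frame(spectrum_id = sprintf("s%03d", seq_len(n)),
                   tissue = "nerve"), df)
}

test_that("PCA restricts to the 13 Ca+K bins and matches an eigen oracle", {
  cat_ <- default_catalog()
  areas <- random_areas(40, seed = 2)
  fit <- fit_pca(areas, cat_)
  expect_length(fit$bins, 13L)
  expect_false(any(grepl("^Na", fit$bins)))
  # column-orthonormal loadings
  expect_equal(unname(crossprod(fit$rotation)), diag(13), tolerance = 1e-8)
  # oracle: eigendecomposition of the sample covariance
  X <- as.matrix(areas[, fit$bins])
  eig <- eigen(cov(X), symmetric = TRUE)
  expect_equal(fit$explained, eig$values / sum(eig$values),
               tolerance = 1e-8)
  for (j in 1:13) {
    v <- eig$vectors[, j]
    expect_equal(abs(sum(v * fit$rotation[, j])), 1, tolerance = 1e-6)
    # sign convention: dominant loading positive
    expect_gt(fit$rotation[which.max(abs(fit$rotation[, j])), j], 0)
  }
  # explained-variance fractions are nonincreasing and sum to <= 1
  expect_true(all(diff(fit$explained) <= 1e-12))
  expect_lte(sum(fit$explained), 1 + 1e-12)
})

test_that("duplicated points score identically; collinear data is rank 1", {
  areas <- random_areas(10, seed = 3)
  dup <- rbind(areas, areas)
  fit <- fit_pca(dup, default_catalog())
  sc <- project(fit, dup)
  expect_equal(sc$PC1[1:10], sc$PC1[11:20])
  # points on a line in 13-space
  cat_ <- default_catalog()
  bins <- catalog_labels(cat_)[catalog_elements(cat_) %in% c("Ca", "K")]
  t_ <- seq(0, 1, length.out = 12)
  dir_ <- seq_len(13)
  line <- as.data.frame(outer(t_, dir_) + 5)
  names(line) <- bins
  line <- cbind(data.frame(spectrum_id = sprintf("l%02d", 1:12),
                           tissue = "nerve"), line)
  # rank 1 means the second component vanishes -> rank < 2 is an error
  expect_error(fit_pca(line, cat_), "rank < 2")
  # adding any off-line point makes it fit, with PC1 explaining ~everything
  line2 <- line
  line2[1, bins] <- line2[1, bins] + c(1e-3, rep(0, 12))
  fit2 <- fit_pca(line2, cat_)
  expect_gt(fit2$explained[1], 1 - 1e-6)
})

test_that("projection maps the training mean to the origin", {
  areas <- random_areas(25, seed = 4)
  fit <- fit_pca(areas, default_catalog())
  center_row <- areas[1, ]
  center_row[fit$bins] <- as.list(fit$center)
  sc <- project(fit, center_row, n_components = 13)
  expect_equal(unname(unlist(sc[paste0("PC", 1:13)])), rep(0, 13),
               tolerance = 1e-10)
  # projecting the fit data reproduces prcomp's scores
  X <- as.matrix(areas[, fit$bins])
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  got <- as.matrix(project(fit, areas, n_components = 13)[paste0("PC", 1:13)])
  expect_equal(abs(got), abs(pr$x), ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(project(fit, areas[, -3]), "missing bin")
})

test_that("full reconstruction recovers the centered data", {
  areas <- random_areas(30, seed = 6)
  fit <- fit_pca(areas, default_catalog())
  X <- as.matrix(areas[, fit$bins])
  scores <- as.matrix(project(fit, areas, n_components = 13)[paste0("PC",
                                                                    1:13)])
  Xc <- sweep(X, 2, fit$center)
  expect_equal(scores %*% t(fit$rotation), Xc, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("loading report ranks all bins and is reproducible", {
  areas <- random_areas(30, seed = 8)
  fit <- fit_pca(areas, default_catalog())
  rep_ <- loading_report(fit)
  expect_setequal(rep_$bin[rep_$component == "PC1"], fit$bins)
  expect_true(all(diff(abs(rep_$loading[rep_$component == "PC1"])) <= 1e-12))
  fit2 <- fit_pca(areas, default_catalog())
  expect_identical(loading_report(fit2), rep_)
})

test_that("single-bin variance puts that bin on top of the loadings", {
  cat_ <- default_catalog()
  bins <- catalog_labels(cat_)[catalog_elements(cat_) %in% c("Ca", "K")]
  set.seed(9)
  df <- as.data.frame(matrix(1, 20, 13, dimnames = list(NULL, bins)))
  df[["K_765.86"]] <- runif(20)
  df[[bins[1]]] <- df[[bins[1]]] + rnorm(20, 0, 1e-4)  # break rank 1
  df <- cbind(data.frame(spectrum_id = sprintf("s%d", 1:20),
                         tissue = "nerve"), df)
  fit <- fit_pca(df, cat_)
  expect_equal(loading_report(fit)$bin[1], "K_765.86")
})

test_that("reference classes anchor the fit only when requested", {
  m <- default_model()
  cat_ <- default_catalog()
  g <- default_grid()
  d <- generate_dataset(m, dataset_spec(c(fibrosis = 20, nerve = 20,
                                          healthy_bone_ref = 15,
                                          tumor_ref = 15), seed = 44),
                        cat_, g)
  areas <- preprocess_all(d, cat_)
  with_ref <- fit_pca(areas, cat_, include_reference = TRUE)
  without <- fit_pca(areas, cat_, include_reference = FALSE)
  # the bone reference's huge Ca pulls the center when included
  expect_false(isTRUE(all.equal(with_ref$center, without$center)))
})

test_that("K bins dominate a top component on calibrated synthetic data", {
  m <- default_model()
  cat_ <- default_catalog()
  d <- generate_dataset(m, dataset_spec(c(fibrosis = 40, nerve = 40,
                                          tumor_stroma = 40,
                                          cell_rich_tumor = 40), seed = 13),
                        cat_, default_grid())
  areas <- preprocess_all(d, cat_)
  fit <- fit_pca(areas, cat_, include_reference = FALSE)
  rep_ <- loading_report(fit, n_components = 2)
  top2 <- function(pc) rep_$bin[rep_$component == pc][1:2]
  k_bins <- catalog_labels(cat_)[catalog_elements(cat_) == "K"]
  expect_true(all(top2("PC1") %in% k_bins) || all(top2("PC2") %in% k_bins))
})
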