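#' Run the full analysis pipeline
#'
#' Chains simulate -> preprocess -> features -> group statistics -> pairwise
#' ROC -> metric scales -> PCA and writes the report bundle to `out_dir`:
#' `areas.csv`, `features.csv`, `summary.json` (per-class median/IQR plus
#' the Kruskal--Wallis omnibus, per element), `pairwise.json` (Dunn's post
#' hoc), `roc.json` (12 pairwise ROC rows), `scales.json` (Ca and K metric
#' scales), `pca.json` (representative-only and all-spectra fits, both
#' anchored by generated reference-class spectra), `config.yaml` and
#' `manifest.json` (config hash, seed, counts, versions; no timestamp, so a
#' bundle is byte-reproducible from seed + config). Writing the raw spectra
#' table is opt-in: at default counts it is tens of millions of rows.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for all randomness (overrides the config seed).
#' @param config a configuration list or YAML path; `NULL` for
#'   [default_config()].
#' @param counts optional named vector overriding the per-class counts.
#' @param n_reference spectra generated per reference class for PCA fixation.
#' @param representative_k representative spectra per class for the
#'   representative-only PCA (capped at the smallest class size).
#' @param write_spectra_csv also write the long-format `spectra.csv`?
#' @return invisibly, a list with every intermediate result (`spectra`,
#'   `areas`, `features`, `summary`, `pairwise`, `roc`, `scales`, `pca`,
#'   `manifest`).
#' @export
run_pipeline <- function(out_dir, seed = NULL, config = NULL, counts = NULL,
                         n_reference = 50L, representative_k = 50L,
                         write_spectra_csv = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config)) config <- default_config()
  if (is.null(seed)) seed <- config$seed
  seed <- as.integer(seed)
  catalog <- catalog_from_config(config)
  grid <- grid_from_config(config)
  model <- model_from_config(config)
  if (is.null(counts)) counts <- unlist(config$counts)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(...) message("[run_pipeline] ", ...)
  result <- list()
  failed <- function(stage_name, e) {
    stop("pipeline stage '", stage_name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # -- simulate ------------------------------------------------------------
  spectra <- tryCatch({
    gspec <- dataset_spec(counts = counts, seed = seed)
    ref <- dataset_spec(counts = stats::setNames(rep(n_reference, 2L),
                                                 reference_classes()),
                        seed = derive_seed(seed, "reference"))
    c(generate_dataset(model, gspec, catalog, grid),
      generate_dataset(model, ref, catalog, grid))
  }, error = function(e) failed("simulate", e))
  stage("simulate: ", length(spectra), " spectra (",
        sum(counts), " study + ", 2L * n_reference, " reference)")
  if (write_spectra_csv) {
    write_spectra(spectra, file.path(out_dir, "spectra.csv"))
  }

  # -- preprocess ----------------------------------------------------------
  areas <- tryCatch(preprocess_all(spectra, catalog,
                                   ref_center_nm = model$ref_center_nm),
                    error = function(e) failed("preprocess", e))
  stage("preprocess: ", nrow(areas), " peak-area vectors, ",
        attr(areas, "n_skipped"), " skipped")
  data.table::fwrite(areas, file.path(out_dir, "areas.csv"), quote = FALSE)

  # -- features ------------------------------------------------------------
  features <- tryCatch(features_table(areas, catalog),
                       error = function(e) failed("features", e))
  write_features(features, file.path(out_dir, "features.csv"))
  study <- features[features$tissue %in% study_classes(), , drop = FALSE]
  stage("features: ", nrow(features), " rows (", nrow(study), " study)")

  # -- group statistics ----------------------------------------------------
  summary_out <- list(); pairwise_out <- list()
  for (el in c("Ca", "K")) {
    groups <- element_groups(study, el)
    kw <- tryCatch(kruskal_wallis(groups),
                   error = function(e) failed("stats", e))
    summary_out[[el]] <- list(groups = summarize_groups(study, el),
                              kruskal_wallis = list(H = kw$H, df = kw$df,
                                                    p = kw$p))
    pairwise_out[[el]] <- dunn_posthoc(groups)
  }
  stage("stats: Kruskal-Wallis p(Ca) = ",
        format(summary_out$Ca$kruskal_wallis$p, digits = 3),
        ", p(K) = ", format(summary_out$K$kruskal_wallis$p, digits = 3))

  # -- ROC and scales ------------------------------------------------------
  roc <- tryCatch(pairwise_roc_report(study),
                  error = function(e) failed("roc", e))
  scales <- tryCatch(
    list(Ca = build_metric_scale(study, "Ca"),
         K = build_metric_scale(study, "K")),
    error = function(e) failed("scale", e))
  stage("roc: ", nrow(roc), " pairwise rows; scales: Ca (",
        paste(format(scales$Ca$cutoffs, digits = 4), collapse = ", "),
        "), K (", paste(format(scales$K$cutoffs, digits = 4),
                        collapse = ", "), ")")

  # -- PCA -----------------------------------------------------------------
  pca <- tryCatch({
    k_rep <- min(representative_k,
                 min(table(study$tissue)[study_classes()]))
    study_areas <- areas[areas$tissue %in% study_classes(), , drop = FALSE]
    ref_areas <- areas[areas$tissue %in% reference_classes(), , drop = FALSE]
    rep_areas <- rbind(select_representative(study_areas, k_rep), ref_areas)
    fit_rep <- fit_pca(rep_areas, catalog, include_reference = TRUE)
    fit_all <- fit_pca(areas, catalog, include_reference = TRUE)
    list(representative = list(explained = fit_rep$explained,
                               loadings = loading_report(fit_rep),
                               scores = project(fit_rep, rep_areas)),
         all = list(explained = fit_all$explained,
                    loadings = loading_report(fit_all),
                    scores = project(fit_all, areas)))
  }, error = function(e) failed("pca", e))
  stage("pca: representative + all fits, PC1 explains ",
        sprintf("%.1f%%", 100 * pca$all$explained[1L]), " (all spectra)")

  # -- bundle --------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    package = "libstissue",
    package_version = as.character(utils::packageVersion("libstissue")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    counts = as.list(counts),
    n_reference = n_reference,
    representative_k = representative_k,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_spectra = length(spectra),
    n_skipped = attr(areas, "n_skipped")
  )
  wj <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  wj(summary_out, "summary.json")
  wj(pairwise_out, "pairwise.json")
  wj(roc, "roc.json")
  wj(lapply(scales, unclass), "scales.json")
  wj(pca, "pca.json")
  wj(manifest, "manifest.json")
  stage("bundle written to ", out_dir)

  invisible(list(spectra = spectra, areas = areas, features = features,
                 summary = summary_out, pairwise = pairwise_out, roc = roc,
                 scales = scales, pca = pca, manifest = manifest))
}
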