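#!/usr/bin/env Rscript

# Stage 4: PCA views of the 13 discriminative Ca + K bin areas.
#
# Two covariance-PCA fits, both anchored by the reference-class spectra
# (healthy bone, bone-infiltrating tumor): one on representative spectra
# only (the 25 shots per study class closest to their class median profile),
# one on all spectra. Exports explained variance, ranked loadings, and the
# first-two-component scores of the representative fit.

suppressMessages(library(libstissue))

catalog <- default_catalog()
areas <- data.table::setDF(data.table::fread("scratch/areas.csv",
                                             showProgress = FALSE))
dir.create("results", showWarnings = FALSE)

study_areas <- areas[areas$tissue %in% study_classes(), ]
ref_areas <- areas[areas$tissue %in% reference_classes(), ]
rep_areas <- rbind(select_representative(study_areas, 25), ref_areas)

fit_rep <- fit_pca(rep_areas, catalog, include_reference = TRUE)
fit_all <- fit_pca(areas, catalog, include_reference = TRUE)

explained <- rbind(
  data.frame(fit = "representative", component = paste0("PC", 1:13),
             fraction = fit_rep$explained),
  data.frame(fit = "all", component = paste0("PC", 1:13),
             fraction = fit_all$explained))
write.csv(explained, "results/pca_explained.csv", row.names = FALSE)

loadings <- rbind(cbind(fit = "representative", loading_report(fit_rep)),
                  cbind(fit = "all", loading_report(fit_all)))
write.csv(loadings, "results/pca_loadings.csv", row.names = FALSE)

scores <- project(fit_rep, rep_areas)
write.csv(scores, "results/pca_scores_representative.csv", row.names = FALSE)

for (f in list(representative = fit_rep, all = fit_all)) {
  message(sprintf("PC1 %.1f%% / PC2 %.1f%% of variance",
                  100 * f$explained[1], 100 * f$explained[2]))
}
top <- loading_report(fit_all, 2)
message("top |loading| bins: PC1 ",
        paste(head(top$bin[top$component == "PC1"], 3), collapse = ", "),
        "; PC2 ",
        paste(head(top$bin[top$component == "PC2"], 3), collapse = ", "))
message("wrote results/pca_explained.csv, results/pca_loadings.csv, ",
        "results/pca_scores_representative.csv")
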