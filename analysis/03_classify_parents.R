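#!/usr/bin/env Rscript
# Stage 3: parent classification per characterization component.
# Outlier screening, 0-1 standardization, PCA on the parents with
# variable contributions, PC-contribution descriptor weights, and a
# 100-tree random forest (stratified 70/30) with OOB error, importances
# and the parent confusion matrix.
#
# Reads:  results/panel_long.csv
# Writes: results/pca_contributions.csv, results/descriptor_weights.csv,
#         results/importances.csv, results/confusion_parents.csv,
#         results/classification_summary.csv, results/outlier_flags.csv

suppressMessages(library(phenoprop))
seed <- 20240116
panel <- read.csv("results/panel_long.csv")

summary_rows <- list(); contrib_rows <- list(); weight_rows <- list()
imp_rows <- list(); conf_rows <- list(); flag_rows <- list()

for (comp in unique(panel$component)) {
  wide <- panel_wide(panel, comp)
  scr <- screen_panel(wide)
  flag_rows[[comp]] <- cbind(component = comp, scr$flags)
  w <- scr$clean
  desc <- setdiff(names(w), c("unit_id", "class", ".latent"))
  parents <- w$class != "hybrid"

  sc <- minmax_standardize(w[, desc])
  pca <- fit_pca(sc$values[parents, ])
  npc <- retained_pcs(pca)
  cn <- pca$contributions[, seq_len(npc), drop = FALSE]
  contrib_rows[[comp]] <- data.frame(
    component = comp,
    descriptor = rep(rownames(cn), ncol(cn)),
    pc = rep(colnames(cn), each = nrow(cn)),
    contribution_pct = round(as.vector(cn), 3),
    evr = rep(round(pca$explained_variance_ratio[seq_len(npc)], 4),
              each = nrow(cn)),
    row.names = NULL)
  wts <- descriptor_weights(pca)
  weight_rows[[comp]] <- data.frame(component = comp,
                                    descriptor = names(wts),
                                    weight = unname(wts))

  fr <- train_forest(sc$values[parents, ], w$class[parents],
                     seed = seed)
  sel <- suppressWarnings(select_features(fr, gini_min = 0,
                                          mda_min = 0.001))
  imp_rows[[comp]] <- data.frame(
    component = comp, descriptor = names(fr$importance_mda),
    mda = unname(fr$importance_mda),
    gini = unname(fr$importance_gini),
    selected = names(fr$importance_mda) %in% sel)
  cm <- as.data.frame(fr$confusion)
  conf_rows[[comp]] <- cbind(component = comp, cm)
  summary_rows[[comp]] <- data.frame(
    component = comp, n_units = nrow(w),
    n_flagged = sum(scr$flags$flagged), retained_pcs = npc,
    oob_error_pct = fr$oob_error,
    validation_accuracy_pct = 100 * sum(diag(fr$confusion)) /
      sum(fr$confusion))
  cat(sprintf("%-11s OOB %5.2f%%  retained PCs %d  flagged %d\n", comp,
              fr$oob_error, npc, sum(scr$flags$flagged)))
}

write.csv(do.call(rbind, contrib_rows), "results/pca_contributions.csv",
          row.names = FALSE)
write.csv(do.call(rbind, weight_rows), "results/descriptor_weights.csv",
          row.names = FALSE)
write.csv(do.call(rbind, imp_rows), "results/importances.csv",
          row.names = FALSE)
write.csv(do.call(rbind, conf_rows), "results/confusion_parents.csv",
          row.names = FALSE)
write.csv(do.call(rbind, flag_rows), "results/outlier_flags.csv",
          row.names = FALSE)
write.csv(do.call(rbind, summary_rows),
          "results/classification_summary.csv", row.names = FALSE)
cat("wrote classification tables under results/\n")
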