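# Step 6 — predict cognitive components from nodal graph measures.
#
# Kernel ridge regression (linear kernel) with nested 5-fold
# cross-validation: inner folds choose the ridge penalty, outer folds give
# pooled out-of-fold predictions; permutation testing (1000 target
# permutations) yields a p-value per model; primal weights rank the nodes
# driving each prediction. The four degree models restate the one-way
# dissociation: both working-memory-network models and the
# reasoning-to-reasoning model should be significant, reasoning-to-working-
# memory should not.

source("analysis/00_common.R")

study <- study_cohort()
comp <- patient_components(study)
tbl <- metric_table(study$sim$connectomes[study$pat], study$networks,
                    study$scheme, levels = 2.5)

rows <- list()
for (metric in c("degree", "local_efficiency")) {
  for (net in c("working_memory", "reasoning")) {
    X <- nodal_matrix(tbl, net, metric)[study$pat, ]
    for (target in c("WM", "RSN")) {
      pv <- permutation_pvalue(X, comp$scores[study$pat, target],
                               n_perm = 1000, seed = study_seed)
      res <- pv$observed
      rows[[length(rows) + 1L]] <- data.frame(
        network = net, metric = metric, target = target,
        r = res$r, p = pv$p, R2 = res$R2, mse = res$mse, nmse = res$nmse)
      if (metric == "degree") {
        top <- compute_weights(res)
        top <- top$node[top$rank <= 5]
        cat(sprintf("%-14s %-16s -> %-3s r = %5.2f  p = %.3f  top nodes: %s\n",
                    net, metric, target, res$r, pv$p,
                    paste(top, collapse = ", ")))
      } else {
        cat(sprintf("%-14s %-16s -> %-3s r = %5.2f  p = %.3f\n",
                    net, metric, target, res$r, pv$p))
      }
    }
  }
}
out <- do.call(rbind, rows)
utils::write.csv(out, file.path(results_dir, "prediction_models.csv"),
                 row.names = FALSE)
cat("Wrote results/prediction_models.csv\n")
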