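# Step 3 — derive the cognitive components.
#
# Patient task scores are residualised against age, age^2 and age^3,
# rank-inverse-normal transformed, and decomposed by PCA with varimax
# rotation under the Kaiser (eigenvalue > 1) retention rule. The expected
# outcome is two components: reasoning (FTM/OOO/HTT) and working memory
# (MKL/PAL/SOS).

source("analysis/00_common.R")

study <- study_cohort()
comp <- patient_components(study)

print(comp$model)
cong <- factor_congruence(planted_loading_pattern(study$cfg),
                          comp$model$loadings[, 1:2])
cat(sprintf("Congruence with the planted loading pattern: %.3f, %.3f\n",
            cong[1], cong[2]))

utils::write.csv(as.data.frame(comp$model$loadings),
                 file.path(results_dir, "pca_loadings.csv"))
utils::write.csv(data.frame(subject_id = rownames(comp$scores),
                            comp$scores, check.names = FALSE),
                 file.path(results_dir, "component_scores.csv"),
                 row.names = FALSE)
cat("Wrote results/pca_loadings.csv, results/component_scores.csv\n")
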