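# Step 4 — cross-sectional group comparisons and metric-component
# correlations.
#
# The 12 global measures (2 networks x 3 metrics, patients vs controls) are
# compared by pooled-variance t-tests with FDR correction; global and nodal
# measures are then correlated with the two cognitive components in
# patients, including the cross-paired combinations, with FDR within the
# analysis families (one family for the 12 global correlations; per
# network x metric x component across nodes for nodal measures).

source("analysis/00_common.R")

study <- study_cohort()
comp <- patient_components(study)
tbl <- metric_table(study$sim$connectomes, study$networks, study$scheme,
                    levels = 2.5)

# --- group comparisons of the global measures -------------------------------
glob <- tbl[is.na(tbl$node), ]
glob$measure <- paste(glob$network, glob$metric, sep = ":")
subjects <- unique(glob$subject_id)
measures <- unique(glob$measure)
wide <- matrix(NA_real_, length(subjects), length(measures),
               dimnames = list(subjects, measures))
wide[cbind(match(glob$subject_id, subjects),
           match(glob$measure, measures))] <- glob$value
grp <- ifelse(rownames(wide) %in% study$ctrl, "control", "patient")
cmp <- group_compare(wide, grp)
cmp <- cmp[order(cmp$p), ]
utils::write.csv(cmp, file.path(results_dir, "group_comparisons.csv"),
                 row.names = FALSE)
cat("Global group comparisons (q < 0.05 in", sum(cmp$q < 0.05, na.rm = TRUE),
    "of", nrow(cmp), "measures):\n")
print(cmp[1:6, c("measure", "t", "q", "direction")], row.names = FALSE)

# --- correlations with the cognitive components -----------------------------
pat_tbl <- tbl[tbl$subject_id %in% study$pat, ]
cors <- correlate_metrics_components(pat_tbl, comp$scores)
utils::write.csv(cors, file.path(results_dir, "metric_component_correlations.csv"),
                 row.names = FALSE)

glob_cors <- cors[cors$family == "global", ]
cat("\nGlobal metric-component correlations (12 tests, one FDR family):\n")
print(glob_cors[order(glob_cors$network, glob_cors$metric),
                c("network", "metric", "component", "r", "q")],
      row.names = FALSE, digits = 3)

nod <- cors[grepl("^nodal", cors$family) & cors$metric == "degree", ]
sig_frac <- tapply(nod$q < 0.05, list(nod$network, nod$component), mean)
cat("\nFraction of nodes with q < 0.05 degree-component correlations:\n")
print(round(sig_frac, 2))
cat("\nPlanted expectation: each network relates to its own component, the\n")
cat("working-memory network additionally to the reasoning component, and\n")
cat("the reasoning network never to working memory. The cross path\n")
cat("(working-memory net -> reasoning component) is the weakest planted\n")
cat("effect and can fall below the FDR threshold in a single cohort.\n")
cat("Wrote results/group_comparisons.csv, results/metric_component_correlations.csv\n")
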