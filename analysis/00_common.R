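# Shared setup for the numbered analysis scripts: one synthetic study
# cohort under the default (asymmetric-coupling) generative conditions.
# Every script re-derives this deterministically from the same seed, so the
# steps can be run independently.

library(netcog)

study_seed <- 1L
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

study_cohort <- function() {
  cfg <- generator_config(seed = study_seed)
  sim <- simulate_cohort(cfg)
  ctrl <- sim$subjects$subject_id[sim$subjects$group == "control"]
  pat <- sim$subjects$subject_id[sim$subjects$group == "patient"]
  scheme <- fit_threshold_scheme(sim$connectomes[ctrl])
  list(cfg = cfg, sim = sim, ctrl = ctrl, pat = pat, scheme = scheme,
       networks = fixture_subnetworks(sim$fixture))
}

# Patient cognitive components: age-detrended, rank-normalised task scores
# followed by varimax-rotated PCA, labelled against the planted pattern.
patient_components <- function(study) {
  pc <- study$sim$cohort[study$sim$cohort$group == "patient", ]
  pp <- preprocess_scores(pc[task_codes()], pc$age)
  rownames(pp) <- pc$subject_id
  model <- pca_varimax(pp)
  list(model = model, scores = label_components(model, study$cfg),
       preprocessed = pp)
}
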