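#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of the generative model. The
#' defaults are the package's study conditions: a control group of 105 and a
#' patient group of 92 (the cohort sizes of the motivating TBI study),
#' typical skeletonised fractional-anisotropy statistics, a one-SD global
#' white-matter deficit in patients, and the asymmetric coupling preset in
#' which working-memory-subnetwork integrity drives both latent abilities
#' while reasoning-subnetwork integrity drives reasoning only
#' (`coupling_rsn_to_wm = 0`).
#'
#' @param n_controls,n_patients Group sizes.
#' @param edge_density Fraction of atlas region pairs connected by a tract.
#' @param fa_mean,fa_sd Mean and SD of control edge fractional anisotropy;
#'   values are truncated to (0, 1) by resampling.
#' @param patient_global_deficit Mean FA reduction in patients, in `fa_sd`
#'   units, applied to every existing connection (diffuse injury).
#' @param bio_sd Between-subject biological variation of subnetwork
#'   integrity (SD of a Gaussian per-subject, per-subnetwork FA offset in
#'   `fa_sd` units, applied to tracts exclusive to each subnetwork; all
#'   subjects). This is the individual-differences signal that couples to
#'   cognition in controls as well as patients.
#' @param subnet_deficit_sd Scale of the half-normal subject-specific
#'   subnetwork degradation factors (in `fa_sd` units; patients only),
#'   applied to tracts exclusive to each subnetwork's induced subgraph.
#' @param coupling_wm_to_wm,coupling_wm_to_rsn,coupling_rsn_to_rsn,coupling_rsn_to_wm
#'   Standardised effects of subnetwork integrity on the latent working
#'   memory and reasoning abilities.
#' @param age_beta1,age_beta2,age_beta3 Polynomial age trend coefficients on
#'   standardised age `z = (age - 50) / 15`, added to every task score.
#' @param noise_sd Residual SD of the latent abilities.
#' @param task_loadings Named loadings (0.6-0.8 by default) of the six tasks;
#'   MKL/PAL/SOS load on working memory, FTM/OOO/HTT on reasoning. Task
#'   residual SD is `sqrt(1 - loading^2)` so scores are approximately
#'   unit-variance.
#' @param seed Integer seed; all stochastic generator operations derive
#'   their streams from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_controls = 105L,
                             n_patients = 92L,
                             edge_density = 0.3,
                             fa_mean = 0.45,
                             fa_sd = 0.06,
                             patient_global_deficit = 1.0,
                             bio_sd = 1.0,
                             subnet_deficit_sd = 1.5,
                             coupling_wm_to_wm = 0.8,
                             coupling_wm_to_rsn = 0.6,
                             coupling_rsn_to_rsn = 0.8,
                             coupling_rsn_to_wm = 0.0,
                             age_beta1 = -0.20,
                             age_beta2 = -0.05,
                             age_beta3 = 0.02,
                             noise_sd = 0.7,
                             task_loadings = c(MKL = 0.8, PAL = 0.7,
                                               SOS = 0.6, FTM = 0.8,
                                               OOO = 0.7, HTT = 0.6),
                             seed = 1L) {
  if (!is.numeric(fa_sd) || fa_sd <= 0) {
    stop("fa_sd must be positive")
  }
  stopifnot(
    n_controls >= 1, n_patients >= 0,
    edge_density > 0, edge_density <= 1,
    fa_mean > 0, fa_mean < 1,
    bio_sd >= 0,
    subnet_deficit_sd >= 0,
    noise_sd >= 0,
    is.finite(c(coupling_wm_to_wm, coupling_wm_to_rsn,
                coupling_rsn_to_rsn, coupling_rsn_to_wm)),
    setequal(names(task_loadings), task_codes()),
    all(abs(task_loadings) <= 1)
  )
  cfg <- list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    edge_density = edge_density, fa_mean = fa_mean, fa_sd = fa_sd,
    patient_global_deficit = patient_global_deficit,
    bio_sd = bio_sd,
    subnet_deficit_sd = subnet_deficit_sd,
    coupling_wm_to_wm = coupling_wm_to_wm,
    coupling_wm_to_rsn = coupling_wm_to_rsn,
    coupling_rsn_to_rsn = coupling_rsn_to_rsn,
    coupling_rsn_to_wm = coupling_rsn_to_wm,
    age_beta1 = age_beta1, age_beta2 = age_beta2, age_beta3 = age_beta3,
    noise_sd = noise_sd,
    task_loadings = task_loadings[task_codes()],
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

#' The six computerised task codes
#'
#' @return `c("MKL", "PAL", "SOS", "FTM", "OOO", "HTT")`; the first three are
#'   working-memory tasks, the last three reasoning tasks.
#' @export
task_codes <- function() c("MKL", "PAL", "SOS", "FTM", "OOO", "HTT")

# Normal draws truncated to (0, 1) by resampling out-of-range values,
# preserving the physical range of fractional anisotropy.
rtruncnorm01 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0 | x >= 1)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean, sd)
    bad <- bad[x[bad] <= 0 | x[bad] >= 1]
  }
  x
}

#' Simulate per-subject FA connectivity matrices
#'
#' Draws, for every subject, a symmetric 90 x 90 matrix of edge fractional
#' anisotropy over the atlas tracts. Edge FA follows a truncated
#' Normal(`fa_mean`, `fa_sd`); every subject additionally carries a Gaussian
#' biological offset per subnetwork (`bio_sd`) on the tracts exclusive to
#' that subnetwork's induced subgraph — the individual-differences signal —
#' and patients are further degraded by `patient_global_deficit * fa_sd`
#' everywhere plus a half-normal injury factor per subnetwork
#' (`subnet_deficit_sd`), again on the exclusive tracts. Tracts shared by
#' both subnetworks carry only the global components, so the two planted
#' integrity factors stay statistically independent (see the methods
#' vignette).
#'
#' @param fixture An `atlas_fixture`.
#' @param cfg A `generator_config`.
#' @param seed Seed for this draw; defaults to `cfg$seed`.
#' @return List with `fa` (named list of 90 x 90 FA matrices), `subjects`
#'   (data.frame `subject_id`, `group`), and `integrity` (data.frame with
#'   per-subject working-memory and reasoning subnetwork integrity: mean
#'   edge FA over the induced subgraph, standardised against controls).
#' @export
simulate_connectomes <- function(fixture, cfg, seed = cfg$seed) {
  stopifnot(inherits(fixture, "atlas_fixture"),
            inherits(cfg, "generator_config"))
  labels <- fixture$node_labels
  n <- length(labels)
  up <- which(upper.tri(fixture$streamlines) & fixture$streamlines > 0)
  row_i <- ((up - 1L) %% n) + 1L
  col_j <- ((up - 1L) %/% n) + 1L
  in_wm <- labels[row_i] %in% fixture$wm_members &
    labels[col_j] %in% fixture$wm_members
  in_rsn <- labels[row_i] %in% fixture$rsn_members &
    labels[col_j] %in% fixture$rsn_members
  wm_only <- in_wm & !in_rsn
  rsn_only <- in_rsn & !in_wm

  n_c <- cfg$n_controls
  n_p <- cfg$n_patients
  ids <- c(sprintf("C%03d", seq_len(n_c)),
           if (n_p > 0) sprintf("P%03d", seq_len(n_p)))
  group <- rep(c("control", "patient"), c(n_c, n_p))

  fa_list <- vector("list", n_c + n_p)
  names(fa_list) <- ids
  wm_raw <- rsn_raw <- numeric(n_c + n_p)
  withr::with_seed(as.integer(seed), {
    bio_wm <- stats::rnorm(n_c + n_p, 0, cfg$bio_sd)
    bio_rsn <- stats::rnorm(n_c + n_p, 0, cfg$bio_sd)
    d_wm <- c(numeric(n_c), abs(stats::rnorm(n_p, 0, cfg$subnet_deficit_sd)))
    d_rsn <- c(numeric(n_c), abs(stats::rnorm(n_p, 0, cfg$subnet_deficit_sd)))
    for (s in seq_along(ids)) {
      is_pat <- group[s] == "patient"
      mu <- cfg$fa_mean + cfg$fa_sd *
        ((bio_wm[s] - d_wm[s]) * wm_only + (bio_rsn[s] - d_rsn[s]) * rsn_only -
           cfg$patient_global_deficit * is_pat)
      vals <- rtruncnorm01(length(up), mu, cfg$fa_sd)
      m <- matrix(0, n, n, dimnames = list(labels, labels))
      m[up] <- vals
      m <- m + t(m)
      fa_list[[s]] <- m
      wm_raw[s] <- mean(vals[in_wm])
      rsn_raw[s] <- mean(vals[in_rsn])
    }
  })
  ctrl <- group == "control"
  integrity <- data.frame(
    subject_id = ids, group = group,
    wm_integrity = (wm_raw - mean(wm_raw[ctrl])) / stats::sd(wm_raw[ctrl]),
    rsn_integrity = (rsn_raw - mean(rsn_raw[ctrl])) / stats::sd(rsn_raw[ctrl]),
    stringsAsFactors = FALSE
  )
  list(fa = fa_list,
       subjects = data.frame(subject_id = ids, group = group,
                             stringsAsFactors = FALSE),
       integrity = integrity)
}

#' Simulate the cohort table of task scores
#'
#' Maps per-subject subnetwork integrity to six task scores through two
#' latent abilities: working memory ability
#' `coupling_wm_to_wm * wm + coupling_rsn_to_wm * rsn + noise` and reasoning
#' ability `coupling_wm_to_rsn * wm + coupling_rsn_to_rsn * rsn + noise`.
#' MKL/PAL/SOS load on working memory and FTM/OOO/HTT on reasoning, each
#' with its configured loading plus a polynomial age trend and residual
#' noise. Ages are drawn to match the study cohorts (controls ~ N(45, 15),
#' patients ~ N(43, 12.4), truncated to 20-80 years).
#'
#' @param integrity Data frame from [simulate_connectomes()] (`subject_id`,
#'   `group`, `wm_integrity`, `rsn_integrity`).
#' @param cfg A `generator_config`.
#' @param seed Seed for this draw; defaults to `cfg$seed + 1` so the task
#'   stream is independent of the connectome stream.
#' @return Cohort data.frame: `subject_id`, `group`, `age`, and the six task
#'   columns MKL, PAL, SOS, FTM, OOO, HTT.
#' @export
simulate_task_scores <- function(integrity, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "generator_config"),
            all(c("subject_id", "group", "wm_integrity", "rsn_integrity")
                %in% names(integrity)))
  n <- nrow(integrity)
  withr::with_seed(as.integer(seed), {
    age_mu <- ifelse(integrity$group == "patient", 42.9, 44.98)
    age_sd <- ifelse(integrity$group == "patient", 12.4, 15.16)
    age <- stats::rnorm(n, age_mu, age_sd)
    bad <- which(age < 20 | age > 80)
    while (length(bad)) {
      age[bad] <- stats::rnorm(length(bad), age_mu[bad], age_sd[bad])
      bad <- bad[age[bad] < 20 | age[bad] > 80]
    }
    wm_ability <- cfg$coupling_wm_to_wm * integrity$wm_integrity +
      cfg$coupling_rsn_to_wm * integrity$rsn_integrity +
      stats::rnorm(n, 0, cfg$noise_sd)
    rsn_ability <- cfg$coupling_wm_to_rsn * integrity$wm_integrity +
      cfg$coupling_rsn_to_rsn * integrity$rsn_integrity +
      stats::rnorm(n, 0, cfg$noise_sd)
    z <- (age - 50) / 15
    trend <- cfg$age_beta1 * z + cfg$age_beta2 * z^2 + cfg$age_beta3 * z^3
    scores <- sapply(task_codes(), function(task) {
      lam <- cfg$task_loadings[[task]]
      ability <- if (task %in% c("MKL", "PAL", "SOS")) wm_ability else rsn_ability
      lam * ability + trend +
        stats::rnorm(n, 0, sqrt(max(0, 1 - lam^2)))
    })
  })
  out <- data.frame(subject_id = integrity$subject_id,
                    group = integrity$group, age = age,
                    stringsAsFactors = FALSE)
  out[task_codes()] <- as.data.frame(scores)
  out
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: builds the atlas fixture (at `cfg$edge_density`),
#' simulates connectomes and task scores, and weights the FA matrices by
#' streamline count into analysis-ready connectomes.
#'
#' @param cfg A `generator_config`.
#' @param fixture Optional pre-built `atlas_fixture`; built from `cfg$seed`
#'   when missing.
#' @return List: `fixture`, `fa` (FA matrices), `connectomes`
#'   (streamline-weighted matrices), `cohort` (task-score table),
#'   `integrity`, `subjects`.
#' @export
simulate_cohort <- function(cfg = generator_config(), fixture = NULL) {
  if (is.null(fixture)) {
    fixture <- make_atlas_fixture(seed = cfg$seed,
                                  edge_density = cfg$edge_density)
  }
  sim <- simulate_connectomes(fixture, cfg)
  cohort <- simulate_task_scores(sim$integrity, cfg)
  connectomes <- lapply(sim$fa, build_connectome,
                        streamlines = fixture$streamlines)
  list(fixture = fixture, fa = sim$fa, connectomes = connectomes,
       cohort = cohort, integrity = sim$integrity, subjects = sim$subjects)
}
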