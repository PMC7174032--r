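test_that("generator config validates its parameters", {
  expect_error(generator_config(fa_sd = 0), "fa_sd must be positive")
  expect_error(generator_config(fa_sd = -1), "fa_sd must be positive")
  cfg <- generator_config()
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$coupling_rsn_to_wm, 0)       # asymmetric preset
  expect_true(cfg$coupling_wm_to_wm > 0 && cfg$coupling_wm_to_rsn > 0 &&
                cfg$coupling_rsn_to_rsn > 0)
})

test_that("simulated connectomes respect the structural invariants", {
  fx <- make_atlas_fixture(seed = 1)
  cfg <- generator_config(n_controls = 6L, n_patients = 5L, seed = 1L)
  sim <- simulate_connectomes(fx, cfg)
  expect_length(sim$fa, 11)
  for (m in sim$fa[c(1, 7)]) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 90))
    expect_true(all(m >= 0 & m < 1))
    # absent tracts have zero FA for every subject
    expect_true(all(m[fx$streamlines == 0] == 0))
    expect_true(all(m[fx$streamlines > 0 & upper.tri(m)] > 0))
  }
  # integrity is standardised against controls
  ctrl <- sim$integrity$group == "control"
  expect_equal(mean(sim$integrity$wm_integrity[ctrl]), 0, tolerance = 1e-12)
  expect_equal(sd(sim$integrity$rsn_integrity[ctrl]), 1, tolerance = 1e-12)
})

test_that("generator is deterministic given the seed", {
  fx <- make_atlas_fixture(seed = 2)
  cfg <- generator_config(n_controls = 4L, n_patients = 4L, seed = 9L)
  a <- simulate_connectomes(fx, cfg)
  b <- simulate_connectomes(fx, cfg)
  expect_identical(a$fa, b$fa)
  expect_identical(simulate_task_scores(a$integrity, cfg),
                   simulate_task_scores(b$integrity, cfg))
})

test_that("null configuration produces no group difference", {
  fx <- make_atlas_fixture(seed = 3)
  cfg <- generator_config(n_controls = 60L, n_patients = 60L,
                          patient_global_deficit = 0, bio_sd = 0,
                          subnet_deficit_sd = 0,
                          coupling_wm_to_wm = 0, coupling_wm_to_rsn = 0,
                          coupling_rsn_to_rsn = 0, seed = 17L)
  sim <- simulate_connectomes(fx, cfg)
  mean_fa <- vapply(sim$fa, function(m) mean(m[fx$streamlines > 0]),
                    numeric(1))
  ctrl <- sim$subjects$group == "control"
  d <- (mean(mean_fa[ctrl]) - mean(mean_fa[!ctrl])) / sd(mean_fa)
  expect_lt(abs(d), 0.5)   # no planted effect; only sampling noise
})

test_that("a one-SD global deficit lowers patient FA essentially always", {
  fx <- make_atlas_fixture(seed = 4)
  hits <- 0
  for (rep in 1:25) {
    cfg <- generator_config(n_controls = 20L, n_patients = 20L,
                            patient_global_deficit = 1.0, seed = 100L + rep)
    sim <- simulate_connectomes(fx, cfg)
    mean_fa <- vapply(sim$fa, function(m) mean(m[fx$streamlines > 0]),
                      numeric(1))
    ctrl <- sim$subjects$group == "control"
    hits <- hits + (mean(mean_fa[!ctrl]) < mean(mean_fa[ctrl]))
  }
  expect_equal(hits, 25)
})

test_that("task scores follow the planted loading and coupling structure", {
  fx <- make_atlas_fixture(seed = 5)
  # noiseless, unit loadings, no age trend: within-factor tasks identical
  cfg0 <- generator_config(
    n_controls = 10L, n_patients = 10L, noise_sd = 0,
    age_beta1 = 0, age_beta2 = 0, age_beta3 = 0,
    task_loadings = c(MKL = 1, PAL = 1, SOS = 1, FTM = 1, OOO = 1, HTT = 1),
    seed = 6L)
  sim <- simulate_connectomes(fx, cfg0)
  cohort <- simulate_task_scores(sim$integrity, cfg0)
  expect_equal(cohort$MKL, cohort$PAL, tolerance = 1e-12)
  expect_equal(cohort$MKL, cohort$SOS, tolerance = 1e-12)
  expect_equal(cohort$FTM, cohort$HTT, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cohort$MKL, cohort$FTM)))
})

test_that("the asymmetric preset decouples reasoning integrity from WM ability", {
  fx <- make_atlas_fixture(seed = 6)
  cors_wm <- cors_rsn <- numeric(6)
  for (rep in 1:6) {
    cfg <- generator_config(n_controls = 50L, n_patients = 200L,
                            seed = 300L + rep)
    sim <- simulate_connectomes(fx, cfg)
    cohort <- simulate_task_scores(sim$integrity, cfg)
    pat <- cohort$group == "patient"
    # reconstruct the latent WM ability direction from its indicator tasks
    wm_ability_proxy <- rowMeans(scale(cohort[pat, c("MKL", "PAL", "SOS")]))
    cors_wm[rep] <- cor(sim$integrity$wm_integrity[pat], wm_ability_proxy)
    cors_rsn[rep] <- cor(sim$integrity$rsn_integrity[pat], wm_ability_proxy)
  }
  expect_true(all(cors_wm > 0.3))
  expect_lt(abs(mean(cors_rsn)), 0.1)
})

test_that("control edge FA follows the configured truncated normal", {
  fx <- make_atlas_fixture(seed = 7)
  cfg <- generator_config(n_controls = 12L, n_patients = 0L, bio_sd = 0,
                          seed = 8L)
  sim <- simulate_connectomes(fx, cfg)
  edges <- unlist(lapply(sim$fa, function(m) m[upper.tri(m) & fx$streamlines > 0]))
  edges <- edges[seq_len(10000)]
  ks <- suppressWarnings(stats::ks.test(edges, "pnorm", cfg$fa_mean, cfg$fa_sd))
  # truncation at (0,1) is ~7 SD away, so the plain normal is the law
  expect_gt(ks$p.value, 0.01)
})
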