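test_that("mean FA extraction averages skeleton voxels under each mask", {
  vol <- array(0, c(4, 4, 4))
  vol[1, 1, 1] <- 0.2
  vol[2, 1, 1] <- 0.4
  vol[3, 3, 3] <- 0.9
  m1 <- array(0, c(4, 4, 4)); m1[1:2, 1, 1] <- 1
  m2 <- array(0, c(4, 4, 4)); m2[4, 4, 4] <- 1   # no skeleton overlap
  out <- mean_fa_per_connection(vol, list(a = m1, b = m2))
  expect_equal(out, c(a = 0.3, b = 0))

  # masked voxels where FA = 0 (off skeleton) are excluded from the mean
  m3 <- array(0, c(4, 4, 4)); m3[1:3, 1, 1] <- 1
  expect_equal(unname(mean_fa_per_connection(vol, list(m3))), 0.3)

  bad <- array(1, c(3, 3, 3))
  expect_error(mean_fa_per_connection(vol, list(bad)), "3x3x3")
})

test_that("mean FA extraction matches a per-voxel loop oracle", {
  set.seed(42)
  vol <- array(stats::runif(1000), c(10, 10, 10))
  vol[vol < 0.3] <- 0   # off-skeleton voxels
  masks <- replicate(5, array(stats::rbinom(1000, 1, 0.2), c(10, 10, 10)),
                     simplify = FALSE)
  got <- mean_fa_per_connection(vol, masks)
  oracle <- sapply(masks, function(m) {
    tot <- 0; cnt <- 0
    for (i in 1:10) for (j in 1:10) for (k in 1:10) {
      if (m[i, j, k] == 1 && vol[i, j, k] > 0) {
        tot <- tot + vol[i, j, k]; cnt <- cnt + 1
      }
    }
    if (cnt == 0) 0 else tot / cnt
  })
  expect_equal(unname(got), oracle, tolerance = 1e-12)
})

test_that("streamline weighting builds a symmetric zero-filled connectome", {
  fa <- matrix(c(0, 0.5, 0.3,
                 0.5, 0, 0.2,
                 0.3, 0.2, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  s <- matrix(c(0, 100, 0,
                100, 0, 10,
                0, 10, 0), 3, 3)
  w <- build_connectome(fa, s)
  expect_equal(w["a", "b"], 50)      # 0.5 * 100
  expect_equal(w["a", "c"], 0)       # absent connection stays zero
  expect_equal(w, t(w))
  expect_equal(diag(w), c(a = 0, b = 0, c = 0))

  ones <- 1 - diag(3)
  expect_equal(unname(build_connectome(fa, ones)), unname(fa))
  expect_error(build_connectome(-fa, s), "nonnegative")
})

test_that("threshold scheme has control-referenced moments and ten levels", {
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  b <- matrix(c(0, 3, 3, 0), 2, 2)
  scheme <- fit_threshold_scheme(list(a, b))
  expect_equal(scheme$mean[1, 2], 2)
  expect_equal(scheme$sd[1, 2], 1)          # population denominator
  expect_equal(scheme$levels, seq(0.5, 5, by = 0.5))
  expect_length(scheme$levels, 10)

  same <- fit_threshold_scheme(list(a, a))
  expect_true(all(same$sd == 0))
  expect_error(fit_threshold_scheme(list(a)), "at least 2")

  sample_sd <- fit_threshold_scheme(list(a, b), sd_denominator = "sample")
  expect_equal(sample_sd$sd[1, 2], sqrt(2))
})

test_that("scheme mean reproduces build + average to machine precision", {
  set.seed(7)
  mats <- replicate(6, {
    fa <- random_weighted_graph(8, 0.6) / 2
    s <- (random_weighted_graph(8, 1) > 0) * 50
    build_connectome(fa, s)
  }, simplify = FALSE)
  scheme <- fit_threshold_scheme(mats)
  expect_equal(scheme$mean, Reduce(`+`, mats) / 6, tolerance = 1e-12)
})

test_that("thresholding applies mu - t*sigma cutoffs edgewise", {
  # toy 3-edge case checked by hand: cutoffs 2-2*1=0, 4-2=2, 6-2=4
  mu <- matrix(0, 3, 3); sd_ <- matrix(0, 3, 3)
  mu[1, 2] <- mu[2, 1] <- 2; mu[1, 3] <- mu[3, 1] <- 4; mu[2, 3] <- mu[3, 2] <- 6
  sd_[upper.tri(sd_) | lower.tri(sd_)] <- 1
  scheme <- structure(list(mean = mu, sd = sd_, levels = seq(0.5, 5, 0.5)),
                      class = "threshold_scheme")
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5; w[1, 3] <- w[3, 1] <- 2.5; w[2, 3] <- w[3, 2] <- 3.5
  thr <- apply_threshold(w, scheme, 2)
  expect_equal(thr[1, 2], 0.5)   # 0.5 >= 0
  expect_equal(thr[1, 3], 2.5)   # 2.5 >= 2
  expect_equal(thr[2, 3], 0)     # 3.5 <  4
  expect_equal(thr, t(thr))

  # sigma = 0: edges kept iff w >= mu (boundary kept)
  scheme0 <- structure(list(mean = mu, sd = matrix(0, 3, 3),
                            levels = seq(0.5, 5, 0.5)),
                       class = "threshold_scheme")
  thr0 <- apply_threshold(mu, scheme0, 1)
  expect_equal(thr0, mu)

  # cutoffs all <= 0 leave the connectome unchanged
  big_t <- apply_threshold(w, scheme, 10)
  expect_equal(big_t, w)

  expect_error(apply_threshold(matrix(0, 2, 2), scheme, 2), "shapes differ")
})

test_that("edge survival is monotone in t and thresholding is idempotent", {
  set.seed(11)
  controls <- replicate(10, random_weighted_graph(12, 0.5), simplify = FALSE)
  scheme <- fit_threshold_scheme(controls)
  w <- random_weighted_graph(12, 0.5)
  prev <- NULL
  for (t in scheme$levels) {
    thr <- apply_threshold(w, scheme, t)
    if (!is.null(prev)) {
      # larger t -> lower cutoff -> weakly more surviving edges
      expect_true(all(thr[prev > 0] > 0))
    }
    expect_equal(apply_threshold(thr, scheme, t), thr)
    prev <- thr
  }
  strict <- apply_threshold(w, scheme, 0.5)
  liberal <- apply_threshold(w, scheme, 5)
  expect_true(all(liberal[strict > 0] > 0))
})

test_that("induced subnetworks keep member edges and commute with thresholding", {
  fx <- make_atlas_fixture(seed = 2)
  set.seed(3)
  controls <- replicate(5, {
    fa <- matrix(stats::runif(90 * 90, 0.2, 0.8), 90, 90)
    build_connectome((fa + t(fa)) / 2, fx$streamlines)
  }, simplify = FALSE)
  w <- controls[[1]]
  expect_equal(extract_subnetwork(w, rownames(w)), w)
  single <- extract_subnetwork(w, rownames(w)[5])
  expect_equal(unname(single), matrix(0, 1, 1))
  expect_error(extract_subnetwork(w, c("lh_insula", "nonexistent_region")),
               "nonexistent_region")

  wm <- fixture_subnetworks(fx)$working_memory
  expect_equal(dim(extract_subnetwork(w, wm)), c(31, 31))

  scheme <- fit_threshold_scheme(controls)
  sub_scheme <- structure(list(
    mean = extract_subnetwork(scheme$mean, wm),
    sd = extract_subnetwork(scheme$sd, wm),
    levels = scheme$levels), class = "threshold_scheme")
  a <- extract_subnetwork(apply_threshold(w, scheme, 2.5), wm)
  b <- apply_threshold(extract_subnetwork(w, wm), sub_scheme, 2.5)
  expect_equal(a, b)
})
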