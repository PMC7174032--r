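test_that("degree centrality counts surviving edges", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- runif(4, 0.5, 1)
  expect_equal(unname(degree_centrality(star)), c(4, 1, 1, 1, 1))
  expect_equal(unname(degree_centrality(matrix(0, 4, 4))), rep(0, 4))
  set.seed(1)
  w <- random_weighted_graph(8)
  brute <- sapply(1:8, function(i) sum(w[i, ] > 0 & seq_len(8) != i))
  expect_equal(unname(degree_centrality(w)), brute)
  expect_equal(unname(degree_centrality(w, strength = TRUE)),
               unname(rowSums(w)))
})

test_that("shortest paths use 1/w lengths with Inf for disconnected pairs", {
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  d <- shortest_path_lengths(path)
  expect_equal(d[1, 3], 2)
  disc <- matrix(0, 3, 3)
  disc[1, 2] <- disc[2, 1] <- 1
  expect_equal(shortest_path_lengths(disc)[1, 3], Inf)
  expect_equal(diag(shortest_path_lengths(disc)), rep(0, 3))
})

test_that("graph measures agree with brute-force oracles on random graphs", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    w <- random_weighted_graph(n, density = runif(1, 0.3, 0.9))
    expect_equal(shortest_path_lengths(w), oracle_shortest_paths(w),
                 tolerance = 1e-8)
    expect_equal(global_efficiency(w), oracle_global_efficiency(w),
                 tolerance = 1e-8)
    expect_equal(unname(local_efficiency(w)), oracle_local_efficiency(w),
                 tolerance = 1e-8)
    expect_equal(unname(clustering_coefficient(w)), oracle_clustering(w),
                 tolerance = 1e-8)
  }
})

test_that("efficiency attains its textbook values on canonical graphs", {
  complete <- 1 - diag(4)
  expect_equal(global_efficiency(complete), 1)
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), 5 / 6)  # pairs: 1,1,1/2 twice each
  expect_error(global_efficiency(matrix(0, 1, 1)), "at least 2")

  triangle <- 1 - diag(3)
  expect_equal(unname(local_efficiency(triangle)), rep(1, 3))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(unname(local_efficiency(star)), rep(0, 5))
})

test_that("Onnela clustering is max-normalised and zero off triangles", {
  triangle <- 1 - diag(3)
  expect_equal(unname(clustering_coefficient(triangle)), rep(1, 3))
  path4 <- matrix(0, 4, 4)
  for (i in 1:3) path4[i, i + 1] <- path4[i + 1, i] <- 1
  expect_equal(unname(clustering_coefficient(path4)), rep(0, 4))
  # triangle with weights {1, 1, 0.125}: every node sees (1*1*0.125)^(1/3) = 0.5
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1
  tri[1, 3] <- tri[3, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 0.125
  expect_equal(unname(clustering_coefficient(tri)), rep(0.5, 3))
})

test_that("weighted formulas reduce to binary definitions on binary graphs", {
  set.seed(33)
  for (rep in 1:10) {
    w <- (random_weighted_graph(7, 0.5) > 0) * 1
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected")
    expect_equal(unname(degree_centrality(w)), unname(igraph::degree(g)))
    ref_c <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    expect_equal(unname(clustering_coefficient(w)), unname(ref_c),
                 tolerance = 1e-12)
    expect_equal(unname(shortest_path_lengths(w)),
                 unname(igraph::distances(g)), tolerance = 1e-12)
  }
})

test_that("metrics respect permutation equivariance and weight rescaling", {
  set.seed(9)
  w <- random_weighted_graph(8, 0.6)
  perm <- sample(8)
  wp <- w[perm, perm]
  expect_equal(unname(degree_centrality(wp)), unname(degree_centrality(w)[perm]))
  expect_equal(unname(local_efficiency(wp)), unname(local_efficiency(w)[perm]))
  expect_equal(unname(clustering_coefficient(wp)),
               unname(clustering_coefficient(w)[perm]))
  expect_equal(global_efficiency(wp), global_efficiency(w))

  ws <- 3.7 * w
  expect_equal(degree_centrality(ws), degree_centrality(w))
  expect_equal(clustering_coefficient(ws), clustering_coefficient(w))
  expect_equal(global_efficiency(ws), 3.7 * global_efficiency(w))
  expect_equal(local_efficiency(ws), 3.7 * local_efficiency(w))
})

test_that("removing an edge never increases global efficiency", {
  set.seed(14)
  w <- random_weighted_graph(7, 0.7)
  e <- which(upper.tri(w) & w > 0)
  base <- global_efficiency(w)
  for (idx in sample(e, min(5, length(e)))) {
    w2 <- w
    w2[idx] <- 0
    w2[t(upper.tri(w2))[idx]] <- 0
    w2 <- pmin(w2, t(w2))
    expect_lte(global_efficiency(w2), base + 1e-12)
  }
})

test_that("hub rule takes the top fifth of control-average degree", {
  set.seed(21)
  mats <- replicate(4, random_weighted_graph(10, 0.6), simplify = FALSE)
  hubs <- identify_hubs(mats, rownames(mats[[1]]))
  expect_length(hubs, 2)   # floor(0.2 * 10)
  avg <- rowMeans(sapply(mats, degree_centrality))
  expect_setequal(hubs, names(sort(avg, decreasing = TRUE))[1:2])
  expect_error(identify_hubs(mats, character(0)), "no members")
  expect_error(identify_hubs(list(), rownames(mats[[1]])), "at least one")
})

test_that("metric table is long-format and consistent with direct calls", {
  sim <- small_cohort(seed = 4, n_controls = 4L, n_patients = 3L)
  ctrl <- sim$subjects$subject_id[sim$subjects$group == "control"]
  scheme <- fit_threshold_scheme(sim$connectomes[ctrl])
  nets <- fixture_subnetworks(sim$fixture)
  tbl <- metric_table(sim$connectomes[1:2], nets, scheme, levels = 2.5)
  expect_setequal(unique(tbl$network), c("working_memory", "reasoning"))
  sub <- extract_subnetwork(
    apply_threshold(sim$connectomes[[1]], scheme, 2.5), nets$working_memory)
  got <- tbl[tbl$subject_id == names(sim$connectomes)[1] &
               tbl$network == "working_memory" &
               tbl$metric == "global_efficiency", "value"]
  expect_equal(got, global_efficiency(sub))
  m <- nodal_matrix(tbl, "working_memory", "degree")
  expect_equal(dim(m), c(2, 31))
  expect_equal(m[1, ], degree_centrality(sub))
})
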