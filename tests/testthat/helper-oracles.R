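# Independent brute-force oracles used across the graph-metric tests.
# These deliberately avoid the package's own code paths (and igraph's
# Dijkstra): shortest paths are found by exhaustive enumeration of simple
# paths, efficiencies by summing over the oracle distances.

random_weighted_graph <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  present <- stats::runif(sum(up)) < density
  vals <- numeric(sum(up))
  vals[present] <- stats::runif(sum(present), 0.1, 2)
  w[up] <- vals
  w <- w + t(w)
  dimnames(w) <- list(paste0("n", 1:n), paste0("n", 1:n))
  w
}

# All-pairs shortest path lengths with 1/w edge lengths, by recursive
# enumeration of every simple path.
oracle_shortest_paths <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  explore <- function(current, target, visited, acc) {
    if (current == target) {
      if (acc < best[visited[1], target]) {
        best[visited[1], target] <<- acc
      }
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (len[current, nxt] < Inf && !(nxt %in% visited)) {
        explore(nxt, target, c(visited, nxt), acc + len[current, nxt])
      }
    }
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      explore(i, j, i, 0)
      best[j, i] <- best[i, j]
    }
  }
  dimnames(best) <- dimnames(w)
  best
}

oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  d <- oracle_shortest_paths(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    nb <- setdiff(which(w[i, ] > 0), i)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(w[nb, nb, drop = FALSE])
  })
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(numeric(n))
  wh <- w / mx
  sapply(seq_len(n), function(i) {
    k <- sum(w[i, ] > 0)
    if (k < 2) return(0)
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
        }
      }
    }
    acc / (k * (k - 1))
  })
}

# Benjamini-Hochberg step-up written from the definition, independent of
# stats::p.adjust: q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- m * p[ord] / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q[ord] <- pmin(adj, 1)
  q
}

# Tiny default-condition cohort for tests that need the full chain but not
# the default sample sizes.
small_cohort <- function(seed = 1L, n_controls = 30L, n_patients = 30L, ...) {
  cfg <- generator_config(n_controls = n_controls, n_patients = n_patients,
                          seed = seed, ...)
  simulate_cohort(cfg)
}
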