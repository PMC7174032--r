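#' Degree centrality
#'
#' Number of nonzero connections incident to each node (binary count of
#' surviving edges — the dysconnectivity reading of degree after
#' thresholding). For a weighted alternative see `strength = TRUE`.
#'
#' @param w Weighted adjacency matrix (symmetric, zero diagonal).
#' @param strength If `TRUE`, return the sum of incident edge weights
#'   instead of the binary count.
#' @return Named numeric vector, one value per node.
#' @export
degree_centrality <- function(w, strength = FALSE) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (strength) rowSums(w) else rowSums(w > 0)
}

#' Pairwise shortest path lengths on a weighted connectome
#'
#' Edges are mapped to lengths `1 / w` (stronger connections are shorter),
#' and shortest paths are computed by Dijkstra's algorithm. Disconnected
#' pairs have infinite distance; the diagonal is zero.
#'
#' @param w Weighted adjacency matrix with nonnegative weights.
#' @return Matrix of pairwise distances.
#' @export
shortest_path_lengths <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), all(w >= 0))
  n <- nrow(w)
  if (n == 1) return(matrix(0, 1, 1, dimnames = dimnames(w)))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ew <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(ew)) 1 / ew else numeric(0),
                         algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' `E_glob = sum(1 / d_ij) / (N (N - 1))`, with disconnected pairs
#' contributing zero. Ranges from 0 (empty graph) to 1 (complete unit-weight
#' graph).
#'
#' @param w Weighted adjacency matrix with at least 2 nodes.
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(w) {
  n <- nrow(w)
  if (is.null(n) || n < 2) stop("global efficiency requires at least 2 nodes")
  d <- shortest_path_lengths(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbours (nodes with a surviving connection to it), using the same
#' `1 / w` edge lengths. Nodes with fewer than two neighbours get 0. A
#' fault-tolerance / segregation measure: how efficiently the neighbourhood
#' communicates when the node is removed.
#'
#' @param w Weighted adjacency matrix.
#' @return Named numeric vector of per-node local efficiency.
#' @export
local_efficiency <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  n <- nrow(w)
  out <- stats::setNames(numeric(n), rownames(w))
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    nb <- nb[nb != i]
    if (length(nb) >= 2) {
      out[i] <- global_efficiency(w[nb, nb, drop = FALSE])
    }
  }
  out
}

#' Weighted clustering coefficient (Onnela)
#'
#' Weights are normalised by the network maximum, `what = w / max(w)`, and
#' each node's coefficient is the mean geometric intensity of the triangles
#' around it: `C_i = sum_{jh} (what_ij what_ih what_jh)^(1/3) /
#' (k_i (k_i - 1))`, where `k_i` is the binary degree. Nodes with fewer than
#' two neighbours get 0.
#'
#' @param w Weighted adjacency matrix.
#' @return Named numeric vector of per-node clustering coefficients in
#'   [0, 1].
#' @export
clustering_coefficient <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), all(w >= 0))
  k <- rowSums(w > 0)
  out <- stats::setNames(numeric(nrow(w)), rownames(w))
  mx <- max(w)
  if (mx == 0) return(out)
  w13 <- (w / mx)^(1 / 3)
  cyc <- diag(w13 %*% w13 %*% w13)
  ok <- k >= 2
  out[ok] <- cyc[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Identify subnetwork hubs from control-average degree
#'
#' Ranks the member nodes of a subnetwork by their average degree
#' centrality (within the induced subnetwork) across healthy controls and
#' returns the top 20% (`floor(fraction * N)` nodes). Ties are broken by
#' label order.
#'
#' @param control_connectomes Nonempty list of weighted control matrices
#'   (typically already thresholded).
#' @param members A `subnetwork_definition` or character vector of node
#'   labels.
#' @param fraction Top fraction of nodes to label as hubs (default 0.2).
#' @return Character vector of hub labels, highest average degree first.
#' @export
identify_hubs <- function(control_connectomes, members, fraction = 0.2) {
  if (inherits(members, "subnetwork_definition")) members <- members$members
  if (length(members) == 0) stop("subnetwork has no members")
  if (!is.list(control_connectomes) || length(control_connectomes) < 1) {
    stop("at least one control connectome is required")
  }
  deg <- vapply(control_connectomes, function(w) {
    degree_centrality(extract_subnetwork(w, members))
  }, numeric(length(members)))
  avg <- rowMeans(deg)
  n_hub <- floor(fraction * length(members))
  ord <- order(-avg, members)
  members[ord][seq_len(n_hub)]
}

#' Global graph measures of a connectome
#'
#' @param w Weighted adjacency matrix.
#' @return Named vector: `global_efficiency`, `avg_local_efficiency`,
#'   `avg_degree`.
#' @export
global_metrics <- function(w) {
  c(global_efficiency = global_efficiency(w),
    avg_local_efficiency = mean(local_efficiency(w)),
    avg_degree = mean(degree_centrality(w)))
}

#' Long-format table of graph measures for a cohort
#'
#' For each subject, threshold level and subnetwork: thresholds the
#' full connectome, extracts the induced subnetwork, and computes the three
#' global measures plus per-node degree, local efficiency and clustering
#' coefficient. Global rows have `node = NA`.
#'
#' @param connectomes Named list of weighted full-brain matrices keyed by
#'   subject id.
#' @param networks Named list of `subnetwork_definition`s.
#' @param scheme A `threshold_scheme`.
#' @param levels Threshold levels to evaluate (default 2.5, the moderate
#'   reporting threshold).
#' @param nodal Include per-node rows (default `TRUE`).
#' @return data.frame: `subject_id`, `network`, `threshold`, `metric`,
#'   `node`, `value`.
#' @export
metric_table <- function(connectomes, networks, scheme, levels = 2.5,
                         nodal = TRUE) {
  stopifnot(is.list(connectomes), !is.null(names(connectomes)),
            is.list(networks), !is.null(names(networks)))
  rows <- list()
  for (t in levels) {
    for (sid in names(connectomes)) {
      thr <- apply_threshold(connectomes[[sid]], scheme, t)
      for (net in names(networks)) {
        sub <- extract_subnetwork(thr, networks[[net]])
        deg <- degree_centrality(sub)
        leff <- local_efficiency(sub)
        glob <- c(global_efficiency = global_efficiency(sub),
                  avg_local_efficiency = mean(leff),
                  avg_degree = mean(deg))
        part <- data.frame(
          subject_id = sid, network = net, threshold = t,
          metric = names(glob), node = NA_character_, value = unname(glob),
          stringsAsFactors = FALSE
        )
        if (nodal) {
          cc <- clustering_coefficient(sub)
          lab <- names(deg)
          part <- rbind(part, data.frame(
            subject_id = sid, network = net, threshold = t,
            metric = rep(c("degree", "local_efficiency",
                           "clustering_coefficient"), each = length(lab)),
            node = rep(lab, 3L), value = c(deg, leff, cc),
            stringsAsFactors = FALSE
          ))
        }
        rows[[length(rows) + 1L]] <- part
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-subject nodal values of one metric as a subjects x nodes matrix
#'
#' Convenience accessor over a [metric_table()] result, used to assemble
#' feature matrices for the multivariate analyses.
#'
#' @param tbl A [metric_table()] data.frame.
#' @param network,metric,threshold Selection keys.
#' @return Numeric matrix, rows = subjects, columns = nodes.
#' @export
nodal_matrix <- function(tbl, network, metric, threshold = 2.5) {
  sel <- tbl[tbl$network == network & tbl$metric == metric &
               tbl$threshold == threshold & !is.na(tbl$node), ]
  if (!nrow(sel)) stop("no nodal rows match the given keys")
  subjects <- unique(sel$subject_id)
  nodes <- unique(sel$node)
  m <- matrix(NA_real_, length(subjects), length(nodes),
              dimnames = list(subjects, nodes))
  m[cbind(match(sel$subject_id, subjects), match(sel$node, nodes))] <- sel$value
  m
}
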