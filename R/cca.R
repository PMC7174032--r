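#' Whole-connectome degree matrix for a cohort
#'
#' Thresholds each subject's full connectome and returns the subjects x
#' nodes matrix of degree centrality over all 90 nodes — the
#' dysconnectivity features entering the canonical correlation analysis.
#'
#' @param connectomes Named list of weighted full matrices.
#' @param scheme A `threshold_scheme`.
#' @param level Threshold level (default 2.5).
#' @return Numeric matrix, rows = subjects, columns = nodes.
#' @export
whole_brain_degree <- function(connectomes, scheme, level = 2.5) {
  out <- t(vapply(connectomes, function(w) {
    degree_centrality(apply_threshold(w, scheme, level))
  }, numeric(nrow(scheme$mean))))
  rownames(out) <- names(connectomes)
  out
}

#' PCA reduction of nodal degrees to a 90%-variance basis
#'
#' Unrotated PCA of the standardised degree matrix; retains the smallest
#' number of components whose cumulative variance reaches `var_target`.
#' Guards the canonical correlation analysis against overfitting to 90
#' raw node measures.
#'
#' @param degrees Subjects x nodes numeric matrix.
#' @param var_target Fraction of variance to capture (default 0.9).
#' @return List: `scores` (subjects x k), `k`, `cum_var` (fraction captured
#'   by the retained components), `rotation`, `center`, `scale`, `dropped`
#'   (zero-variance columns removed before standardisation).
#' @export
reduce_degrees <- function(degrees, var_target = 0.9) {
  degrees <- as.matrix(degrees)
  if (nrow(degrees) < 2) stop("at least 2 subjects are required")
  sds <- apply(degrees, 2, stats::sd)
  dropped <- colnames(degrees)[sds == 0]
  keep <- degrees[, sds > 0, drop = FALSE]
  z <- scale(keep)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= var_target)[1]
  list(scores = pc$x[, seq_len(k), drop = FALSE], k = k, cum_var = cum[k],
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       center = attr(z, "scaled:center"), scale = attr(z, "scaled:scale"),
       dropped = dropped)
}

#' Canonical correlation analysis
#'
#' Standard CCA of two column-centred blocks, solved by QR decomposition of
#' each block followed by an SVD of the cross-product of their orthonormal
#' bases. Returns `min(ncol(X), ncol(Y))` modes ordered by decreasing
#' canonical correlation. Fails with the condition numbers of both blocks
#' when a within-set covariance is singular.
#'
#' @param X,Y Numeric matrices with the same rows (subjects); e.g. the two
#'   cognitive component scores and the reduced degree components.
#' @return Object of class `cca_fit`: list with `cor` (canonical
#'   correlations), `xcoef`, `ycoef` (weights), `U`, `V` (subject
#'   variates), `x_center`, `y_center`, `n`.
#' @export
cca_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) > max(ncol(X), ncol(Y)))
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  qx <- qr(Xc); qy <- qr(Yc)
  if (qx$rank < ncol(X) || qy$rank < ncol(Y)) {
    stop(sprintf(
      "singular within-set covariance (condition numbers: X %.3g, Y %.3g)",
      kappa(Xc), kappa(Yc)))
  }
  Qx <- qr.Q(qx); Qy <- qr.Q(qy)
  sv <- svd(crossprod(Qx, Qy))
  d <- pmin(pmax(sv$d, 0), 1)
  xcoef <- backsolve(qr.R(qx), sv$u)
  ycoef <- backsolve(qr.R(qy), sv$v)
  rownames(xcoef) <- colnames(X); rownames(ycoef) <- colnames(Y)
  fit <- list(cor = d, xcoef = xcoef, ycoef = ycoef,
              U = Xc %*% xcoef, V = Yc %*% ycoef,
              x_center = attr(Xc, "scaled:center"),
              y_center = attr(Yc, "scaled:center"), n = nrow(X))
  class(fit) <- "cca_fit"
  fit
}

#' Apply trained canonical weights to held-out data
#'
#' @param fit A `cca_fit`.
#' @param X,Y Held-out rows of the two blocks.
#' @return List: `U`, `V` (held-out variates, centred with the training
#'   means), `cor` (held-out correlation per mode).
#' @export
cca_predict <- function(fit, X, Y) {
  U <- sweep(as.matrix(X), 2, fit$x_center) %*% fit$xcoef
  V <- sweep(as.matrix(Y), 2, fit$y_center) %*% fit$ycoef
  r <- vapply(seq_len(ncol(U)), function(m) {
    suppressWarnings(stats::cor(U[, m], V[, m]))
  }, numeric(1))
  list(U = U, V = V, cor = r)
}

#' Permutation test of canonical modes
#'
#' Shuffles the subject correspondence between the two blocks (row
#' permutation of `Y`), refits the CCA each time, and returns for each mode
#' the marginal permutation p-value
#' `p_m = (1 + #\{null rho_m >= observed rho_m\}) / (n_perm + 1)`. The null
#' refits reuse the orthonormal basis of each block, which is exact for row
#' permutations of centred data.
#'
#' @param X,Y Input blocks as in [cca_fit()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List: `fit` (observed `cca_fit`), `p` (per-mode p-values),
#'   `null` (n_perm x modes matrix of null canonical correlations),
#'   `null_mean` (per-mode mean of the null).
#' @export
cca_permutation_test <- function(X, Y, n_perm = 10000, seed = 1L) {
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  fit <- cca_fit(X, Y)
  Xc <- scale(as.matrix(X), scale = FALSE)
  Yc <- scale(as.matrix(Y), scale = FALSE)
  Qx <- qr.Q(qr(Xc)); Qy <- qr.Q(qr(Yc))
  n <- nrow(Qx)
  m <- length(fit$cor)
  null <- matrix(NA_real_, n_perm, m)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      null[b, ] <- svd(crossprod(Qx, Qy[perm, , drop = FALSE]),
                       nu = 0, nv = 0)$d[seq_len(m)]
    }
  })
  p <- vapply(seq_len(m), function(j) {
    (1 + sum(null[, j] >= fit$cor[j])) / (n_perm + 1)
  }, numeric(1))
  list(fit = fit, p = p, null = null, null_mean = colMeans(null))
}

#' Back-project canonical variates onto raw variables
#'
#' Pearson correlation of each mode's behavioural variate with every raw
#' task score, and of its connectome variate with every raw node degree —
#' the loadings used to interpret what each canonical mode captures.
#'
#' @param fit A `cca_fit`.
#' @param raw_tasks Subjects x tasks matrix (same rows as the fit).
#' @param raw_degrees Subjects x nodes matrix.
#' @return List of two matrices: `task_loadings` (tasks x modes) and
#'   `node_loadings` (nodes x modes). Zero-variance raw columns give NA.
#' @export
back_project <- function(fit, raw_tasks, raw_degrees) {
  stopifnot(inherits(fit, "cca_fit"))
  safe_cor <- function(a, b) suppressWarnings(stats::cor(a, b))
  task_loadings <- safe_cor(as.matrix(raw_tasks), fit$U)
  node_loadings <- safe_cor(as.matrix(raw_degrees), fit$V)
  colnames(task_loadings) <- colnames(node_loadings) <-
    paste0("mode", seq_along(fit$cor))
  list(task_loadings = task_loadings, node_loadings = node_loadings)
}

#' Subsampling train/test generalisation of the CCA
#'
#' Repeatedly subsamples the cohort, fits the CCA on the training rows,
#' applies the trained weights to the held-out rows, and averages the
#' held-out correlation per mode over iterations; the whole routine is then
#' repeated with the subject correspondence permuted, giving the overfit
#' reference curve. Observed curves above the permuted curves indicate
#' generalisable (non-overfit) modes.
#'
#' @param X,Y Input blocks.
#' @param train_fractions Grid of training fractions (all < 1, each leaving
#'   at least 5 held-out subjects).
#' @param n_iter Iterations per fraction (default 1000).
#' @param seed Integer seed.
#' @return data.frame: `fraction`, `mode`, `observed_r`, `permuted_r`
#'   (means over iterations).
#' @export
subsample_generalization <- function(X, Y,
                                     train_fractions = c(0.5, 0.6, 0.7, 0.8, 0.9),
                                     n_iter = 1000, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (any(train_fractions >= 1)) stop("train fractions must be < 1")
  n_train <- floor(train_fractions * n)
  if (any(n - n_train < 5)) {
    stop("each train fraction must leave at least 5 held-out subjects")
  }
  m <- min(ncol(X), ncol(Y))
  res <- list()
  withr::with_seed(as.integer(seed), {
    for (f in seq_along(train_fractions)) {
      obs <- prm <- matrix(NA_real_, n_iter, m)
      for (it in seq_len(n_iter)) {
        tr <- sample.int(n, n_train[f])
        fit <- cca_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
        obs[it, ] <- cca_predict(fit, X[-tr, , drop = FALSE],
                                 Y[-tr, , drop = FALSE])$cor
        Yp <- Y[sample.int(n), , drop = FALSE]
        fitp <- cca_fit(X[tr, , drop = FALSE], Yp[tr, , drop = FALSE])
        prm[it, ] <- cca_predict(fitp, X[-tr, , drop = FALSE],
                                 Yp[-tr, , drop = FALSE])$cor
      }
      res[[f]] <- data.frame(
        fraction = train_fractions[f], mode = seq_len(m),
        observed_r = colMeans(obs, na.rm = TRUE),
        permuted_r = colMeans(prm, na.rm = TRUE)
      )
    }
  })
  do.call(rbind, res)
}
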