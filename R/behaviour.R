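#' Regress a polynomial age trend out of task scores
#'
#' Ordinary least squares of each score column on {1, age, age^2, age^3},
#' returning the residuals. Accounts for the non-linear relationship
#' between age and cognitive performance before any latent-structure
#' analysis.
#'
#' @param scores Numeric matrix or data.frame, subjects x tasks.
#' @param age Numeric vector of ages (years), one per subject.
#' @param degree Polynomial degree (default 3).
#' @return Matrix of residuals with the input's dimnames.
#' @export
detrend_age <- function(scores, age, degree = 3L) {
  x <- as.matrix(scores)
  stopifnot(is.numeric(age), length(age) == nrow(x), all(is.finite(age)),
            degree >= 1)
  if (nrow(x) < 5) stop("at least 5 subjects are required")
  design <- stats::poly(age, degree = degree, raw = TRUE)
  design <- cbind(1, design)
  if (qr(design)$rank < ncol(design)) {
    stop("age design matrix is rank deficient (constant or collinear ages)")
  }
  fit <- stats::lm.fit(design, x)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(x)
  res
}

#' Rank-based inverse normal transform (Blom)
#'
#' Maps values to normal quantiles of their ranks,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with ties receiving average ranks.
#' Strictly monotone in the input; enforces approximate normality before
#' correlation and component analyses.
#'
#' @param x Numeric vector (n >= 3, not all equal).
#' @param offset Rank offset; 3/8 is the Blom convention.
#' @return Transformed numeric vector.
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n < 3) stop("at least 3 values are required")
  if (length(unique(x)) == 1) stop("all values are equal; ranks are degenerate")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - offset) / (n + 1 - 2 * offset))
}

#' Age-detrend and normalise a block of task scores
#'
#' The standard behavioural preprocessing: cubic age regression followed by
#' the rank-based inverse normal transform, column by column.
#'
#' @inheritParams detrend_age
#' @return Matrix of preprocessed scores.
#' @export
preprocess_scores <- function(scores, age, degree = 3L) {
  res <- detrend_age(scores, age, degree)
  apply(res, 2, inverse_normal_transform)
}

#' Principal component analysis with varimax rotation
#'
#' Eigendecomposition of the task correlation matrix; components with
#' unrotated eigenvalue > 1 are retained (Kaiser criterion) and varimax
#' rotated (with Kaiser row normalisation). Component scores are obtained
#' by least-squares regression of the standardised data on the rotated
#' loadings. Each component's sign is flipped so its largest-magnitude
#' loading is positive. Variance explained is reported both before and
#' after rotation.
#'
#' @param x Numeric matrix or data.frame, subjects x tasks; columns are
#'   standardised internally.
#' @param kaiser Apply the eigenvalue > 1 retention rule (default `TRUE`).
#' @param n_components Retained component count when `kaiser = FALSE`.
#' @param rotate_tol Convergence tolerance of the varimax iterations.
#' @return Object of class `component_model`: list with `loadings`
#'   (tasks x components), `scores` (subjects x components, zero mean),
#'   `eigenvalues`, `n_retained`, `explained_variance_unrotated`,
#'   `explained_variance_rotated` (percent), `communality`, `rotated`
#'   (logical).
#' @export
pca_varimax <- function(x, kaiser = TRUE, n_components = 2L,
                        rotate_tol = 1e-6) {
  x <- as.matrix(x)
  stopifnot(nrow(x) > 2, ncol(x) >= 2)
  z <- scale(x)
  if (any(!is.finite(z))) stop("a task column has zero variance")
  r <- stats::cor(x)
  ee <- eigen(r, symmetric = TRUE)
  values <- ee$values
  k <- if (kaiser) sum(values > 1) else as.integer(n_components)
  k <- max(k, 1L)
  load_unrot <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(values[seq_len(k)]), k)
  rownames(load_unrot) <- colnames(x)
  rotated <- k >= 2
  if (!rotated) {
    warning("fewer than 2 components retained; returning unrotated solution")
    loadings <- load_unrot
  } else {
    loadings <- varimax_multistart(load_unrot, eps = rotate_tol)
  }
  # sign convention: dominant loading of each component positive
  for (j in seq_len(ncol(loadings))) {
    peak <- which.max(abs(loadings[, j]))
    if (loadings[peak, j] < 0) loadings[, j] <- -loadings[, j]
  }
  colnames(loadings) <- paste0("C", seq_len(ncol(loadings)))
  scores <- z %*% loadings %*% solve(crossprod(loadings))
  colnames(scores) <- colnames(loadings)
  p <- ncol(x)
  model <- list(
    loadings = loadings,
    scores = scores,
    eigenvalues = values,
    n_retained = k,
    explained_variance_unrotated = 100 * values[seq_len(k)] / p,
    explained_variance_rotated = 100 * colSums(loadings^2) / p,
    communality = rowSums(loadings^2),
    rotated = rotated
  )
  class(model) <- "component_model"
  model
}

#' @export
print.component_model <- function(x, ...) {
  cat("Component model:", x$n_retained, "component(s) retained",
      if (x$rotated) "(varimax rotated)" else "(unrotated)", "\n")
  cat("Variance explained (rotated, %):",
      paste(sprintf("%.2f", x$explained_variance_rotated), collapse = ", "),
      "| total:", sprintf("%.2f", sum(x$explained_variance_rotated)), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

# Varimax criterion with Kaiser row normalisation: sum over components of
# the variance of the squared normalised loadings.
varimax_criterion <- function(L) {
  h <- sqrt(rowSums(L^2))
  h[h == 0] <- 1
  z2 <- (L / h)^2
  sum(apply(z2, 2, function(col) mean(col^2) - mean(col)^2))
}

# stats::varimax from several deterministic random starts, keeping the
# rotation with the highest criterion. The single-start iteration can stall
# at a saddle when the unrotated loadings are nearly symmetric across
# components (common with balanced two-factor batteries).
varimax_multistart <- function(L, eps = 1e-6, n_starts = 8L) {
  k <- ncol(L)
  starts <- withr::with_seed(1L, {
    c(list(diag(k)), replicate(n_starts, {
      qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
    }, simplify = FALSE))
  })
  best <- NULL
  best_crit <- -Inf
  for (R0 in starts) {
    rot <- stats::varimax(L %*% R0, normalize = TRUE, eps = eps)
    cand <- unclass(rot$loadings)
    crit <- varimax_criterion(cand)
    if (crit > best_crit + 1e-12) {
      best_crit <- crit
      best <- cand
    }
  }
  dimnames(best) <- dimnames(L)
  best
}

#' Tucker congruence between two loading matrices
#'
#' Matches the columns of `b` to those of `a` (each column of `a` is paired
#' with its best-matching remaining column of `b`, in order) and returns the
#' absolute Tucker congruence coefficient per matched component. Used to
#' quantify recovery of a planted factor pattern up to sign and permutation.
#'
#' @param a,b Loading matrices with equal dimensions (tasks x components).
#' @return Numeric vector of per-component congruences in [0, 1].
#' @export
factor_congruence <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)))
  cong <- abs(crossprod(a, b)) /
    outer(sqrt(colSums(a^2)), sqrt(colSums(b^2)))
  out <- numeric(ncol(a))
  remaining <- seq_len(ncol(b))
  for (j in seq_len(ncol(a))) {
    pick <- remaining[which.max(cong[j, remaining])]
    out[j] <- cong[j, pick]
    remaining <- setdiff(remaining, pick)
  }
  out
}

#' Planted task-loading pattern of the generator
#'
#' The tasks x 2 loading matrix the synthetic cohorts are built from:
#' MKL/PAL/SOS on the working-memory component, FTM/OOO/HTT on the
#' reasoning component.
#'
#' @param cfg A `generator_config`.
#' @return 6 x 2 matrix with columns `WM`, `RSN`.
#' @export
planted_loading_pattern <- function(cfg = generator_config()) {
  lam <- cfg$task_loadings
  out <- matrix(0, 6, 2, dimnames = list(task_codes(), c("WM", "RSN")))
  out[c("MKL", "PAL", "SOS"), "WM"] <- lam[c("MKL", "PAL", "SOS")]
  out[c("FTM", "OOO", "HTT"), "RSN"] <- lam[c("FTM", "OOO", "HTT")]
  out
}

#' Label rotated components as working memory or reasoning
#'
#' Assigns each retained component to the planted pattern column it is most
#' congruent with, returning the component scores relabelled `WM` / `RSN`.
#'
#' @param model A `component_model` with two retained components.
#' @param cfg A `generator_config` (for the planted pattern).
#' @return Subjects x 2 score matrix with columns `WM` and `RSN`.
#' @export
label_components <- function(model, cfg = generator_config()) {
  stopifnot(inherits(model, "component_model"), model$n_retained >= 2)
  target <- planted_loading_pattern(cfg)
  cong <- abs(crossprod(target, model$loadings[rownames(target), 1:2]))
  if (which.max(cong["WM", ]) == which.max(cong["RSN", ])) {
    # degenerate match; fall back to order of congruence with WM
    wm_col <- which.max(cong["WM", ])
    rsn_col <- setdiff(1:2, wm_col)
  } else {
    wm_col <- which.max(cong["WM", ])
    rsn_col <- which.max(cong["RSN", ])
  }
  out <- model$scores[, c(wm_col, rsn_col)]
  colnames(out) <- c("WM", "RSN")
  out
}
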