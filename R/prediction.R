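#' Kernel ridge regression (linear kernel), dual form
#'
#' Fits the dual solution `alpha = (K + lambda I)^-1 y` on centred data,
#' with `K = Xc Xc'`. Only the linear kernel is supported, which keeps the
#' primal weights `w = Xc' alpha` available for interpretation.
#'
#' @param X Training features, subjects x nodes (finite).
#' @param y Training target.
#' @param lambda Ridge penalty (> 0).
#' @param kernel Kernel name; only `"linear"`.
#' @return Object of class `krr_model`: `alpha`, `Xc` (centred training
#'   features), `x_center`, `y_center`, `lambda`, `kernel`.
#' @export
krr_fit <- function(X, y, lambda, kernel = "linear") {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)), all(is.finite(y)), nrow(X) == length(y))
  if (!identical(kernel, "linear")) {
    stop("only the linear kernel is supported")
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    stop("lambda must be a positive scalar")
  }
  Xc <- scale(X, scale = FALSE)
  K <- tcrossprod(Xc)
  A <- K + lambda * diag(nrow(K))
  cond <- kappa(A, exact = FALSE)
  if (!is.finite(cond) || cond > 1e12) {
    stop(sprintf("kernel system is numerically singular (condition ~ %.3g)",
                 cond))
  }
  yc <- y - mean(y)
  alpha <- solve(A, yc)
  model <- list(alpha = alpha, Xc = Xc,
                x_center = attr(Xc, "scaled:center"),
                y_center = mean(y), lambda = lambda, kernel = kernel)
  class(model) <- "krr_model"
  model
}

#' Predict from a fitted kernel ridge model
#'
#' @param object A `krr_model`.
#' @param newdata New subjects x nodes feature matrix.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.krr_model <- function(object, newdata, ...) {
  Knew <- sweep(as.matrix(newdata), 2, object$x_center) %*% t(object$Xc)
  drop(Knew %*% object$alpha) + object$y_center
}

std_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

std_apply <- function(X, st) {
  sweep(sweep(as.matrix(X), 2, st$center), 2, st$scale, "/")
}

# Precompute the fold structure and per-fold kernel eigendecompositions for
# nested cross-validation. The structure depends only on the features and
# the fold assignment, so permutation tests of the target can reuse it:
# feature standardisation, kernels and eigenbases are unchanged when only y
# is permuted.
krr_cv_build <- function(X, outer_k = 5L, inner_k = 5L) {
  X <- as.matrix(X)
  n <- nrow(X)
  f_out <- sample(rep(seq_len(outer_k), length.out = n))
  if (min(table(f_out)) < 2) stop("an outer fold has fewer than 2 subjects")
  outer <- lapply(seq_len(outer_k), function(o) {
    tr <- which(f_out != o)
    te <- which(f_out == o)
    st <- std_fit(X[tr, , drop = FALSE])
    Ztr <- std_apply(X[tr, , drop = FALSE], st)
    eig <- eigen(tcrossprod(Ztr), symmetric = TRUE)
    Ktest <- std_apply(X[te, , drop = FALSE], st) %*% t(Ztr)
    f_in <- sample(rep(seq_len(inner_k), length.out = length(tr)))
    if (min(table(f_in)) < 2) stop("an inner fold has fewer than 2 subjects")
    inner <- lapply(seq_len(inner_k), function(i) {
      itr <- tr[f_in != i]
      ival <- tr[f_in == i]
      sti <- std_fit(X[itr, , drop = FALSE])
      Zi <- std_apply(X[itr, , drop = FALSE], sti)
      eigi <- eigen(tcrossprod(Zi), symmetric = TRUE)
      Kval <- std_apply(X[ival, , drop = FALSE], sti) %*% t(Zi)
      list(itr = itr, ival = ival, Q = eigi$vectors,
           ev = pmax(eigi$values, 0), Kval = Kval)
    })
    list(tr = tr, te = te, Ztr = Ztr, Q = eig$vectors,
         ev = pmax(eig$values, 0), Ktest = Ktest, inner = inner)
  })
  list(outer = outer, f_out = f_out, n = n, p = ncol(X),
       feature_names = colnames(X))
}

# Evaluate one target vector on a prebuilt nested-CV structure: inner-fold
# lambda selection by mean validation MSE, outer-fold prediction with the
# selected lambda, pooled out-of-fold accuracy, and per-fold primal weights.
krr_cv_evaluate <- function(structure, y, lambda_grid) {
  n <- structure$n
  pred <- numeric(n)
  lambda_sel <- numeric(length(structure$outer))
  fold_weights <- matrix(0, structure$p, length(structure$outer))
  rownames(fold_weights) <- structure$feature_names
  for (o in seq_along(structure$outer)) {
    fo <- structure$outer[[o]]
    mse <- numeric(length(lambda_grid))
    for (inn in fo$inner) {
      ytr <- y[inn$itr]
      ybar <- mean(ytr)
      Qty <- crossprod(inn$Q, ytr - ybar)
      yval <- y[inn$ival]
      KvQ <- inn$Kval %*% inn$Q
      for (l in seq_along(lambda_grid)) {
        predv <- drop(KvQ %*% (Qty / (inn$ev + lambda_grid[l]))) + ybar
        mse[l] <- mse[l] + sum((predv - yval)^2)
      }
    }
    best <- which.min(mse)
    lambda_sel[o] <- lambda_grid[best]
    ytr <- y[fo$tr]
    ybar <- mean(ytr)
    Qty <- crossprod(fo$Q, ytr - ybar)
    alpha <- drop(fo$Q %*% (Qty / (fo$ev + lambda_sel[o])))
    pred[fo$te] <- drop(fo$Ktest %*% alpha) + ybar
    fold_weights[, o] <- drop(crossprod(fo$Ztr, alpha))
  }
  r <- suppressWarnings(stats::cor(pred, y))
  mse <- mean((pred - y)^2)
  list(predictions = pred, r = r, R2 = r^2, mse = mse,
       nmse = mse / stats::var(y), lambda = lambda_sel,
       fold_weights = fold_weights)
}

#' Nested cross-validated kernel ridge regression
#'
#' Outer folds are held out entirely; within each outer training set, inner
#' folds select the ridge penalty minimising validation MSE over
#' `lambda_grid`. Out-of-fold predictions are pooled across outer folds to
#' give Pearson r, R-squared (squared pooled r), MSE, and normalised MSE
#' (MSE divided by the variance of the observed target). Features are
#' standardised inside each training fold only, so no information leaks
#' from held-out subjects.
#'
#' @param X Subjects x nodes feature matrix.
#' @param y Target component scores.
#' @param lambda_grid Ridge penalties to search (default 13 log-spaced
#'   points over 1e-4..1e2; with fold-standardised features the kernel
#'   eigenvalues scale with the training-set size, and penalties far above
#'   that scale collapse predictions toward the training mean, which biases
#'   the pooled cross-validated correlation negative under the null).
#' @param outer_k,inner_k Fold counts (default 5 and 5).
#' @param seed Integer seed fixing the fold assignment.
#' @return Object of class `prediction_result`: `predictions` (pooled
#'   out-of-fold), `r`, `R2`, `mse`, `nmse`, `lambda` (selected per outer
#'   fold), `fold_weights`, `weights` (per-node, averaged over folds),
#'   `ranking` (nodes by |weight|), `folds` (outer assignment).
#' @export
nested_cv <- function(X, y, lambda_grid = 10^seq(-4, 2, length.out = 13),
                      outer_k = 5L, inner_k = 5L, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)), all(is.finite(y)), nrow(X) == length(y))
  structure_ <- withr::with_seed(as.integer(seed),
                                 krr_cv_build(X, outer_k, inner_k))
  out <- krr_cv_evaluate(structure_, y, lambda_grid)
  out$weights <- rowMeans(out$fold_weights)
  out$ranking <- names(sort(abs(out$weights), decreasing = TRUE))
  out$folds <- structure_$f_out
  class(out) <- "prediction_result"
  out
}

#' Permutation p-value for a nested-CV prediction model
#'
#' Permutes the target, reruns the full nested cross-validation (including
#' inner-fold lambda selection) for each permutation, and returns
#' `p = (1 + #\{null r >= observed r\}) / (n_perm + 1)`. The fold assignment
#' and feature kernels are fixed by `seed` and shared across permutations
#' (they do not depend on the target).
#'
#' @inheritParams nested_cv
#' @param n_perm Number of target permutations (default 1000).
#' @return List: `observed` (`prediction_result`), `p`, `null_r` (vector of
#'   null pooled correlations).
#' @export
permutation_pvalue <- function(X, y, n_perm = 1000,
                               lambda_grid = 10^seq(-4, 2, length.out = 13),
                               outer_k = 5L, inner_k = 5L, seed = 1L) {
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  X <- as.matrix(X)
  observed <- nested_cv(X, y, lambda_grid, outer_k, inner_k, seed)
  structure_ <- withr::with_seed(as.integer(seed),
                                 krr_cv_build(X, outer_k, inner_k))
  null_r <- numeric(n_perm)
  withr::with_seed(as.integer(seed) + 1L, {
    for (b in seq_len(n_perm)) {
      yp <- y[sample.int(length(y))]
      null_r[b] <- krr_cv_evaluate(structure_, yp, lambda_grid)$r
    }
  })
  p <- (1 + sum(null_r >= observed$r)) / (n_perm + 1)
  list(observed = observed, p = p, null_r = null_r)
}

#' Per-node weights of a fitted prediction model
#'
#' For the linear kernel, the primal weights `w = Xc' alpha` computed on the
#' standardised training features of each outer fold, averaged across
#' folds, with nodes ranked by absolute weight. Identifies which nodes
#' contribute most to the prediction.
#'
#' @param model A `prediction_result` (from [nested_cv()]) or a
#'   `krr_model`.
#' @return data.frame: `node`, `weight`, `rank`.
#' @export
compute_weights <- function(model) {
  if (inherits(model, "krr_model")) {
    if (!identical(model$kernel, "linear")) {
      stop("weights are only defined for the linear kernel")
    }
    w <- drop(crossprod(model$Xc, model$alpha))
    names(w) <- colnames(model$Xc)
  } else if (inherits(model, "prediction_result")) {
    w <- model$weights
  } else {
    stop("model must be a krr_model or prediction_result")
  }
  ord <- order(abs(w), decreasing = TRUE)
  data.frame(node = if (is.null(names(w))) as.character(seq_along(w)) else names(w),
             weight = unname(w),
             rank = match(seq_along(w), ord),
             stringsAsFactors = FALSE)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "Nested-CV kernel ridge: pooled r = %.3f, R2 = %.3f, MSE = %.3f, norm MSE = %.3f\n",
    x$r, x$R2, x$mse, x$nmse))
  cat("lambda per outer fold:", paste(signif(x$lambda, 3), collapse = ", "), "\n")
  invisible(x)
}
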