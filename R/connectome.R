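#' Mean fractional anisotropy per connection from voxel masks
#'
#' For each tract mask, intersects the binary mask with a skeletonised FA
#' volume and returns the arithmetic mean of FA over voxels where the mask
#' is nonzero and FA is positive (i.e. voxels on the white-matter skeleton).
#' A connection whose mask has no such overlap gets 0, matching the
#' zero-fill convention for absent connections.
#'
#' @param fa_volume Numeric 3-D array of skeletonised FA values (zero off
#'   the skeleton).
#' @param masks Named list of binary arrays with the same dimensions as
#'   `fa_volume`, one per connection.
#' @return Named numeric vector of per-connection mean FA.
#' @export
mean_fa_per_connection <- function(fa_volume, masks) {
  stopifnot(is.array(fa_volume), is.list(masks))
  vapply(masks, function(mask) {
    if (!identical(dim(mask), dim(fa_volume))) {
      stop(sprintf(
        "mask dimensions (%s) do not match FA volume dimensions (%s)",
        paste(dim(mask), collapse = "x"),
        paste(dim(fa_volume), collapse = "x")
      ))
    }
    sel <- mask != 0 & fa_volume > 0
    if (!any(sel)) return(0)
    mean(fa_volume[sel])
  }, numeric(1))
}

#' Build a streamline-weighted connectome
#'
#' Multiplies each connection's mean FA by the number of streamlines used to
#' create it, so that large tracts carry more weight than weak connections.
#' Absent connections (zero streamlines) stay zero.
#'
#' @param fa 90 x 90 (or n x n) symmetric nonnegative matrix of per-edge
#'   mean FA.
#' @param streamlines Matrix of the same shape with nonnegative streamline
#'   counts.
#' @return Symmetric weighted adjacency matrix `w = fa * streamlines` with
#'   zero diagonal, carrying the row/column labels of the inputs.
#' @export
build_connectome <- function(fa, streamlines) {
  stopifnot(is.matrix(fa), is.matrix(streamlines),
            identical(dim(fa), dim(streamlines)))
  if (any(fa < 0) || any(streamlines < 0)) {
    stop("FA and streamline counts must be nonnegative")
  }
  w <- fa * streamlines
  w <- (w + t(w)) / 2
  diag(w) <- 0
  if (!is.null(dimnames(fa))) dimnames(w) <- dimnames(fa)
  else if (!is.null(dimnames(streamlines))) dimnames(w) <- dimnames(streamlines)
  w
}

#' Fit the control-referenced threshold scheme
#'
#' Computes, for every connection, the mean and standard deviation of the
#' streamline-weighted edge values over all healthy controls (zeros for
#' absent connections included), and stores the ladder of threshold levels.
#' The default ladder is 0.5 to 5 SD units in increments of 0.5 — ten
#' levels in total.
#'
#' @param control_connectomes List of at least two weighted control
#'   matrices of identical shape.
#' @param levels Strictly increasing vector of SD-unit multipliers.
#' @param sd_denominator `"population"` (divide by n; default) or
#'   `"sample"` (n - 1).
#' @return Object of class `threshold_scheme`: list with `mean`, `sd`
#'   (matrices), `levels`, `n_controls`.
#' @export
fit_threshold_scheme <- function(control_connectomes,
                                 levels = seq(0.5, 5, by = 0.5),
                                 sd_denominator = c("population", "sample")) {
  sd_denominator <- match.arg(sd_denominator)
  if (!is.list(control_connectomes) || length(control_connectomes) < 2) {
    stop("at least 2 control connectomes are required")
  }
  stopifnot(is.numeric(levels), length(levels) >= 1,
            all(diff(levels) > 0) || length(levels) == 1)
  dims <- dim(control_connectomes[[1]])
  stopifnot(all(vapply(control_connectomes,
                       function(m) identical(dim(m), dims), logical(1))))
  n <- length(control_connectomes)
  mu <- Reduce(`+`, control_connectomes) / n
  ss <- Reduce(`+`, lapply(control_connectomes, function(m) (m - mu)^2))
  sd_mat <- sqrt(ss / if (sd_denominator == "population") n else n - 1)
  scheme <- list(mean = mu, sd = sd_mat, levels = as.numeric(levels),
                 n_controls = n, sd_denominator = sd_denominator)
  class(scheme) <- "threshold_scheme"
  scheme
}

#' Apply a control-referenced edge threshold
#'
#' The cutoff for each connection is `mean - t * sd` computed from the
#' control group; any value strictly less than its cutoff is replaced with
#' zero. Larger `t` lowers the cutoff, so weakly more edges survive at
#' higher `t`. Negative cutoffs are allowed (every present edge survives).
#'
#' @param w Weighted connectome matrix.
#' @param scheme A `threshold_scheme`.
#' @param t SD-unit multiplier (typically one of `scheme$levels`; the
#'   analyses report `t = 2.5` by default).
#' @return Thresholded connectome of the same shape.
#' @export
apply_threshold <- function(w, scheme, t) {
  stopifnot(inherits(scheme, "threshold_scheme"),
            is.numeric(t), length(t) == 1, t > 0)
  if (!identical(dim(w), dim(scheme$mean))) {
    stop(sprintf("connectome (%s) and scheme (%s) shapes differ",
                 paste(dim(w), collapse = "x"),
                 paste(dim(scheme$mean), collapse = "x")))
  }
  cutoff <- scheme$mean - t * scheme$sd
  out <- w
  out[out < cutoff] <- 0
  diag(out) <- 0
  out
}

#' Define a named subnetwork
#'
#' @param name Subnetwork name, e.g. `"working_memory"` or `"reasoning"`.
#' @param members Character vector of node labels.
#' @return Object of class `subnetwork_definition`.
#' @export
subnetwork_definition <- function(name, members) {
  stopifnot(is.character(members), length(members) >= 1,
            !anyDuplicated(members))
  structure(list(name = name, members = members),
            class = "subnetwork_definition")
}

#' Extract the induced subnetwork of a connectome
#'
#' Restricts the weighted matrix to the member nodes; edges between members
#' keep their original weights (the induced subgraph).
#'
#' @param w Weighted connectome with node labels as dimnames.
#' @param members A `subnetwork_definition` or character vector of labels.
#' @return Weighted adjacency matrix over the member nodes.
#' @export
extract_subnetwork <- function(w, members) {
  if (inherits(members, "subnetwork_definition")) members <- members$members
  stopifnot(is.matrix(w), !is.null(rownames(w)))
  missing_members <- setdiff(members, rownames(w))
  if (length(missing_members)) {
    stop("unknown node label(s): ", paste(missing_members, collapse = ", "))
  }
  w[members, members, drop = FALSE]
}

#' Subnetwork definitions from an atlas fixture
#'
#' @param fixture An `atlas_fixture`.
#' @return Named list of two `subnetwork_definition`s: `working_memory` and
#'   `reasoning`.
#' @export
fixture_subnetworks <- function(fixture) {
  list(
    working_memory = subnetwork_definition("working_memory",
                                           fixture$wm_members),
    reasoning = subnetwork_definition("reasoning", fixture$rsn_members)
  )
}
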