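#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, capped at 1 and monotone over the p-value
#' ordering. Thin validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA allowed; excluded and
#'   returned as NA).
#' @return Vector of q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-sample group comparison of network measures
#'
#' Per measure, a two-sample t-test of controls against patients (pooled
#' variance by default), FDR corrected within the supplied family. The sign
#' convention is control mean minus patient mean: a deficit in patients
#' yields a positive t.
#'
#' @param x Numeric matrix or data.frame, subjects x measures.
#' @param group Factor/character vector with levels `control` and `patient`.
#' @param var_equal Pooled-variance t (default `TRUE`); `FALSE` gives Welch.
#' @return data.frame: `measure`, `t`, `p`, `q`, `direction`
#'   (`control > patient` / `patient > control`), `excluded` (zero variance
#'   in both groups; such measures get NA statistics and do not enter the
#'   FDR family).
#' @export
group_compare <- function(x, group, var_equal = TRUE) {
  x <- as.matrix(x)
  group <- as.character(group)
  stopifnot(all(group %in% c("control", "patient")),
            sum(group == "control") >= 2, sum(group == "patient") >= 2,
            nrow(x) == length(group))
  measures <- colnames(x)
  if (is.null(measures)) measures <- paste0("m", seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(j) {
    a <- x[group == "control", j]
    b <- x[group == "patient", j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(data.frame(measure = measures[j], t = NA_real_, p = NA_real_,
                        excluded = TRUE, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(measure = measures[j], t = unname(tt$statistic),
               p = tt$p.value, excluded = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- NA_real_
  res$q[!res$excluded] <- fdr_adjust(res$p[!res$excluded])
  res$direction <- ifelse(is.na(res$t), NA_character_,
                          ifelse(res$t >= 0, "control > patient",
                                 "patient > control"))
  res[c("measure", "t", "p", "q", "direction", "excluded")]
}

#' Correlate network measures with cognitive components, FDR by family
#'
#' Pearson (or Spearman) correlation of every measure in a long-format
#' [metric_table()] against every cognitive component, over patients with
#' matched subject ids, including the cross-paired combinations (working
#' memory network against the reasoning component and vice versa). FDR
#' correction mirrors the analysis families: all global rows form one
#' family (the 12 global correlations when two networks x three metrics x
#' two components are present), while nodal rows are corrected across
#' nodes within each network x metric x component family.
#'
#' @param tbl Long metric table (`subject_id`, `network`, `threshold`,
#'   `metric`, `node`, `value`), typically patients only.
#' @param components Matrix or data.frame of component scores with subject
#'   ids as rownames and one column per component.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: `network`, `metric`, `node`, `component`, `family`,
#'   `n`, `r`, `p`, `q`.
#' @export
correlate_metrics_components <- function(tbl, components,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  components <- as.matrix(components)
  stopifnot(!is.null(rownames(components)), !is.null(colnames(components)))
  tbl <- tbl[tbl$subject_id %in% rownames(components), , drop = FALSE]
  if (!nrow(tbl)) stop("no metric rows match the component subject ids")
  keys <- unique(tbl[c("network", "threshold", "metric", "node")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    kk <- keys[i, ]
    sel <- tbl$network == kk$network & tbl$threshold == kk$threshold &
      tbl$metric == kk$metric &
      (if (is.na(kk$node)) is.na(tbl$node) else !is.na(tbl$node) & tbl$node == kk$node)
    vals <- tbl$value[sel]
    ids <- tbl$subject_id[sel]
    for (comp in colnames(components)) {
      y <- components[ids, comp]
      n_ok <- sum(is.finite(vals) & is.finite(y))
      if (n_ok < 4) stop("fewer than 4 matched subjects for a correlation")
      if (stats::sd(vals) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(vals, y, method = method, exact = FALSE)
        r <- unname(ct$estimate); p <- ct$p.value
      }
      fam <- if (is.na(kk$node)) "global" else {
        paste("nodal", kk$network, kk$metric, comp, sep = ":")
      }
      out[[length(out) + 1L]] <- data.frame(
        network = kk$network, metric = kk$metric, node = kk$node,
        threshold = kk$threshold, component = comp, family = fam,
        n = n_ok, r = r, p = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  out$q <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam & !is.na(out$p)
    out$q[sel] <- fdr_adjust(out$p[sel])
  }
  out
}
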