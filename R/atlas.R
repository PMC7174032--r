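#' Desikan-Killiany style node labels for the 90-region parcellation
#'
#' Returns the fixed 90 region labels used throughout the package: the 34
#' Desikan-Killiany cortical parcels per hemisphere plus 11 subcortical /
#' cerebellar structures per hemisphere. The exact composition beyond the
#' standard cortical set is a package fixture convention chosen to reach the
#' 90-node grey-matter parcellation the connectome analysis operates on.
#'
#' @return Character vector of 90 unique labels, prefixed `lh_` / `rh_`.
#' @export
dk_node_labels <- function() {
  cortical <- c(
    "bankssts", "caudal_anterior_cingulate", "caudal_middle_frontal",
    "cuneus", "entorhinal", "fusiform", "inferior_parietal",
    "inferior_temporal", "isthmus_cingulate", "lateral_occipital",
    "lateral_orbitofrontal", "lingual", "medial_orbitofrontal",
    "middle_temporal", "parahippocampal", "paracentral", "pars_opercularis",
    "pars_orbitalis", "pars_triangularis", "pericalcarine", "postcentral",
    "posterior_cingulate", "precentral", "precuneus",
    "rostral_anterior_cingulate", "rostral_middle_frontal",
    "superior_frontal", "superior_parietal", "superior_temporal",
    "supramarginal", "frontal_pole", "temporal_pole", "transverse_temporal",
    "insula"
  )
  subcortical <- c(
    "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
    "accumbens", "ventral_dc", "cerebellum_cortex", "hypothalamus",
    "basal_forebrain"
  )
  regions <- c(cortical, subcortical)
  c(paste0("lh_", regions), paste0("rh_", regions))
}

# The nine regions with shared membership across the working-memory and
# reasoning subnetworks; printed region names, fixed by construction.
shared_members <- function() {
  c("lh_lateral_orbitofrontal", "lh_precentral", "lh_rostral_middle_frontal",
    "lh_superior_frontal", "rh_caudal_middle_frontal", "rh_precentral",
    "rh_rostral_middle_frontal", "rh_superior_frontal", "rh_superior_parietal")
}

# Members exclusive to the working-memory subnetwork (22, giving 31 in total
# with the shared nine). Includes the six eventual hub regions; the remainder
# fill the list to size as a fixture convention.
wm_exclusive_members <- function() {
  c("lh_caudate", "rh_pallidum", "lh_insula", "rh_insula", "rh_precuneus",
    "rh_paracentral", "rh_supramarginal", "lh_caudal_anterior_cingulate",
    "rh_rostral_anterior_cingulate", "lh_thalamus", "rh_thalamus",
    "rh_caudate", "lh_pallidum", "lh_putamen", "rh_putamen",
    "lh_supramarginal", "lh_precuneus", "lh_paracentral", "lh_postcentral",
    "rh_postcentral", "lh_superior_temporal", "rh_superior_temporal")
}

# Members exclusive to the reasoning subnetwork (17, giving 26 in total).
rsn_exclusive_members <- function() {
  c("lh_superior_parietal", "rh_inferior_parietal", "lh_inferior_parietal",
    "lh_lateral_occipital", "rh_lateral_occipital", "lh_cuneus", "rh_cuneus",
    "rh_lingual", "lh_lingual", "rh_pericalcarine", "lh_pericalcarine",
    "lh_pars_opercularis", "rh_pars_opercularis", "rh_inferior_temporal",
    "rh_temporal_pole", "lh_middle_temporal", "rh_middle_temporal")
}

#' Build the atlas fixture: labels, streamline counts and subnetwork lists
#'
#' Constructs the fixed 90-node parcellation with a random but seeded
#' symmetric streamline-count matrix (emulating a probabilistic-tractography
#' atlas of region-to-region white-matter connections) and the two
#' functionally defined subnetwork membership lists: working memory
#' (31 nodes) and reasoning (26 nodes), sharing 9 nodes.
#'
#' Streamline counts are log-normal across connected pairs; a pair is
#' connected with probability `edge_density`. Unconnected pairs have count 0
#' and stay absent in every derived connectome.
#'
#' @param seed Integer seed controlling the streamline matrix.
#' @param edge_density Fraction of region pairs connected by a tract.
#' @return Object of class `atlas_fixture`: list with `node_labels`
#'   (90 labels), `streamlines` (90 x 90 symmetric integer matrix, zero
#'   diagonal), `wm_members` (31 labels), `rsn_members` (26 labels).
#' @export
make_atlas_fixture <- function(seed = 1L, edge_density = 0.3) {
  stopifnot(edge_density > 0, edge_density <= 1)
  labels <- dk_node_labels()
  n <- length(labels)
  s <- matrix(0L, n, n, dimnames = list(labels, labels))
  withr::with_seed(as.integer(seed), {
    up <- upper.tri(s)
    connected <- stats::runif(sum(up)) < edge_density
    counts <- integer(sum(up))
    counts[connected] <- pmax(
      1L, as.integer(round(stats::rlnorm(sum(connected), log(40), 0.9)))
    )
    s[up] <- counts
  })
  s <- s + t(s)
  fixture <- list(
    node_labels = labels,
    streamlines = s,
    wm_members = c(shared_members(), wm_exclusive_members()),
    rsn_members = c(shared_members(), rsn_exclusive_members())
  )
  class(fixture) <- "atlas_fixture"
  validate_atlas_fixture(fixture)
  fixture
}

validate_atlas_fixture <- function(fixture) {
  stopifnot(
    length(fixture$node_labels) == 90L,
    !anyDuplicated(fixture$node_labels),
    length(fixture$wm_members) == 31L,
    length(fixture$rsn_members) == 26L,
    length(intersect(fixture$wm_members, fixture$rsn_members)) == 9L,
    all(fixture$wm_members %in% fixture$node_labels),
    all(fixture$rsn_members %in% fixture$node_labels),
    isTRUE(all.equal(fixture$streamlines, t(fixture$streamlines))),
    all(diag(fixture$streamlines) == 0),
    all(fixture$streamlines >= 0)
  )
  invisible(fixture)
}

#' @export
print.atlas_fixture <- function(x, ...) {
  cat("Atlas fixture: 90 nodes,",
      sum(x$streamlines[upper.tri(x$streamlines)] > 0), "tracts;",
      "WM subnetwork", length(x$wm_members), "nodes,",
      "reasoning subnetwork", length(x$rsn_members), "nodes,",
      length(intersect(x$wm_members, x$rsn_members)), "shared\n")
  invisible(x)
}
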