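#' Write / read a labelled connectivity matrix as dense CSV
#'
#' @param w Square matrix with node labels as dimnames.
#' @param path CSV file path.
#' @return `read_connectome_csv` returns the matrix; the writer returns the
#'   path invisibly.
#' @export
write_connectome_csv <- function(w, path) {
  utils::write.csv(as.data.frame(w), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write / read the cohort table (subjects x group, age, task scores)
#'
#' The on-disk format is a plain CSV with header
#' `subject_id,group,age,MKL,PAL,SOS,FTM,OOO,HTT`.
#'
#' @param cohort Cohort data.frame.
#' @param path CSV file path.
#' @return `read_cohort_csv` returns the validated data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(all(c("subject_id", "group", "age", task_codes()) %in% names(cohort)))
  utils::write.csv(cohort[c("subject_id", "group", "age", task_codes())],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", task_codes())
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(cohort$group)) || any(is.na(cohort$age))) {
    stop("cohort file has missing group or age values")
  }
  cohort[required]
}

#' Serialise / load an atlas fixture as plain-text files
#'
#' Writes `node_labels.txt`, `wm_members.txt`, `rsn_members.txt` (one label
#' per line) and `streamlines.csv` (dense labelled matrix) under `dir`.
#'
#' @param fixture An `atlas_fixture`.
#' @param dir Directory (created if needed).
#' @return `read_fixture` returns a validated `atlas_fixture`.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(fixture$node_labels, file.path(dir, "node_labels.txt"))
  writeLines(fixture$wm_members, file.path(dir, "wm_members.txt"))
  writeLines(fixture$rsn_members, file.path(dir, "rsn_members.txt"))
  write_connectome_csv(fixture$streamlines, file.path(dir, "streamlines.csv"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  fixture <- list(
    node_labels = readLines(file.path(dir, "node_labels.txt")),
    streamlines = read_connectome_csv(file.path(dir, "streamlines.csv")),
    wm_members = readLines(file.path(dir, "wm_members.txt")),
    rsn_members = readLines(file.path(dir, "rsn_members.txt"))
  )
  class(fixture) <- "atlas_fixture"
  validate_atlas_fixture(fixture)
  fixture
}
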