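#' Multi-subject hemodynamic cohort
#'
#' A cohort bundles one channel-by-time matrix per subject together with the
#' metadata the synchrony analyses require: subject identifiers, optional group
#' labels, the sampling rate, and channel identifiers. All subjects must share
#' the channel set, recording length, and sampling rate, because intersubject
#' correlation is only defined on time-locked recordings.
#'
#' @param data named list of numeric matrices, one per subject, each
#'   channels x time. Names are taken as subject ids when `subjects` is `NULL`.
#' @param subjects character vector of subject ids (optional).
#' @param group optional per-subject labels (e.g. training arm).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_ids optional channel names; defaults to `ch1..chK`.
#' @return an object of class `"nsync_cohort"`.
#' @export
cohort <- function(data, subjects = NULL, group = NULL, sampling_rate,
                   channel_ids = NULL) {
  .assert(is.list(data) && length(data) >= 1, "data must be a non-empty list")
  data <- lapply(data, function(m) {
    if (is.vector(m)) m <- matrix(m, nrow = 1)
    .assert(is.matrix(m) && is.numeric(m), "each subject needs a numeric matrix")
    m
  })
  if (is.null(subjects)) {
    subjects <- names(data)
    if (is.null(subjects)) subjects <- paste0("sub", seq_along(data))
  }
  .assert(length(subjects) == length(data), "subjects/data length mismatch")
  .assert(!anyDuplicated(subjects), "duplicate subject ids")
  dims <- vapply(data, dim, integer(2))
  .assert(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
          "all subjects must share channel count and recording length")
  .assert(is.numeric(sampling_rate) && sampling_rate > 0,
          "sampling_rate must be positive")
  if (!is.null(group)) {
    .assert(length(group) == length(data), "group labels/data length mismatch")
  }
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(dims[1, 1]))
  .assert(length(channel_ids) == dims[1, 1], "channel_ids length mismatch")
  names(data) <- subjects
  structure(
    list(subjects = as.character(subjects), data = data,
         group = group, sampling_rate = sampling_rate,
         channel_ids = as.character(channel_ids)),
    class = "nsync_cohort")
}

#' @export
print.nsync_cohort <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("<nsync_cohort> %d subjects, %d channels x %d samples @ %.3g Hz\n",
              length(x$subjects), d[1], d[2], x$sampling_rate))
  if (!is.null(x$group)) {
    cat("  groups:", paste(sprintf("%s=%d", names(table(x$group)),
                                   as.integer(table(x$group))), collapse = ", "), "\n")
  }
  invisible(x)
}

n_subjects <- function(cohort) length(cohort$subjects)
n_channels <- function(cohort) nrow(cohort$data[[1]])
n_timepoints <- function(cohort) ncol(cohort$data[[1]])

# subjects x time matrix for one channel
.channel_matrix <- function(cohort, channel) {
  ch <- .resolve_channel(cohort, channel)
  t(vapply(cohort$data, function(m) m[ch, ], numeric(n_timepoints(cohort))))
}

.resolve_channel <- function(cohort, channel) {
  if (is.character(channel)) {
    ch <- match(channel, cohort$channel_ids)
    .assert(!is.na(ch), sprintf("unknown channel '%s'", channel))
    return(ch)
  }
  .assert(channel >= 1 && channel <= n_channels(cohort), "channel out of range")
  as.integer(channel)
}

#' Similarity / dissimilarity matrix between subjects
#'
#' Symmetric subject-by-subject matrix with an explicit `kind` declaring its
#' orientation and diagonal convention: `"pearson_r"` (diagonal 1),
#' `"sq_euclidean"` (a distance; diagonal 0) or `"annak_similarity"`
#' (diagonal `rank_i / n`).
#'
#' @param values symmetric numeric matrix.
#' @param kind one of `"pearson_r"`, `"sq_euclidean"`, `"annak_similarity"`.
#' @param subjects optional subject ids.
#' @return object of class `"similarity_matrix"`.
#' @export
similarity_matrix <- function(values,
                              kind = c("pearson_r", "sq_euclidean",
                                       "annak_similarity"),
                              subjects = NULL) {
  kind <- match.arg(kind)
  .assert(is.matrix(values) && nrow(values) == ncol(values),
          "values must be a square matrix")
  .assert(max(abs(values - t(values))) <= 1e-12, "matrix must be symmetric")
  if (kind == "pearson_r") {
    .assert(all(values >= -1 - 1e-9 & values <= 1 + 1e-9),
            "correlations must lie in [-1, 1]")
  }
  if (kind == "sq_euclidean") {
    .assert(all(values >= -1e-12), "distances must be non-negative")
  }
  if (is.null(subjects)) {
    subjects <- rownames(values)
    if (is.null(subjects)) subjects <- paste0("sub", seq_len(nrow(values)))
  }
  dimnames(values) <- list(subjects, subjects)
  structure(list(values = values, kind = kind, subjects = subjects),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> kind=%s, n=%d\n", x$kind, nrow(x$values)))
  invisible(x)
}

# strictly-upper-triangle entries, column-major order (shared by isrsa/mantel)
.upper_tri <- function(m) m[upper.tri(m)]
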