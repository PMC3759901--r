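#' Study design for a longitudinal expression cohort
#'
#' Describes which sample column belongs to which patient and time point, on
#' which platform, and (for two-card TaqMan arrays) on which card. The first
#' time-point label is the designated baseline against which all later time
#' points are compared.
#'
#' @param samples data.frame with columns `sample_id`, `patient`, `time_point`
#'   and optionally `card` (values `"A"`/`"B"`) and `replicate` (for
#'   single-tube assays measured in triplicate).
#' @param time_points character vector giving the time-point labels in
#'   chronological order; defaults to their order of first appearance in
#'   `samples`. The first label is the baseline.
#' @param platform one of `"taqman_card"`, `"affy_mrna"`, `"affy_mirna"`,
#'   `"taqman_single"`.
#' @return An object of class `study_design`: a list with elements `samples`
#'   (the validated sample table), `patients`, `time_points`, `baseline`
#'   (always `time_points[1]`) and `platform`.
#' @examples
#' sheet <- expand.grid(patient = c("Pat1", "Pat2"),
#'                      time_point = c("baseline", "t48h", "t96h", "m1"),
#'                      stringsAsFactors = FALSE)
#' sheet$sample_id <- paste(sheet$patient, sheet$time_point, sep = "_")
#' study_design(sheet)
#' @export
study_design <- function(samples, time_points = NULL,
                         platform = c("taqman_card", "affy_mrna",
                                      "affy_mirna", "taqman_single")) {
  platform <- match.arg(platform)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient", "time_point")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0L)
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  for (v in req) samples[[v]] <- as.character(samples[[v]])
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet")

  if (is.null(time_points)) {
    time_points <- unique(samples$time_point)
  } else {
    time_points <- as.character(time_points)
    extra <- setdiff(samples$time_point, time_points)
    if (length(extra) > 0L)
      stop("time points in sample sheet not in 'time_points': ",
           paste(extra, collapse = ", "))
  }
  if (length(time_points) < 2L)
    stop("a study design needs at least 2 time points")
  patients <- unique(samples$patient)
  if (length(patients) < 1L) stop("a study design needs at least 1 patient")

  has_rep <- "replicate" %in% names(samples)
  key <- paste(samples$patient, samples$time_point,
               if (has_rep) samples$replicate else "", sep = "\r")
  if (anyDuplicated(key))
    stop("each (patient, time_point", if (has_rep) ", replicate" else "",
         ") pair must map to exactly one sample column")
  if (!has_rep) {
    full <- expand.grid(patient = patients, time_point = time_points,
                        stringsAsFactors = FALSE)
    got <- paste(samples$patient, samples$time_point, sep = "\r")
    want <- paste(full$patient, full$time_point, sep = "\r")
    if (!all(want %in% got))
      stop("missing sample column(s) for: ",
           paste(setdiff(want, got), collapse = "; "))
  }
  # canonical column order: patient, then time point
  ord <- order(match(samples$patient, patients),
               match(samples$time_point, time_points))
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL

  structure(list(samples = samples, patients = patients,
                 time_points = time_points, baseline = time_points[1L],
                 platform = platform),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design (", x$platform, "): ", length(x$patients), " patient(s) x ",
      length(x$time_points), " time point(s)\n", sep = "")
  cat("  time points:", paste(x$time_points, collapse = ", "),
      "(baseline:", x$baseline, ")\n")
  cat("  samples:", nrow(x$samples), "\n")
  invisible(x)
}

# sample ids for one patient in chronological time-point order
design_columns <- function(design, patient) {
  s <- design$samples
  s <- s[s$patient == patient, , drop = FALSE]
  s$sample_id[match(design$time_points, s$time_point)]
}

#' Randomly rearrange each patient's temporal sequence
#'
#' Draws, independently for every patient, a uniform random permutation of its
#' time-point labels (the identity permutation is allowed) and returns a new
#' design in which the samples carry the permuted labels. Platform and card
#' assignments are untouched. This is the elementary move of the permutation
#' null for the filtered-feature count.
#'
#' @param design a [study_design()].
#' @return A `study_design` with relabelled time points.
#' @seealso [relabel_design()] for a deterministic relabelling,
#'   [permutation_test()] for the test built on this move.
#' @export
permute_design <- function(design) {
  tp <- design$time_points
  perms <- lapply(design$patients, function(p) sample.int(length(tp)))
  names(perms) <- design$patients
  relabel_design(design, perms)
}

#' Deterministically relabel each patient's time points
#'
#' Applies a given permutation of the time-point labels to each patient. Used
#' by [permute_design()] and by exhaustive enumeration of all joint
#' relabellings on small designs.
#'
#' @param design a [study_design()].
#' @param perms named list (one element per patient) of integer permutation
#'   vectors of `seq_along(design$time_points)`: the sample currently labelled
#'   `time_points[i]` receives the label `time_points[perms[[p]][i]]`.
#' @return A relabelled `study_design`.
#' @export
relabel_design <- function(design, perms) {
  s <- design$samples
  tp <- design$time_points
  for (p in design$patients) {
    pi <- perms[[p]]
    if (is.null(pi)) pi <- seq_along(tp)
    stopifnot(length(pi) == length(tp), all(sort(pi) == seq_along(tp)))
    rows <- which(s$patient == p)
    s$time_point[rows] <- tp[pi[match(s$time_point[rows], tp)]]
  }
  study_design(s, time_points = tp, platform = design$platform)
}
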