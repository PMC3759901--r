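#' Longitudinal feature-by-sample expression matrix
#'
#' The container moved through the whole pipeline: a numeric matrix of feature
#' values (rows = miRNAs or genes, columns = samples), the scale the values
#' live on, a detection mask, and the [study_design()] the columns belong to.
#'
#' Scales: `"ct"` for raw real-time PCR threshold cycles (undetermined wells
#' encoded as Ct 45), `"linear"` for non-negative expression signals, `"log2"`
#' for log-transformed intensities. The detection mask marks wells whose raw Ct
#' fell below the detection limit; it is carried unchanged through
#' normalization so detection counts are invariant.
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids matching the design's sample sheet).
#' @param design a [study_design()].
#' @param scale one of `"ct"`, `"linear"`, `"log2"`.
#' @param detection_mask logical matrix of the same shape (`TRUE` = detected);
#'   defaults to all `TRUE` for linear/log2 input and to `values <
#'   detection_limit` for Ct input.
#' @param detection_limit Ct detection limit used for the default mask.
#' @param card optional character vector (`"A"`/`"B"`, named by feature or in
#'   row order) assigning each assay to its card; two-card TaqMan sets are
#'   loess-normalized and quantile-anchored per (patient, card). Defaults to a
#'   single card.
#' @return An object of class `long_matrix`.
#' @export
longitudinal_matrix <- function(values, design, scale = c("linear", "ct", "log2"),
                                detection_mask = NULL, detection_limit = 38,
                                card = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("values must have feature rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  ids <- design$samples$sample_id
  if (is.null(colnames(values))) stop("values must have sample colnames")
  absent <- setdiff(colnames(values), ids)
  if (length(absent) > 0L)
    stop("design error: matrix column(s) without sample-sheet entry: ",
         paste(absent, collapse = ", "))
  absent <- setdiff(ids, colnames(values))
  if (length(absent) > 0L)
    stop("design error: sample-sheet entry without matrix column: ",
         paste(absent, collapse = ", "))
  perm <- match(ids, colnames(values))   # canonical (patient, time) order
  values <- values[, perm, drop = FALSE]
  if (anyNA(values) || !all(is.finite(values)))
    stop("values must be finite and non-missing")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale values must be >= 0")
  if (scale == "ct" && any(values < 0))
    stop("negative Ct values are invalid")
  if (is.null(detection_mask)) {
    detection_mask <- if (scale == "ct") values < detection_limit
                      else matrix(TRUE, nrow(values), ncol(values))
    dimnames(detection_mask) <- dimnames(values)
  } else {
    stopifnot(is.logical(detection_mask),
              all(dim(detection_mask) == dim(values)))
    # same column permutation as the values; unnamed masks are taken to be in
    # the input column order
    if (!is.null(colnames(detection_mask)))
      detection_mask <- detection_mask[, ids, drop = FALSE]
    else
      detection_mask <- detection_mask[, perm, drop = FALSE]
    dimnames(detection_mask) <- dimnames(values)
  }
  if (is.null(card)) {
    card <- rep("A", nrow(values))
  } else {
    card <- as.character(card)
    if (!is.null(names(card))) card <- card[rownames(values)]
    if (length(card) != nrow(values) || anyNA(card))
      stop("card must assign one card to every feature")
  }
  names(card) <- rownames(values)
  structure(list(values = values, scale = scale,
                 detection_mask = detection_mask, design = design,
                 card = card),
            class = "long_matrix")
}

#' @export
print.long_matrix <- function(x, ...) {
  cat("Longitudinal matrix: ", nrow(x$values), " features x ",
      ncol(x$values), " samples [scale: ", x$scale, "]\n", sep = "")
  cat("  detected wells: ", sum(x$detection_mask), "/",
      length(x$detection_mask), "\n", sep = "")
  print(x$design)
  invisible(x)
}

#' @export
dim.long_matrix <- function(x) dim(x$values)

#' Per-sample detection counts
#'
#' Number of features detected (raw Ct below the detection limit) in each
#' sample, the quality metric reported per card and time point.
#'
#' @param x a [longitudinal_matrix()].
#' @return Named integer vector, one entry per sample.
#' @export
detection_counts <- function(x) colSums(x$detection_mask)

#' Read a feature-by-sample matrix with its sample sheet
#'
#' Reads a tab-delimited matrix (first column = feature id, header = sample
#' ids) plus a CSV sample sheet with columns `sample_id`, `patient`,
#' `time_point` and optionally `platform`, `card`, `replicate`, and returns a
#' validated [longitudinal_matrix()]. For Ct input the literal
#' `"Undetermined"` is accepted and encoded as Ct 45.
#'
#' @param path path to the TSV matrix.
#' @param sample_sheet path to the CSV sample sheet.
#' @param scale scale of the stored values (`"ct"`, `"linear"`, `"log2"`).
#' @param platform platform tag for the design; defaults to the sheet's
#'   `platform` column if present, else `"taqman_card"`.
#' @param time_points optional chronological time-point order (first =
#'   baseline); defaults to order of appearance in the sheet.
#' @param blacklist optional character vector of feature ids to drop on load
#'   (e.g. assays retired from the miRNA annotation).
#' @param detection_limit Ct detection limit for the default mask.
#' @param card optional per-feature card assignment (see
#'   [longitudinal_matrix()]).
#' @return A `long_matrix`.
#' @export
read_matrix <- function(path, sample_sheet, scale = c("linear", "ct", "log2"),
                        platform = NULL, time_points = NULL, blacklist = NULL,
                        detection_limit = 38, card = NULL) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix file needs a feature column plus samples")
  features <- raw[[1L]]
  dup <- features[duplicated(features)]
  if (length(dup) > 0L)
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  if (scale == "ct") cells[trimws(cells) %in% c("Undetermined", "undetermined")] <- "45"
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error in %s: non-numeric value '%s' at row %d (%s), column '%s'",
                 path, cells[bad[1L], bad[2L]], bad[1L], features[bad[1L]],
                 colnames(cells)[bad[2L]]))
  }
  dimnames(num) <- list(features, colnames(cells))
  if (!is.null(blacklist)) {
    keep <- !(features %in% blacklist)
    num <- num[keep, , drop = FALSE]
  }
  sheet <- utils::read.csv(sample_sheet, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (is.null(platform))
    platform <- if ("platform" %in% names(sheet)) sheet$platform[1L] else "taqman_card"
  design <- study_design(sheet, time_points = time_points, platform = platform)
  longitudinal_matrix(num, design, scale = scale,
                      detection_limit = detection_limit, card = card)
}

#' Write a longitudinal matrix (and optionally its sample sheet) to disk
#'
#' Inverse of [read_matrix()]: values go to a TSV with the feature id in the
#' first column, the design to a CSV sample sheet. The round trip is lossless
#' for values, mask (reconstructed from Ct and the detection limit) and design
#' metadata.
#'
#' @param x a [longitudinal_matrix()].
#' @param path output TSV path.
#' @param sheet_path optional output CSV path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, sheet_path = NULL) {
  df <- data.frame(feature = rownames(x$values),
                   x$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sheet_path)) {
    s <- x$design$samples
    if (!"platform" %in% names(s)) s$platform <- x$design$platform
    utils::write.csv(s, sheet_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read miRNA-target interaction tables
#'
#' Merges a prediction export (columns `mirna`, `gene`, `n_algorithms`: how
#' many of the 10 prediction algorithms support the pair) with a validation
#' export (columns `mirna`, `gene`) into one interaction table. A pair present
#' in both files keeps its algorithm count and is marked validated.
#'
#' @param predicted_path CSV of predicted interactions.
#' @param validated_path CSV of experimentally validated interactions
#'   (optional; `NULL` for predictions only).
#' @return A data.frame of class `interaction_table` with columns `mirna`,
#'   `gene`, `n_algorithms` (NA for validated-only pairs), `validated`,
#'   `source` (`"predicted"`, `"validated"` or `"both"`).
#' @export
read_interactions <- function(predicted_path, validated_path = NULL) {
  pred <- utils::read.csv(predicted_path, stringsAsFactors = FALSE)
  need <- c("mirna", "gene", "n_algorithms")
  if (!all(need %in% names(pred)))
    stop("predicted file needs columns: ", paste(need, collapse = ", "))
  pred$n_algorithms <- as.numeric(pred$n_algorithms)
  val <- if (is.null(validated_path)) {
    data.frame(mirna = character(), gene = character())
  } else {
    utils::read.csv(validated_path, stringsAsFactors = FALSE)
  }
  if (!all(c("mirna", "gene") %in% names(val)))
    stop("validated file needs columns: mirna, gene")
  interaction_table(pred[, need], val[, c("mirna", "gene")])
}

#' Build an interaction table from prediction and validation records
#'
#' @param predicted data.frame with columns `mirna`, `gene`, `n_algorithms`.
#' @param validated data.frame with columns `mirna`, `gene`.
#' @return An `interaction_table` data.frame (see [read_interactions()]).
#' @export
interaction_table <- function(predicted,
                              validated = data.frame(mirna = character(),
                                                     gene = character())) {
  predicted <- as.data.frame(predicted, stringsAsFactors = FALSE)
  validated <- as.data.frame(validated, stringsAsFactors = FALSE)
  if (nrow(predicted) > 0L) {
    if (any(!is.finite(predicted$n_algorithms)) ||
        any(predicted$n_algorithms < 0 | predicted$n_algorithms > 10))
      stop("n_algorithms must be between 0 and 10")
    if (anyDuplicated(paste(predicted$mirna, predicted$gene, sep = "\r")))
      stop("duplicate (mirna, gene) pair in predicted records")
  }
  if (nrow(validated) > 0L &&
      anyDuplicated(paste(validated$mirna, validated$gene, sep = "\r")))
    stop("duplicate (mirna, gene) pair in validated records")

  pk <- paste(predicted$mirna, predicted$gene, sep = "\r")
  vk <- paste(validated$mirna, validated$gene, sep = "\r")
  out <- data.frame(mirna = predicted$mirna, gene = predicted$gene,
                    n_algorithms = predicted$n_algorithms,
                    validated = pk %in% vk,
                    stringsAsFactors = FALSE)
  out$source <- ifelse(out$validated, "both", "predicted")
  only_val <- !(vk %in% pk)
  if (any(only_val)) {
    out <- rbind(out, data.frame(mirna = validated$mirna[only_val],
                                 gene = validated$gene[only_val],
                                 n_algorithms = NA_real_, validated = TRUE,
                                 source = "validated",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}
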