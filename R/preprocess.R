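#' Preprocessing parameters
#'
#' Bundles the tunables of the TaqMan/intensity preprocessing stage.
#'
#' @param detection_limit_ct Ct detection limit; wells with raw Ct above it are
#'   censored to the limit and flagged undetected (default 38, so the floor
#'   signal is 2^-38 * 1e9 = 0.0036, printed as 0.004).
#' @param undetermined_ct sentinel Ct encoding wells that never crossed the
#'   fluorescence threshold (default 45).
#' @param linear_scale_factor multiplier of 2^(-Ct) for the linear scale
#'   (default 1e9, the value forced by the anchor points Ct 38 -> 0.004 and
#'   Ct 20 -> 953).
#' @param quantile pooled per-patient quantile equalized across patients by
#'   [quantile_scale()] (default 0.95).
#' @param loess_span span of the local regressions in [loess_normalize()]
#'   (default 0.7).
#' @param hk_feature housekeeping feature for [relative_quantify()]
#'   (default `"hsa-miR-191-5p"`).
#' @param report_scale multiplier applied to housekeeping-normalized ratios
#'   (default 1000).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(detection_limit_ct = 38, undetermined_ct = 45,
                              linear_scale_factor = 1e9, quantile = 0.95,
                              loess_span = 0.7, hk_feature = "hsa-miR-191-5p",
                              report_scale = 1000) {
  stopifnot(quantile > 0, quantile < 1,
            detection_limit_ct < undetermined_ct,
            loess_span > 0, loess_span <= 1,
            linear_scale_factor > 0, report_scale > 0)
  structure(list(detection_limit_ct = detection_limit_ct,
                 undetermined_ct = undetermined_ct,
                 linear_scale_factor = linear_scale_factor,
                 quantile = quantile, loess_span = loess_span,
                 hk_feature = hk_feature, report_scale = report_scale),
            class = "preprocess_params")
}

#' Convert Ct values to the linear expression scale
#'
#' Vectorized scalar form of the conversion: Ct is censored at the detection
#' limit and mapped to `2^(-Ct) * linear_scale_factor`. One PCR cycle
#' corresponds to a doubling, so the map is strictly decreasing and satisfies
#' `ct_signal(ct - 1) == 2 * ct_signal(ct)`.
#'
#' @param ct numeric vector of threshold cycles (must be non-negative).
#' @param params a [preprocess_params()].
#' @return Numeric vector of linear-scale signals.
#' @examples
#' ct_signal(38)  # 0.0036..., the detection-floor signal, printed as 0.004
#' ct_signal(20)  # 953.67...
#' @export
ct_signal <- function(ct, params = preprocess_params()) {
  if (any(ct < 0)) stop("negative Ct values are invalid")
  ct <- pmin(ct, params$detection_limit_ct)
  2^(-ct) * params$linear_scale_factor
}

#' Censor a Ct matrix at the detection limit and convert to linear scale
#'
#' Every well with raw Ct above the detection limit (including the Ct 45
#' sentinel for undetermined wells) is censored to the limit and flagged as
#' undetected in the mask, then all values are converted with [ct_signal()].
#' Censored wells therefore all carry exactly the detection-floor signal.
#'
#' @param x a `ct`-scale [longitudinal_matrix()].
#' @param params a [preprocess_params()].
#' @return A `linear`-scale `long_matrix` with updated detection mask
#'   (`TRUE` iff raw Ct < detection limit).
#' @export
ct_to_linear <- function(x, params = preprocess_params()) {
  stopifnot(inherits(x, "long_matrix"))
  if (x$scale != "ct") stop("ct_to_linear expects a ct-scale matrix")
  mask <- x$values < params$detection_limit_ct
  vals <- ct_signal(x$values, params)
  dimnames(vals) <- dimnames(x$values)
  dimnames(mask) <- dimnames(x$values)
  longitudinal_matrix(vals, x$design, scale = "linear", detection_mask = mask,
                      card = x$card)
}

# (feature rows, sample columns) blocks for group-wise normalization:
# per (patient, card) for TaqMan two-card sets, or one joint block
norm_blocks <- function(x, group_by) {
  if (group_by == "all_samples")
    return(list(list(rows = seq_len(nrow(x$values)),
                     ids = x$design$samples$sample_id)))
  blocks <- list()
  for (p in x$design$patients) {
    ids <- x$design$samples$sample_id[x$design$samples$patient == p]
    for (cd in unique(x$card)) {
      blocks[[paste(p, cd, sep = ".")]] <-
        list(rows = which(x$card == cd), ids = ids)
    }
  }
  blocks
}

# one cycle of pairwise loess on log2 values within a group of columns.
# Wells undetected in either sample of a pair are excluded from curve fitting
# but still corrected.
cyclic_loess_group <- function(lv, det, span) {
  n <- ncol(lv)
  adj <- matrix(0, nrow(lv), n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      M <- lv[, i] - lv[, j]
      A <- (lv[, i] + lv[, j]) / 2
      use <- det[, i] & det[, j]
      if (sum(use) < 10L) next
      au <- A[use]
      fit <- stats::loess(M[use] ~ au, span = span, degree = 1L,
                          family = "gaussian")
      a_clamp <- pmin(pmax(A, min(au)), max(au))
      m_hat <- stats::predict(fit, newdata = data.frame(au = a_clamp))
      adj[, i] <- adj[, i] - m_hat / 2
      adj[, j] <- adj[, j] + m_hat / 2
    }
  }
  lv + adj / (n - 1L)
}

#' Cyclic loess normalization of a linear-scale matrix
#'
#' Removes intensity-dependent systematic differences between samples by
#' pairwise (cyclic) loess on log2 values: for every sample pair the log ratio
#' M is regressed on the mean log intensity A with a degree-1 local fit, and
#' half of the fitted trend is subtracted from each side; corrections are
#' averaged over one full cycle of all pairs. Normalization is applied
#' separately within each (patient, card) group for TaqMan card data, or over
#' all samples jointly for a single-batch intensity matrix. Undetected wells
#' never enter the curve fits and are re-anchored at the detection-floor
#' signal afterwards, so detection counts are invariant.
#'
#' @param x a `linear`-scale [longitudinal_matrix()].
#' @param params a [preprocess_params()] (span, detection floor).
#' @param group_by `"patient_and_card"` (default, TaqMan cards) or
#'   `"all_samples"` (summarized intensity matrices).
#' @return A normalized `linear`-scale `long_matrix`.
#' @export
loess_normalize <- function(x, params = preprocess_params(),
                            group_by = c("patient_and_card", "all_samples")) {
  stopifnot(inherits(x, "long_matrix"))
  group_by <- match.arg(group_by)
  if (x$scale != "linear") stop("loess_normalize expects a linear-scale matrix")
  blocks <- norm_blocks(x, group_by)
  bad <- vapply(blocks, function(b) length(b$ids), 1L) < 2L
  if (any(bad))
    stop("configuration error: normalization group(s) with < 2 samples: ",
         paste(names(blocks)[bad], collapse = ", "))
  floor_sig <- ct_signal(params$detection_limit_ct, params)
  vals <- x$values
  lv_all <- log2(pmax(vals, .Machine$double.xmin))
  for (b in blocks) {
    lv <- cyclic_loess_group(lv_all[b$rows, b$ids, drop = FALSE],
                             x$detection_mask[b$rows, b$ids, drop = FALSE],
                             params$loess_span)
    vals[b$rows, b$ids] <- 2^lv
  }
  if (any(!x$detection_mask)) vals[!x$detection_mask] <- floor_sig
  longitudinal_matrix(vals, x$design, scale = "linear",
                      detection_mask = x$detection_mask, card = x$card)
}

#' Anchor each patient's upper quantile to a common target
#'
#' Per card, pools all of a patient's samples and multiplies them by one
#' scalar so that every patient's pooled 95% quantile (or `params$quantile`)
#' equals a common target, the geometric mean of the per-patient pre-scaling
#' quantiles. Within-patient ratios are unchanged, so fold changes are
#' unaffected; only between-patient scale differences (e.g. a card with
#' globally shifted Ct values) are removed. The operation is idempotent.
#'
#' @param x a `linear`-scale [longitudinal_matrix()].
#' @param params a [preprocess_params()].
#' @return A rescaled `linear`-scale `long_matrix` with attribute
#'   `"scale_factors"` (named per patient.card group).
#' @export
quantile_scale <- function(x, params = preprocess_params()) {
  stopifnot(inherits(x, "long_matrix"))
  if (x$scale != "linear") stop("quantile_scale expects a linear-scale matrix")
  s <- x$design$samples
  pats <- x$design$patients
  vals <- x$values
  factors <- c()
  for (cd in unique(x$card)) {
    rows <- x$card == cd
    # pooled per-patient quantile of detected wells on this card
    q <- vapply(pats, function(p) {
      ids <- s$sample_id[s$patient == p]
      v <- vals[rows, ids]
      det <- x$detection_mask[rows, ids]
      if (!any(det)) return(NA_real_)
      stats::quantile(v, probs = params$quantile, names = FALSE)
    }, 1)
    ok <- is.finite(q) & q > 0
    if (!all(ok))
      warning("patient(s) with all-censored card ", cd, ": ",
              paste(pats[!ok], collapse = ", "), "; scale factor 1")
    target <- exp(mean(log(q[ok])))
    f <- ifelse(ok, target / q, 1)
    names(f) <- paste(pats, cd, sep = ".")
    factors <- c(factors, f)
    for (i in seq_along(pats)) {
      ids <- s$sample_id[s$patient == pats[i]]
      vals[rows, ids] <- vals[rows, ids] * f[i]
    }
  }
  out <- longitudinal_matrix(vals, x$design, scale = "linear",
                             detection_mask = x$detection_mask, card = x$card)
  attr(out, "scale_factors") <- factors
  out
}

#' Housekeeping-normalized relative quantification of single-tube assays
#'
#' For triplicate single-tube real-time PCR measurements: per (patient, time
#' point), Ct values are censored at the detection limit, averaged over the
#' replicates, converted to the linear scale as 2^(-Ct), divided by the
#' housekeeping feature's signal in the same sample, and scaled by 1000.
#' The housekeeping feature itself therefore reads 1000 everywhere and a
#' feature one cycle above it reads 500.
#'
#' @param x a `ct`-scale [longitudinal_matrix()] whose design has a
#'   `replicate` column marking replicate wells of the same sample.
#' @param params a [preprocess_params()] (housekeeping id, report scale).
#' @return A `linear`-scale `long_matrix` with one column per
#'   (patient, time point).
#' @export
relative_quantify <- function(x, params = preprocess_params()) {
  stopifnot(inherits(x, "long_matrix"))
  if (x$scale != "ct") stop("relative_quantify expects a ct-scale matrix")
  if (!params$hk_feature %in% rownames(x$values))
    stop("housekeeping feature '", params$hk_feature, "' not in matrix")
  s <- x$design$samples
  key <- paste(s$patient, s$time_point, sep = "\r")
  groups <- split(s$sample_id, key)
  ug <- unique(key)
  groups <- groups[ug]
  ct_cens <- pmin(x$values, params$detection_limit_ct)
  mean_ct <- vapply(groups, function(ids)
    rowMeans(ct_cens[, ids, drop = FALSE]), numeric(nrow(ct_cens)))
  if (any(mean_ct[params$hk_feature, ] >= params$detection_limit_ct))
    stop("housekeeping feature undetected in at least one sample")
  sig <- 2^(-mean_ct)
  vals <- params$report_scale * sweep(sig, 2, sig[params$hk_feature, ], "/")
  uk <- do.call(rbind, strsplit(ug, "\r", fixed = TRUE))
  sheet <- data.frame(sample_id = paste(uk[, 1], uk[, 2], sep = "_"),
                      patient = uk[, 1], time_point = uk[, 2],
                      stringsAsFactors = FALSE)
  colnames(vals) <- sheet$sample_id
  design <- study_design(sheet, time_points = x$design$time_points,
                         platform = "taqman_single")
  mask <- mean_ct < params$detection_limit_ct
  colnames(mask) <- sheet$sample_id
  longitudinal_matrix(vals, design, scale = "linear", detection_mask = mask)
}

#' Coefficients of variation across all samples
#'
#' Per-feature CV (sample standard deviation over mean, computed across every
#' sample of the matrix on the linear scale, censored wells included at the
#' detection-floor signal) plus the unweighted mean CV over features. Features
#' with zero mean get `NA` and are excluded from the mean. A decreasing mean
#' CV is the quality signal that normalization removed systematic variation.
#'
#' @param x a `linear`-scale [longitudinal_matrix()].
#' @return List with `per_feature` (named numeric) and `mean_cv`.
#' @export
cv_stats <- function(x) {
  stopifnot(inherits(x, "long_matrix"))
  if (x$scale != "linear") stop("cv_stats expects a linear-scale matrix")
  m <- rowMeans(x$values)
  sd_ <- apply(x$values, 1L, stats::sd)
  cv <- ifelse(m > 0, sd_ / m, NA_real_)
  names(cv) <- rownames(x$values)
  list(per_feature = cv, mean_cv = mean(cv, na.rm = TRUE))
}
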