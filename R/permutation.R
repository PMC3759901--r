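# fast internal evaluation of the filtered-feature count for one relabelling.
# L: log2 floored values; det: detection mask; cols: per patient, column
# indices ordered baseline-first; ords: per patient, a permutation of the
# time-point positions (identity = observed labelling).
count_filtered_fast <- function(L, det, cols, ords, cutoff, min_patients,
                                n_bins, robust = FALSE) {
  n_tp <- length(cols[[1L]])
  n_feat <- nrow(L)
  up_any <- down_any <- logical(n_feat)
  for (ti in 2:n_tp) {
    up_votes <- down_votes <- integer(n_feat)
    for (pi in seq_along(cols)) {
      pc <- cols[[pi]][ords[[pi]]]
      ib <- pc[1L]; it <- pc[ti]
      M <- L[, it] - L[, ib]
      A <- (L[, it] + L[, ib]) / 2
      usable <- det[, it] | det[, ib]
      pair <- structure(list(M = M, A = A, usable = usable),
                        class = "ma_pair")
      curve <- fit_maid_curve(pair, n_bins = n_bins, robust = robust)
      s <- M / predict(curve, A)
      s[!usable] <- 0
      up_votes <- up_votes + (s > cutoff)
      down_votes <- down_votes + (s < -cutoff)
    }
    up_any <- up_any | (up_votes >= min_patients)
    down_any <- down_any | (down_votes >= min_patients)
  }
  sum(up_any) + sum(down_any)
}

# shared setup for the fast path
fast_path_inputs <- function(x, floor = NULL) {
  d <- x$design
  if (is.null(floor)) {
    pos <- x$values[x$values > 0]
    floor <- if (length(pos)) min(pos) else .Machine$double.eps
  }
  L <- log2(pmax(x$values, floor))
  ids <- colnames(x$values)
  cols <- lapply(d$patients, function(p) match(design_columns(d, p), ids))
  names(cols) <- d$patients
  list(L = L, det = x$detection_mask, cols = cols)
}

#' Permutation test for the number of filtered features
#'
#' Empirical significance of the MAID filtering result: the temporal sequence
#' of each patient's samples is rearranged uniformly at random (independently
#' per patient, identity allowed), and for every permuted data set the whole
#' filtering pipeline is re-run — MA transforms, spread-curve fits, MAID
#' scores, the k-of-n rule — and the size of the union set of up- and
#' down-regulated features over all post-baseline comparisons is recorded.
#' The empirical p-value is the fraction of permutations whose count reaches
#' the observed count.
#'
#' @param x a normalized `linear`-scale [longitudinal_matrix()].
#' @param cutoff,min_patients filter parameters (see [filter_features()]).
#' @param n_perm number of permutations (1000 in the original design).
#' @param seed integer seed; the whole null vector is reproducible from it.
#' @param plus_one if `TRUE`, use the add-one estimator
#'   `(1 + #{null >= obs}) / (1 + n_perm)` instead of the plain fraction.
#' @param n_bins,robust passed to [fit_maid_curve()].
#' @return An object of class `maid_permutation`: `observed_count`,
#'   `null_counts` (length `n_perm`), `mean_null`, `p_emp`, `n_perm`, `seed`.
#' @export
permutation_test <- function(x, cutoff, min_patients, n_perm = 1000L,
                             seed = 1L, plus_one = FALSE, n_bins = 20L,
                             robust = FALSE) {
  stopifnot(inherits(x, "long_matrix"))
  if (x$scale != "linear") stop("permutation_test expects a linear-scale matrix")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  fp <- fast_path_inputs(x)
  n_tp <- length(x$design$time_points)
  n_pat <- length(fp$cols)
  identity_ord <- replicate(n_pat, seq_len(n_tp), simplify = FALSE)
  observed <- count_filtered_fast(fp$L, fp$det, fp$cols, identity_ord,
                                  cutoff, min_patients, n_bins, robust)
  set.seed(as.integer(seed))
  null_counts <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    ords <- replicate(n_pat, sample.int(n_tp), simplify = FALSE)
    null_counts[i] <- count_filtered_fast(fp$L, fp$det, fp$cols, ords,
                                          cutoff, min_patients, n_bins, robust)
  }
  hits <- sum(null_counts >= observed)
  p_emp <- if (plus_one) (hits + 1) / (n_perm + 1) else hits / n_perm
  structure(list(observed_count = observed, null_counts = null_counts,
                 mean_null = mean(null_counts), p_emp = p_emp,
                 n_perm = n_perm, seed = as.integer(seed),
                 cutoff = cutoff, min_patients = min_patients),
            class = "maid_permutation")
}

#' @export
print.maid_permutation <- function(x, ...) {
  cat("Permutation test of the filtered-feature count\n")
  cat(sprintf("  observed: %d features (C = %g, k = %d)\n",
              x$observed_count, x$cutoff, x$min_patients))
  cat(sprintf("  null: mean %.2f over %d permutations (seed %d)\n",
              x$mean_null, x$n_perm, x$seed))
  cat(sprintf("  empirical p-value: %.4g\n", x$p_emp))
  invisible(x)
}

#' @export
plot.maid_permutation <- function(x, ...) {
  graphics::hist(x$null_counts, breaks = 30, col = "grey",
                 xlab = "filtered features under the null",
                 main = "Permutation null", ...)
  graphics::abline(v = x$observed_count, col = "red", lwd = 2)
  invisible(x)
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates every joint relabelling of the patients' time points (feasible
#' only for tiny designs: `factorial(T)^P` combinations) and returns the exact
#' distribution of the filtered-feature count together with the exact p-value.
#' Serves as the ground truth against which the Monte-Carlo
#' [permutation_test()] estimate is checked.
#'
#' @inheritParams permutation_test
#' @return List with `observed_count`, `counts` (one per relabelling),
#'   `p_exact`.
#' @export
exact_permutation_p <- function(x, cutoff, min_patients, n_bins = 20L) {
  stopifnot(inherits(x, "long_matrix"))
  d <- x$design
  n_tp <- length(d$time_points)
  n_pat <- length(d$patients)
  if (factorial(n_tp)^n_pat > 2e4)
    stop("design too large for exhaustive enumeration")
  perms_1 <- all_permutations(n_tp)
  idx <- expand.grid(rep(list(seq_len(nrow(perms_1))), n_pat))
  fit0 <- maid_fit(x, cutoff = cutoff, min_patients = min_patients,
                   n_bins = n_bins)
  observed <- length(fit0$filter$union_up) + length(fit0$filter$union_down)
  counts <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    perms <- lapply(seq_len(n_pat), function(pi) perms_1[idx[r, pi], ])
    names(perms) <- d$patients
    xr <- longitudinal_matrix(x$values, relabel_design(d, perms),
                              scale = x$scale,
                              detection_mask = x$detection_mask,
                              card = x$card)
    fit <- maid_fit(xr, cutoff = cutoff, min_patients = min_patients,
                    n_bins = n_bins)
    counts[r] <- length(fit$filter$union_up) + length(fit$filter$union_down)
  }
  list(observed_count = observed, counts = counts,
       p_exact = mean(counts >= observed))
}

# all permutations of 1..n as rows
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L), deparse.level = 0)
  }))
}
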