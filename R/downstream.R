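#' Paired t-test for one feature's before/after values
#'
#' Classical paired t-test (two-sided) on per-patient value pairs, as used to
#' assess one-month-versus-baseline expression differences in validation data.
#' When the differences have zero variance the statistic is undefined and both
#' `t_stat` and `p_value` are `NA`.
#'
#' @param before,after numeric vectors of equal length (>= 2), paired by
#'   patient.
#' @param feature optional feature id carried into the result.
#' @return A list of class `paired_comparison`: `feature`, `t_stat`, `df`,
#'   `p_value`, `mean_diff`, `direction` (`"up"` if after > before, `"down"`
#'   if lower, `"none"` for zero difference).
#' @export
paired_t_test <- function(before, after, feature = NA_character_) {
  stopifnot(length(before) == length(after), length(before) >= 2L)
  d <- after - before
  md <- mean(d)
  undef <- list(statistic = NA_real_, parameter = length(d) - 1L,
                p.value = NA_real_)
  res <- if (stats::sd(d) == 0) undef else tryCatch({
    ht <- stats::t.test(after, before, paired = TRUE)
    list(statistic = unname(ht$statistic), parameter = unname(ht$parameter),
         p.value = ht$p.value)
  }, error = function(e) undef)  # "data are essentially constant"
  structure(list(feature = feature, t_stat = res$statistic,
                 df = res$parameter, p_value = res$p.value, mean_diff = md,
                 direction = if (md > 0) "up" else if (md < 0) "down" else "none"),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired t-test%s: t = %.4g (df %d), p = %.4g, direction %s\n",
              if (is.na(x$feature)) "" else paste0(" [", x$feature, "]"),
              x$t_stat, x$df, x$p_value, x$direction))
  invisible(x)
}

#' Paired t-tests for every feature of two matched matrices
#'
#' Runs [paired_t_test()] row-wise on two matrices whose columns are the same
#' patients before and after treatment.
#'
#' @param before,after numeric matrices (features x patients) with identical
#'   dimnames.
#' @param alpha reporting threshold; features with `p_value < alpha` are
#'   flagged (a plain per-feature screen, no multiplicity correction).
#' @return data.frame with one row per feature: `feature`, `t_stat`,
#'   `p_value`, `mean_diff`, `direction`, `significant`.
#' @export
paired_t_table <- function(before, after, alpha = 0.10) {
  stopifnot(all(dim(before) == dim(after)))
  rows <- lapply(rownames(before), function(f) {
    r <- paired_t_test(before[f, ], after[f, ], feature = f)
    data.frame(feature = f, t_stat = r$t_stat, p_value = r$p_value,
               mean_diff = r$mean_diff, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), used to measure
#' cross-platform concordance of expression measurements. Constant input
#' yields `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\], or `NA` if either input is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Row z-scores and single-linkage Pearson clustering
#'
#' The heat-map layout computation: rows are centered and scaled to z-scores,
#' and rows and columns are ordered by single-linkage hierarchical clustering
#' with `1 - Pearson correlation` between profiles as the distance. Constant
#' rows (zero variance) cannot enter a correlation; they are flagged, given
#' z-score 0, excluded from the row distance computation and appended after
#' the ordered rows.
#'
#' @param x a [longitudinal_matrix()] or a plain numeric matrix (>= 2 rows and
#'   columns).
#' @return An object of class `cluster_layout`: `zscores`, `row_order`,
#'   `column_order` (permutations of row/column indices), `row_dendrogram`,
#'   `column_dendrogram` ([stats::hclust] trees), `constant_rows`.
#' @export
cluster_heatmap <- function(x) {
  vals <- if (inherits(x, "long_matrix")) x$values else as.matrix(x)
  stopifnot(nrow(vals) >= 2L, ncol(vals) >= 2L)
  rsd <- apply(vals, 1L, stats::sd)
  constant <- rsd == 0
  z <- vals
  z[!constant, ] <- t(scale(t(vals[!constant, , drop = FALSE])))
  z[constant, ] <- 0
  vv <- vals[!constant, , drop = FALSE]
  if (nrow(vv) < 2L) stop("need at least 2 non-constant rows")
  row_d <- stats::as.dist(1 - stats::cor(t(vv)))
  row_h <- stats::hclust(row_d, method = "single")
  row_order <- c(which(!constant)[row_h$order], which(constant))
  col_d <- stats::as.dist(1 - stats::cor(vv))
  col_h <- stats::hclust(col_d, method = "single")
  structure(list(zscores = z, row_order = row_order,
                 column_order = col_h$order, row_dendrogram = row_h,
                 column_dendrogram = col_h,
                 constant_rows = rownames(vals)[constant]),
            class = "cluster_layout")
}

#' @export
print.cluster_layout <- function(x, ...) {
  cat("Cluster layout:", nrow(x$zscores), "rows x", ncol(x$zscores),
      "columns (single linkage, 1 - Pearson r)\n")
  if (length(x$constant_rows))
    cat("  constant rows (appended last):",
        paste(x$constant_rows, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cluster_layout <- function(x, ...) {
  z <- x$zscores[x$row_order, x$column_order, drop = FALSE]
  graphics::image(t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  axes = FALSE, xlab = "samples", ylab = "features", ...)
  invisible(x)
}
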