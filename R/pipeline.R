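#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates an end-to-end run — simulate or ingest, preprocess, MAID
#' filter, permutation test, paired-t validation, target network — and returns
#' a machine-readable report sufficient to re-run the analysis identically.
#' Stages execute in that order; a failure aborts with the failing stage
#' named.
#'
#' The configuration is a named list (or a YAML file path, read with the yaml
#' package) with blocks:
#' \describe{
#'   \item{data}{either `simulate = list(...)` (arguments to [sim_config()])
#'     or `matrix`/`samples`/`scale` paths for [read_matrix()].}
#'   \item{preprocess}{`loess` (logical, default TRUE), `quantile_scale`
#'     (logical, default TRUE), `group_by`, plus [preprocess_params()]
#'     overrides.}
#'   \item{filter}{`cutoff` and `min_patients` (required), `n_bins`,
#'     `robust`.}
#'   \item{permutation}{`n_perm` (0 disables the stage) and `seed`.}
#'   \item{validate}{`time_point` to compare against baseline with per-feature
#'     paired t-tests over the filtered union set (default: last time point);
#'     `alpha` reporting threshold. Set `validate = FALSE` to skip.}
#'   \item{network}{`predicted`/`validated` interaction CSV paths and
#'     `min_algorithms`; omitted = stage skipped.}
#'   \item{output}{optional directory; filtered table, network files and the
#'     JSON report are written there.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return A list of class `run_report`: per-stage parameter echo and results
#'   (detection counts, CV before/after, filtered counts, permutation p-value,
#'   validation table, network statistics), `config`, `config_hash`,
#'   `version`. Written to `output/report.json` when an output directory is
#'   configured.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$filter$cutoff) || is.null(config$filter$min_patients))
    stop("config error: filter$cutoff and filter$min_patients are required")
  for (p in c(config$data$matrix, config$data$samples,
              config$network$predicted, config$network$validated))
    if (!is.null(p) && !file.exists(p))
      stop("config error: input path does not exist: ", p)

  report <- list(version = as.character(utils::packageVersion("maidflow")),
                 config = config, stages = list())
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- data -----------------------------------------------------------------
  truth <- NULL
  x <- run_stage("data", function() {
    if (!is.null(config$data$simulate)) {
      sim <- simulate_cohort(do.call(sim_config, config$data$simulate))
      truth <<- sim$truth
      sim$matrix
    } else {
      read_matrix(config$data$matrix, config$data$samples,
                  scale = config$data$scale %||% "linear")
    }
  })
  report$stages$data <- list(
    n_features = nrow(x$values), n_samples = ncol(x$values),
    scale = x$scale, detection_counts = as.list(detection_counts(x)))

  # --- preprocess -----------------------------------------------------------
  pp <- config$preprocess
  params <- do.call(preprocess_params,
                    pp[intersect(names(pp), names(formals(preprocess_params)))])
  x <- run_stage("preprocess", function() {
    if (x$scale == "ct") x <- ct_to_linear(x, params)
    cv_raw <- cv_stats(x)$mean_cv
    if (!identical(pp$loess, FALSE))
      x <- loess_normalize(x, params,
                           group_by = pp$group_by %||% "patient_and_card")
    cv_loess <- cv_stats(x)$mean_cv
    if (!identical(pp$quantile_scale, FALSE)) x <- quantile_scale(x, params)
    attr(x, "cv") <- c(raw_linear = cv_raw, post_loess = cv_loess,
                       post_scaling = cv_stats(x)$mean_cv)
    x
  })
  report$stages$preprocess <- list(params = unclass(params),
                                   mean_cv = as.list(attr(x, "cv")))

  # --- filter ---------------------------------------------------------------
  fit <- run_stage("filter", function()
    maid_fit(x, cutoff = config$filter$cutoff,
             min_patients = config$filter$min_patients,
             n_bins = config$filter$n_bins %||% 20L,
             robust = isTRUE(config$filter$robust)))
  counts <- summarize_counts(fit)
  report$stages$filter <- list(
    cutoff = fit$cutoff, min_patients = fit$min_patients, counts = counts,
    union_up = fit$filter$union_up, union_down = fit$filter$union_down)
  if (!is.null(truth))
    report$stages$filter$recovery <- recovery_stats(fit, truth)

  # --- permutation ----------------------------------------------------------
  n_perm <- config$permutation$n_perm %||% 0L
  if (n_perm > 0L) {
    pt <- run_stage("permutation", function()
      permutation_test(x, cutoff = config$filter$cutoff,
                       min_patients = config$filter$min_patients,
                       n_perm = n_perm,
                       seed = config$permutation$seed %||%
                         stop("config error: permutation$seed is required"),
                       n_bins = config$filter$n_bins %||% 20L))
    report$stages$permutation <- list(
      n_perm = pt$n_perm, seed = pt$seed, observed_count = pt$observed_count,
      mean_null = pt$mean_null, p_emp = pt$p_emp,
      null_counts = pt$null_counts)
  }

  # --- validate -------------------------------------------------------------
  if (!identical(config$validate, FALSE)) {
    feats <- union(fit$filter$union_up, fit$filter$union_down)
    if (length(feats) > 0L) {
      vt <- run_stage("validate", function() {
        tp <- config$validate$time_point %||% utils::tail(x$design$time_points, 1L)
        before <- after <- matrix(NA_real_, length(feats),
                                  length(x$design$patients),
                                  dimnames = list(feats, x$design$patients))
        for (p in x$design$patients) {
          cols <- design_columns(x$design, p)
          names(cols) <- x$design$time_points
          before[, p] <- x$values[feats, cols[x$design$baseline]]
          after[, p] <- x$values[feats, cols[tp]]
        }
        paired_t_table(before, after, alpha = config$validate$alpha %||% 0.10)
      })
      report$stages$validate <- vt
    }
  }

  # --- network --------------------------------------------------------------
  if (!is.null(config$network)) {
    net <- run_stage("network", function() {
      it <- read_interactions(config$network$predicted,
                              config$network$validated)
      genes <- config$network$genes %||% fit  # second filter result optional
      build_network(fit, genes, it,
                    min_algorithms = config$network$min_algorithms %||% 5L)
    })
    report$stages$network <- network_stats(net)
    report$stages$network$degrees <- NULL
  } else {
    net <- NULL
  }

  report$config_hash <- config_hash(config)

  out_dir <- config$output
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(counts, file.path(out_dir, "filtered_counts.csv"),
                     row.names = FALSE)
    if (!is.null(net)) {
      write_sif(net, file.path(out_dir, "network.sif"))
      write_graphml(net, file.path(out_dir, "network.graphml"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
  }
  class(report) <- "run_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable content hash of the configuration (md5 of its serialized JSON)
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' @export
print.run_report <- function(x, ...) {
  cat("maidflow run report (version ", x$version, ", config ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat("stages run:", paste(names(x$stages), collapse = ", "), "\n")
  if (!is.null(x$stages$filter)) {
    cat("\nFiltered feature counts:\n")
    print(x$stages$filter$counts)
  }
  if (!is.null(x$stages$permutation))
    cat(sprintf("\nPermutation test: observed %d, null mean %.2f, p = %.4g\n",
                x$stages$permutation$observed_count,
                x$stages$permutation$mean_null, x$stages$permutation$p_emp))
  invisible(x)
}
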