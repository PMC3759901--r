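#' Configuration of the synthetic longitudinal cohort generator
#'
#' Describes the statistical structure the analysis assumes: a small cohort
#' measured at a baseline and several on-treatment time points, log-normal
#' feature abundances, Gaussian log-scale measurement noise whose standard
#' deviation decays exponentially with abundance (the premise of the MAID
#' curve), per-patient-and-card multiplicative scale biases, detection
#' censoring, and planted up-/down-regulated features.
#'
#' @param n_patients number of patients (default 6).
#' @param time_points chronological labels, baseline first (default
#'   `baseline, t48h, t96h, m1`).
#' @param n_features number of assayed features (default 651, a two-card
#'   miRNA panel; use ~19204 for an mRNA-chip-sized matrix).
#' @param n_up,n_down numbers of planted up-/down-regulated features
#'   (default 0: a null cohort).
#' @param effect_log2 planted effect size. With `effect_mode = "absolute"` it
#'   is the log2 fold change itself; with `"spread_multiple"` (default) it
#'   multiplies the expected spread of the log2 fold change at the feature's
#'   abundance, `sqrt(2) * s(mu_f)`, so that e.g. `effect_log2 = 3` plants
#'   effects three times the MAID curve's height.
#' @param effect_mode `"spread_multiple"` or `"absolute"`.
#' @param effect_ramp per-post-baseline-time-point multiplier of the effect
#'   (recycled). The default `c(0.5, 0.5, 1)` mimics a dose titration in which
#'   the first on-treatment weeks use a reduced dose; use `1` for a constant
#'   full-size effect.
#' @param patient_effect_sd between-patient SD of the planted effect on the
#'   log2 scale (default 0: identical effect in every patient).
#' @param spread_params `c(a, b, c)` of the true noise curve
#'   `s(A) = a * exp(-b * A) + c` giving the per-sample log2 noise SD at log2
#'   abundance A. Default `c(0.35, 0.2, 0.25)`: SD ~0.6 for weakly expressed
#'   features (A ~ 0) decaying to ~0.25 at high abundance.
#' @param baseline_mean_log2,baseline_sd_log2 normal distribution of the true
#'   log2 abundances (defaults 4 and 4, spanning the detectable Ct range).
#' @param patient_bias_sd SD of the per-(patient, card) log2 scale bias
#'   (default 0.25); emulates card-level measurement offsets.
#' @param frac_undetected expected fraction of features absent from the
#'   tissue, reported as undetermined wells (default 0.38, matching ~400 of
#'   651 panel miRNAs detected per sample).
#' @param detection_limit_ct,undetermined_ct,linear_scale_factor Ct
#'   conventions of the emulated platform (see [preprocess_params()]).
#' @param platform `"taqman"` (Ct output with censoring) or `"intensity"`
#'   (linear-scale output, no censoring).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 6L,
                       time_points = c("baseline", "t48h", "t96h", "m1"),
                       n_features = 651L, n_up = 0L, n_down = 0L,
                       effect_log2 = 3,
                       effect_mode = c("spread_multiple", "absolute"),
                       effect_ramp = c(0.5, 0.5, 1),
                       patient_effect_sd = 0,
                       spread_params = c(a = 0.35, b = 0.2, c = 0.25),
                       baseline_mean_log2 = 4, baseline_sd_log2 = 4,
                       patient_bias_sd = 0.25, frac_undetected = 0.38,
                       detection_limit_ct = 38, undetermined_ct = 45,
                       linear_scale_factor = 1e9,
                       platform = c("taqman", "intensity"), seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  platform <- match.arg(platform)
  stopifnot(n_up + n_down <= n_features, length(time_points) >= 2L,
            is.finite(effect_log2), all(spread_params[1:2] >= 0),
            spread_params[3] > 0, frac_undetected >= 0, frac_undetected < 1,
            patient_bias_sd >= 0, patient_effect_sd >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 time_points = time_points,
                 n_features = as.integer(n_features),
                 n_up = as.integer(n_up), n_down = as.integer(n_down),
                 effect_log2 = effect_log2, effect_mode = effect_mode,
                 effect_ramp = effect_ramp,
                 patient_effect_sd = patient_effect_sd,
                 spread_params = unname(spread_params),
                 baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 patient_bias_sd = patient_bias_sd,
                 frac_undetected = frac_undetected,
                 detection_limit_ct = detection_limit_ct,
                 undetermined_ct = undetermined_ct,
                 linear_scale_factor = linear_scale_factor,
                 platform = platform, seed = as.integer(seed)),
            class = "sim_config")
}

# true noise SD at log2 abundance A
spread_at <- function(config, A) {
  p <- config$spread_params
  p[1L] * exp(-p[2L] * A) + p[3L]
}

#' Simulate a longitudinal cohort with planted differential expression
#'
#' Generates one feature-by-sample matrix under the generative model of
#' [sim_config()]: true log2 abundance `mu_f ~ N(baseline_mean, baseline_sd)`
#' for expressed features; per-sample log2 value `mu_f + bias(patient, card) +
#' effect(f, time point) + eps` with `eps ~ N(0, s(mu_f))`; a `frac_undetected`
#' share of features is absent from the tissue and reads as undetermined
#' wells. The first `n_up` expressed features are planted up-regulated at all
#' post-baseline time points and the next `n_down` down-regulated, with the
#' per-feature log2 effect determined by `effect_log2`, `effect_mode` and
#' `effect_ramp`. For the TaqMan platform, values are converted to Ct via
#' `Ct = -log2(S / linear_scale_factor)` and wells beyond the detection limit
#' are reported at the undetermined sentinel (Ct 45). Features are assigned
#' alternately to cards A and B.
#'
#' @param config a [sim_config()].
#' @return List with `matrix` (a [longitudinal_matrix()], scale `"ct"` or
#'   `"linear"` depending on the platform) and `truth` (class `sim_truth`:
#'   `planted_up`, `planted_down`, `true_effects` feature x comparison matrix
#'   of log2 effects, `mu`, `bias`, `expressed`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_features
  tp <- config$time_points
  n_tp <- length(tp)
  n_comp <- n_tp - 1L
  patients <- sprintf("Pat%d", seq_len(config$n_patients))
  feats <- sprintf("feat%04d", seq_len(nf))
  card <- rep(c("A", "B"), length.out = nf)

  expressed <- stats::runif(nf) > config$frac_undetected
  mu <- ifelse(expressed,
               stats::rnorm(nf, config$baseline_mean_log2,
                            config$baseline_sd_log2),
               NA_real_)

  # planted features are drawn from the expressed pool
  idx_expr <- which(expressed)
  n_plant <- config$n_up + config$n_down
  if (n_plant > length(idx_expr))
    stop("not enough expressed features to plant effects in")
  planted_up <- idx_expr[seq_len(config$n_up)]
  planted_down <- idx_expr[config$n_up + seq_len(config$n_down)]

  ramp <- rep_len(config$effect_ramp, n_comp)
  base_eff <- numeric(nf)
  scale_eff <- if (config$effect_mode == "spread_multiple")
    sqrt(2) * spread_at(config, mu) else rep(1, nf)
  base_eff[planted_up] <- config$effect_log2 * scale_eff[planted_up]
  base_eff[planted_down] <- -config$effect_log2 * scale_eff[planted_down]
  true_effects <- outer(base_eff, ramp)
  dimnames(true_effects) <- list(feats, tp[-1L])

  sheet <- expand.grid(time_point = tp, patient = patients,
                       stringsAsFactors = FALSE)[, c(2, 1)]
  sheet$sample_id <- paste(sheet$patient, sheet$time_point, sep = "_")
  bias <- matrix(stats::rnorm(config$n_patients * 2L, 0,
                              config$patient_bias_sd),
                 config$n_patients, 2L,
                 dimnames = list(patients, c("A", "B")))

  vals <- matrix(NA_real_, nf, nrow(sheet),
                 dimnames = list(feats, sheet$sample_id))
  noise_sd <- ifelse(expressed, spread_at(config, mu), 0)
  for (si in seq_len(nrow(sheet))) {
    p <- sheet$patient[si]
    ti <- match(sheet$time_point[si], tp)
    eff <- if (ti == 1L) 0 else true_effects[, ti - 1L]
    lv <- mu + bias[p, card] + eff + stats::rnorm(nf, 0, noise_sd)
    vals[, si] <- ifelse(expressed, lv, -Inf)
  }

  truth <- structure(list(planted_up = feats[planted_up],
                          planted_down = feats[planted_down],
                          true_effects = true_effects, mu = mu, bias = bias,
                          expressed = expressed),
                     class = "sim_truth")

  if (config$platform == "taqman") {
    ct <- log2(config$linear_scale_factor) - vals  # Ct = -log2(S / factor)
    ct[!is.finite(ct) | ct > config$detection_limit_ct] <- config$undetermined_ct
    design <- study_design(sheet, time_points = tp, platform = "taqman_card")
    mat <- longitudinal_matrix(ct, design, scale = "ct",
                               detection_limit = config$detection_limit_ct,
                               card = card)
  } else {
    lin <- 2^vals
    lin[!is.finite(vals)] <- 0
    design <- study_design(sheet, time_points = tp, platform = "affy_mrna")
    mat <- longitudinal_matrix(lin, design, scale = "linear", card = card)
  }
  list(matrix = mat, truth = truth)
}

#' Simulate a pure-null cohort
#'
#' Convenience wrapper: the same generative model with no planted effects, so
#' time points are exchangeable within each patient. Used to calibrate the
#' permutation test and to measure the filter's chance level.
#'
#' @param config a [sim_config()]; its `n_up`/`n_down` are forced to 0.
#' @return The `matrix` element of [simulate_cohort()].
#' @export
simulate_null <- function(config) {
  config$n_up <- 0L
  config$n_down <- 0L
  simulate_cohort(config)$matrix
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth:", length(x$planted_up), "up,",
      length(x$planted_down), "down planted among",
      sum(x$expressed), "expressed features\n")
  invisible(x)
}

#' Sensitivity and false-discovery proportion against planted truth
#'
#' Compares a filtering result with the planted feature sets of a simulated
#' cohort. A planted feature counts as recovered when it appears in the union
#' set with the planted direction; any reported feature that was not planted
#' in that direction counts as a false discovery.
#'
#' @param result a [filter_features()] result or [maid_fit()].
#' @param truth the `truth` element of [simulate_cohort()].
#' @return List with `sensitivity`, `fdp`, `n_true_positive`, `n_reported`.
#' @export
recovery_stats <- function(result, truth) {
  if (inherits(result, "maid_fit")) result <- result$filter
  stopifnot(inherits(result, "maid_filter"), inherits(truth, "sim_truth"))
  tp_up <- intersect(result$union_up, truth$planted_up)
  tp_down <- intersect(result$union_down, truth$planted_down)
  n_tp <- length(tp_up) + length(tp_down)
  n_rep <- length(result$union_up) + length(result$union_down)
  n_planted <- length(truth$planted_up) + length(truth$planted_down)
  list(sensitivity = if (n_planted > 0) n_tp / n_planted else NA_real_,
       fdp = if (n_rep > 0) (n_rep - n_tp) / n_rep else 0,
       n_true_positive = n_tp, n_reported = n_rep)
}
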