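test_that("Ct-to-linear conversion reproduces the published anchor points", {
  expect_equal(signif(ct_signal(38), 1), 0.004)   # detection-floor signal
  expect_equal(floor(ct_signal(20)), 953)
  expect_equal(ct_signal(20), 2^-20 * 1e9)
})

test_that("Ct-to-linear is strictly decreasing and one cycle doubles", {
  ct <- seq(5, 37.5, by = 0.5)
  s <- ct_signal(ct)
  expect_true(all(diff(s) < 0))
  expect_equal(ct_signal(ct - 1), 2 * ct_signal(ct))
  expect_equal(ct_signal(19), 2 * ct_signal(20))
  expect_error(ct_signal(-1), "negative Ct")
})

test_that("values beyond the detection limit are censored to the floor", {
  d <- make_design(1, c("baseline", "m1"))
  ct <- matrix(c(20, 39, 45, 38), 2, dimnames = list(c("hi", "lo"), NULL))
  x <- make_matrix(ct, d, scale = "ct")
  lin <- ct_to_linear(x)
  floor_sig <- ct_signal(38)
  # Ct 39 and the undetermined sentinel 45 both land exactly on the floor
  expect_equal(unname(lin$values["lo", ]), c(floor_sig, floor_sig))
  expect_equal(unname(lin$detection_mask["lo", ]), c(FALSE, FALSE))
  expect_equal(lin$values["hi", 1], ct_signal(20))
  expect_true(lin$detection_mask["hi", 1])
  # exactly at the limit: floored but per the "raw Ct < 38" rule not detected
  expect_false(lin$detection_mask["hi", 2])
})

test_that("loess normalization leaves identical samples fixed", {
  d <- make_design(1)
  set.seed(1)
  v <- matrix(rep(2^rnorm(200, 6, 2), 4), ncol = 4)
  x <- make_matrix(v, d)
  out <- loess_normalize(x)
  expect_equal(out$values, x$values, tolerance = 1e-10)
})

test_that("loess normalization removes a constant log-scale offset", {
  d <- make_design(1, c("baseline", "m1"))
  set.seed(2)
  base <- 2^rnorm(300, 6, 2)
  v <- cbind(base, 2 * base)          # sample 2 = 2 x sample 1
  x <- make_matrix(v, d)
  out <- loess_normalize(x)
  M <- log2(out$values[, 2]) - log2(out$values[, 1])
  expect_lt(abs(median(M)), 1e-6)
})

test_that("loess normalization shrinks an intensity-dependent bow", {
  d <- make_design(1)
  set.seed(3)
  mu <- rnorm(384, 6, 2.5)
  lv <- sapply(1:4, function(i) mu + rnorm(384, 0, 0.1))
  lv[, 2] <- lv[, 2] + 0.5 * sin(mu / 2)     # bowed sample
  x <- make_matrix(2^lv, d)
  out <- loess_normalize(x)
  bow <- function(vals) {
    M <- log2(vals[, 2]) - log2(vals[, 1])
    A <- (log2(vals[, 2]) + log2(vals[, 1])) / 2
    dec <- cut(A, quantile(A, 0:10 / 10), include.lowest = TRUE)
    abs(tapply(M, dec, median))
  }
  expect_true(all(bow(out$values) < bow(x$values)))
})

test_that("pairwise loess agrees with the limma dialect on clean data", {
  skip_if_not_installed("limma")
  set.seed(7)
  mu <- rnorm(400, 6, 3)
  lv <- cbind(mu + rnorm(400, 0, 0.3),
              mu + 0.4 * sin(mu / 2) + rnorm(400, 0, 0.3))
  mine <- maidflow:::cyclic_loess_group(lv, matrix(TRUE, 400, 2), 0.7)
  lim <- limma::normalizeCyclicLoess(lv, span = 0.7, iterations = 1,
                                     method = "pairs")
  expect_lt(max(abs(mine - lim)), 0.15)  # same trend, different smoother internals
})

test_that("undetected wells stay on the floor and detection counts are invariant", {
  sim <- simulate_cohort(sim_config(n_features = 300, seed = 4))
  lin <- ct_to_linear(sim$matrix)
  counts0 <- detection_counts(lin)
  norm <- loess_normalize(lin)
  expect_identical(detection_counts(norm), counts0)
  expect_true(all(norm$values[!norm$detection_mask] == ct_signal(38)))
  scaled <- quantile_scale(norm)
  expect_identical(detection_counts(scaled), counts0)
})

test_that("quantile scaling equalizes pooled per-patient quantiles", {
  d <- make_design(2, c("baseline", "m1"))
  # patient 1 pools at 100, patient 2 at 400 -> geometric-mean target 200
  v <- cbind(rep(100, 20), rep(100, 20), rep(400, 20), rep(400, 20))
  x <- make_matrix(v, d)
  out <- quantile_scale(x)
  f <- attr(out, "scale_factors")
  expect_equal(unname(f), c(2, 0.5))
  expect_equal(unname(out$values), matrix(200, 20, 4))
})

test_that("quantile scaling is idempotent and preserves within-patient ratios", {
  sim <- simulate_cohort(sim_config(n_features = 400, patient_bias_sd = 0.6,
                                    seed = 5))
  x <- ct_to_linear(sim$matrix)
  s1 <- quantile_scale(x)
  # per-patient pooled 95% quantiles equal after one pass, within each card
  for (cd in unique(s1$card)) {
    q <- sapply(s1$design$patients, function(p) {
      ids <- s1$design$samples$sample_id[s1$design$samples$patient == p]
      quantile(s1$values[s1$card == cd, ids], 0.95, names = FALSE)
    })
    expect_lt(diff(range(q)), 1e-9)
  }
  s2 <- quantile_scale(s1)
  expect_equal(s2$values, s1$values, tolerance = 1e-9)
  # within-patient structure untouched
  ids <- x$design$samples$sample_id[x$design$samples$patient == "Pat1"]
  expect_equal(s1$values[, ids[2]] / s1$values[, ids[1]],
               x$values[, ids[2]] / x$values[, ids[1]])
})

test_that("single-patient quantile scaling is the identity", {
  d <- make_design(1, c("baseline", "m1"))
  set.seed(6)
  x <- make_matrix(matrix(2^rnorm(100, 6, 2), ncol = 2), d)
  out <- quantile_scale(x)
  expect_equal(out$values, x$values)
  expect_equal(unname(attr(out, "scale_factors")), 1)
})

test_that("relative quantification normalizes to the housekeeping miRNA", {
  tps <- c("baseline", "m1")
  sheet <- do.call(rbind, lapply(1:3, function(r) {
    s <- make_sheet(1, tps)
    s$replicate <- r
    s$sample_id <- paste0(s$sample_id, "_r", r)
    s
  }))
  d <- study_design(sheet, time_points = tps, platform = "taqman_single")
  ct <- rbind(
    `hsa-miR-191-5p` = rep(25, 6),
    same_as_hk      = rep(25, 6),
    one_cycle_up    = rep(26, 6),
    triplicate_mean = rep(c(30.0, 30.5, 31.0), 2))
  colnames(ct) <- d$samples$sample_id
  # design order is patient/time sorted; rebuild values in that order
  x <- longitudinal_matrix(ct[, d$samples$sample_id], d, scale = "ct")
  out <- relative_quantify(x)
  expect_equal(dim(out), c(4L, 2L))
  expect_equal(unname(out$values["hsa-miR-191-5p", ]), c(1000, 1000))
  expect_equal(unname(out$values["same_as_hk", ]), c(1000, 1000))
  expect_equal(unname(out$values["one_cycle_up", ]), c(500, 500))
  # mean Ct of the triplicate (30, 30.5, 31) is 30.5
  expect_equal(unname(out$values["triplicate_mean", 1]),
               1000 * 2^-30.5 / 2^-25)
  expect_error(relative_quantify(x, preprocess_params(hk_feature = "absent")),
               "housekeeping")
})

test_that("coefficients of variation follow the textbook definition", {
  d <- make_design(1)
  v <- rbind(constant = c(5, 5, 5, 5),
             simple   = c(1, 2, 3, 2),
             zero     = c(0, 0, 0, 0))
  x <- make_matrix(v, d)
  cv <- cv_stats(x)
  expect_equal(unname(cv$per_feature["constant"]), 0)
  expect_equal(unname(cv$per_feature["simple"]), sd(c(1, 2, 3, 2)) / 2)
  expect_true(is.na(cv$per_feature["zero"]))
  expect_equal(cv$mean_cv,
               mean(cv$per_feature[c("constant", "simple")]))

  # three-value textbook case: sd 1, mean 2 -> CV 0.5
  d2 <- make_design(1, c("baseline", "t48h", "m1"))
  x2 <- make_matrix(matrix(c(1, 2, 3), 1), d2)
  expect_equal(unname(cv_stats(x2)$per_feature), 0.5)
})

test_that("loess normalization reduces the mean CV under sample-level biases", {
  d <- make_design(1)
  set.seed(8)
  mu <- rnorm(384, 6, 2)
  bias <- c(0, 0.6, -0.5, 0.3)                     # multiplicative sample biases
  lv <- sapply(1:4, function(i) mu + bias[i] + rnorm(384, 0, 0.15))
  x <- make_matrix(2^lv, d)
  out <- loess_normalize(x)
  expect_lt(cv_stats(out)$mean_cv, cv_stats(x)$mean_cv)
})
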