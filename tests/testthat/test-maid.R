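test_that("MA transform computes log ratios and mean intensities", {
  d <- make_design(1, c("baseline", "m1"))
  v <- rbind(up = c(100, 400), flat = c(50, 50), both_censored = c(0.004, 0.004))
  mask <- rbind(c(TRUE, TRUE), c(TRUE, TRUE), c(FALSE, FALSE))
  x <- make_matrix(v, d, detection_mask = mask)
  pair <- ma_transform(x, "Pat1", "m1", floor = 0.004)
  expect_equal(unname(pair$M["up"]), 2)
  expect_equal(unname(pair$A["up"]), (log2(400) + log2(100)) / 2)  # 7.6439
  expect_equal(unname(pair$A["up"]), 7.643856, tolerance = 1e-6)
  expect_equal(unname(pair$M["flat"]), 0)
  expect_false(pair$usable["both_censored"])
  expect_equal(unname(pair$M["both_censored"]), 0)
  expect_true(all(pair$usable[c("up", "flat")]))
  expect_error(ma_transform(x, "PatX", "m1"), "unknown patient")
  expect_error(ma_transform(x, "Pat1", "baseline"), "post-baseline")
})

test_that("curve fit recovers a flat spread on homoscedastic data", {
  sigma <- 0.8
  pair <- make_pair(5000, function(A) sigma, seed = 11)
  curve <- fit_maid_curve(pair)
  aa <- seq(min(pair$A), max(pair$A), length.out = 100)
  expect_lt(max(abs(predict(curve, aa) - sigma)), 0.1 * sigma)
})

test_that("curve fit recovers a planted exponential spread curve", {
  s_true <- function(A) 2 * exp(-0.5 * A) + 0.1
  pair <- make_pair(5000, s_true, seed = 42)
  curve <- fit_maid_curve(pair)
  expect_identical(curve$type, "exponential")
  aa <- seq(quantile(pair$A, 0.1), quantile(pair$A, 0.9), length.out = 100)
  rel <- abs(predict(curve, aa) - s_true(aa)) / s_true(aa)
  expect_lt(max(rel), 0.15)
})

test_that("curve fit degrades gracefully on tiny inputs", {
  pair <- make_pair(10, function(A) 0.5, seed = 3)
  curve <- fit_maid_curve(pair)              # 10 usable -> 3 bins, no crash
  expect_equal(curve$diagnostics$n_bins, 3L)
  expect_true(all(predict(curve, c(0, 5, 10)) > 0))
  small <- make_pair(5, function(A) 0.5, seed = 3)
  expect_error(fit_maid_curve(small), "too few")
})

test_that("fitted curves are positive and non-increasing", {
  for (seed in 1:5) {
    pair <- make_pair(800, function(A) 1.5 * exp(-0.4 * A) + 0.2, seed = seed)
    curve <- fit_maid_curve(pair)
    aa <- seq(min(pair$A), max(pair$A), length.out = 200)
    f <- predict(curve, aa)
    expect_true(all(f > 0))
    expect_true(all(diff(f) <= 1e-12))
  }
})

test_that("MAID scores divide fold changes by the local spread", {
  pair <- structure(list(M = c(0, 1, -1), A = c(5, 5, 5),
                         usable = c(TRUE, TRUE, FALSE)),
                    class = "ma_pair")
  curve <- structure(list(a = 0, b = 0, c = 0.5, type = "exponential",
                          diagnostics = list()), class = "maid_curve")
  expect_equal(maid_score(pair, curve), c(0, 2, 0))  # unusable scores 0
})

test_that("swapping treated and baseline negates every score", {
  tps <- c("baseline", "m1")
  d <- make_design(1, tps)
  set.seed(12)
  mu <- rnorm(400, 6, 2)
  v <- 2^cbind(mu + rnorm(400, 0, 0.4), mu + rnorm(400, 0, 0.4))
  x <- make_matrix(v, d)
  pair <- ma_transform(x, "Pat1", "m1")
  swapped <- longitudinal_matrix(x$values,
                                 relabel_design(d, list(Pat1 = c(2L, 1L))),
                                 scale = "linear",
                                 detection_mask = x$detection_mask)
  pair_sw <- ma_transform(swapped, "Pat1", "m1")
  curve <- fit_maid_curve(pair)
  curve_sw <- fit_maid_curve(pair_sw)
  expect_equal(coef(curve), coef(curve_sw))  # spread is sign-invariant
  expect_equal(maid_score(pair_sw, curve_sw), -maid_score(pair, curve))
})

test_that("the k-of-n filter applies the published rule", {
  # one feature, 6 patients, 1 comparison, hand-written score table
  sc <- array(0, c(1, 6, 1), dimnames = list("f1", paste0("P", 1:6), "m1"))
  sc["f1", 1:4, 1] <- 2.5
  r <- filter_features(sc, cutoff = 2, min_patients = 4)
  expect_identical(r$per_comparison$m1$up, "f1")
  expect_identical(r$union_up, "f1")
  expect_length(r$union_down, 0)

  sc["f1", 4, 1] <- 0                       # only 3 of 6 patients pass
  r2 <- filter_features(sc, cutoff = 2, min_patients = 4)
  expect_length(r2$union_up, 0)

  r3 <- filter_features(array(0, c(3, 6, 2),
                              dimnames = list(letters[1:3], paste0("P", 1:6),
                                              c("t48h", "m1"))),
                        cutoff = 1, min_patients = 4)
  expect_length(r3$union_up, 0)
  expect_length(r3$union_down, 0)
  expect_error(filter_features(sc, cutoff = 2, min_patients = 7),
               "cannot exceed")
})

test_that("filter agrees with an exhaustive brute-force enumeration", {
  set.seed(21)
  sc <- array(rnorm(20 * 6 * 3, 0, 1.2), c(20, 6, 3),
              dimnames = list(sprintf("f%02d", 1:20), paste0("P", 1:6),
                              c("t48h", "t96h", "m1")))
  C <- 1; k <- 4
  r <- filter_features(sc, C, k)
  # independent oracle: loop over every (feature, comparison, direction)
  up <- down <- character()
  for (f in dimnames(sc)[[1]]) {
    for (cmp in dimnames(sc)[[3]]) {
      n_up <- n_down <- 0
      for (p in dimnames(sc)[[2]]) {
        if (sc[f, p, cmp] > C) n_up <- n_up + 1
        if (sc[f, p, cmp] < -C) n_down <- n_down + 1
      }
      if (n_up >= k) up <- c(up, f)
      if (n_down >= k) down <- c(down, f)
      expect_identical(f %in% r$per_comparison[[cmp]]$up, n_up >= k)
      expect_identical(f %in% r$per_comparison[[cmp]]$down, n_down >= k)
    }
  }
  expect_identical(r$union_up, sort(unique(up)))
  expect_identical(r$union_down, sort(unique(down)))
})

test_that("raising the cutoff or the patient threshold never adds features", {
  set.seed(22)
  sc <- array(rnorm(100 * 6 * 3, 0, 1.5), c(100, 6, 3),
              dimnames = list(sprintf("f%03d", 1:100), paste0("P", 1:6),
                              c("t48h", "t96h", "m1")))
  sizes <- function(r) length(r$union_up) + length(r$union_down)
  for (k in c(2, 4)) {
    prev <- Inf
    for (C in c(0.5, 1, 1.5, 2, 3)) {
      r <- filter_features(sc, C, k)
      expect_lte(sizes(r), prev)
      prev <- sizes(r)
    }
  }
  for (C in c(0.5, 1.5)) {
    prev <- Inf
    for (k in 1:6) {
      r <- filter_features(sc, C, k)
      expect_lte(sizes(r), prev)
      prev <- sizes(r)
    }
  }
})

test_that("count summaries are consistent with the sets", {
  sc <- array(0, c(3, 6, 2), dimnames = list(c("a", "b", "c"),
                                             paste0("P", 1:6),
                                             c("t48h", "m1")))
  sc["a", , "t48h"] <- 3; sc["b", , "t48h"] <- 3
  sc["b", , "m1"] <- 3; sc["c", , "m1"] <- -3
  r <- filter_features(sc, 1, 4)
  tab <- summarize_counts(r)
  expect_identical(tab$comparison, c("t48h", "m1", "Total"))
  expect_equal(tab$up, c(2, 1, 2))       # union up = {a, b}
  expect_equal(tab$down, c(0, 1, 1))
  expect_equal(tab$total, tab$up + tab$down)

  empty <- filter_features(array(0, c(3, 6, 2), dimnames = dimnames(sc)), 1, 4)
  expect_true(all(summarize_counts(empty)[, c("up", "down", "total")] == 0))
})

test_that("a feature regulated both ways across comparisons is flagged", {
  sc <- array(0, c(1, 6, 2), dimnames = list("f1", paste0("P", 1:6),
                                             c("t48h", "m1")))
  sc["f1", , "t48h"] <- 2; sc["f1", , "m1"] <- -2
  r <- filter_features(sc, 1, 4)
  expect_identical(r$union_up, "f1")
  expect_identical(r$union_down, "f1")
  expect_identical(r$conflicts, "f1")
})

test_that("maid_fit recovers planted features end to end", {
  sim <- simulate_cohort(sim_config(n_features = 300, n_up = 20, n_down = 10,
                                    effect_log2 = 3, effect_ramp = 1,
                                    seed = 77))
  fit <- maid_fit(ct_to_linear(sim$matrix), cutoff = 1, min_patients = 4)
  rec <- recovery_stats(fit, sim$truth)
  expect_gte(rec$sensitivity, 0.9)
  expect_lte(rec$fdp, 0.1)
  # model-object interface
  expect_s3_class(fit, "maid_fit")
  expect_equal(dim(coef(fit)), c(18L, 3L))      # 6 patients x 3 comparisons
  s <- summary(fit)
  expect_identical(s$counts, summarize_counts(fit$filter))
  expect_output(print(fit), "MAID fit")
})
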