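# shared fixture builders; everything is generated in code at test time

# minimal sample sheet for n patients x given time points
make_sheet <- function(n_patients = 2, time_points = c("baseline", "t48h", "t96h", "m1")) {
  g <- expand.grid(patient = sprintf("Pat%d", seq_len(n_patients)),
                   time_point = time_points, stringsAsFactors = FALSE)
  g$sample_id <- paste(g$patient, g$time_point, sep = "_")
  g[, c("sample_id", "patient", "time_point")]
}

make_design <- function(n_patients = 2, time_points = c("baseline", "t48h", "t96h", "m1"),
                        platform = "taqman_card") {
  study_design(make_sheet(n_patients, time_points), time_points = time_points,
               platform = platform)
}

# long_matrix with given values (features x samples in design order)
make_matrix <- function(values, design, scale = "linear", ...) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  colnames(values) <- design$samples$sample_id
  longitudinal_matrix(values, design, scale = scale, ...)
}

# write a matrix fixture + sheet to temp files; returns the two paths
write_fixture <- function(values, sheet, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mpath <- file.path(dir, "matrix.tsv")
  spath <- file.path(dir, "samples.csv")
  df <- data.frame(feature = rownames(values), values, check.names = FALSE)
  utils::write.table(df, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(sheet, spath, row.names = FALSE, quote = FALSE)
  c(matrix = mpath, sheet = spath)
}

# hand-built filter result (for network tests)
mini_filter <- function(up = character(), down = character()) {
  n <- max(1L, length(up) + length(down))
  sc <- array(0, c(n, 6, 1),
              dimnames = list(sprintf("pad%02d", seq_len(n)),
                              paste0("P", 1:6), "m1"))
  r <- filter_features(sc, 1, 4)
  r$union_up <- sort(up); r$union_down <- sort(down)
  r$conflicts <- intersect(r$union_up, r$union_down)
  r$per_comparison$m1 <- list(up = r$union_up, down = r$union_down)
  r
}

# synthetic MA pair with prescribed spread curve s(A); for curve-fit tests
make_pair <- function(n, s_fun, a_range = c(0, 12), seed = 1) {
  set.seed(seed)
  A <- stats::runif(n, a_range[1], a_range[2])
  M <- stats::rnorm(n, 0, s_fun(A))
  structure(list(M = M, A = A, usable = rep(TRUE, n)), class = "ma_pair")
}
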