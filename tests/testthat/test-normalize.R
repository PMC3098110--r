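test_that("row factors are per-sample medians, zero medians refuse loudly", {
  Y <- rbind(c(2, 4, 6), c(5, 5, 5))
  rownames(Y) <- c("a", "b")
  expect_equal(row_median_factors(Y), c(a = 4, b = 5))
  Yz <- rbind(c(0, 0, 0), c(5, 5, 5))
  rownames(Yz) <- c("bad", "ok")
  expect_error(row_median_factors(Yz), "near zero.*bad")
})

test_that("column factors pin every column median at exactly 1", {
  Yr <- cbind(c(0.5, 1.5, 1.0), c(2, 2, 2))
  colnames(Yr) <- c("pA", "pB")
  cf <- column_median_factors(Yr)
  expect_equal(cf, c(pA = 1.0, pB = 2.0))
  norm <- sweep(Yr, 2, cf, "/")
  expect_equal(unname(apply(norm, 2, median)), c(1, 1))
  Yz <- cbind(c(1, 1), c(0, 0))
  colnames(Yz) <- c("ok", "dead")
  expect_error(column_median_factors(Yz), "near zero.*dead")
})

test_that("probe MAD scores deviation from 1 across normal samples", {
  # constant sub-matrix: every normalised value is 1, MAD 0
  Y <- matrix(5, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(probe_stability_mad(Y, 1:3, 1:3)), c(0, 0, 0))
  # hand case: column b re-normalises to 0.9/1.1/1.0 -> MAD 0.1
  Y2 <- cbind(a = c(1, 1, 1), b = c(0.9, 1.1, 1.0), c = c(1, 1, 1))
  # row medians 1, column medians (1, 1, 1) -> values stay put
  mads <- probe_stability_mad(Y2, 1:3, 1:3)
  expect_equal(mads[["b"]], 0.1)
  expect_equal(mads[["a"]], 0)
  expect_error(probe_stability_mad(Y2, integer(0), 1:3), "no normal samples")
})

test_that("calibration selection takes the k smallest MADs, ties by index", {
  mads <- c(A = 0.02, B = 0.10, C = 0.01, D = 0.05, E = 0.03, F = 0.20)
  expect_equal(select_calibration_probes(mads, 5),
               c("C", "A", "E", "D", "B"))
  tied <- c(w = 0.1, x = 0.1, y = 0.1, z = 0.1)
  expect_equal(select_calibration_probes(tied, 2,
                                         probe_index = c(w = 4, x = 3,
                                                         y = 2, z = 1)),
               c("z", "y"))
  expect_error(select_calibration_probes(mads, 7), "smaller")
})

test_that("final row factors are calibration-probe medians per sample", {
  Z <- rbind(c(0.9, 1.0, 1.1, 1.0, 1.0), rep(2.0, 5))
  colnames(Z) <- paste0("p", 1:5)
  rownames(Z) <- c("a", "b")
  f <- final_row_factors(Z, colnames(Z))
  expect_equal(f, c(a = 1.0, b = 2.0))
  expect_equal(unname((Z / f)["b", ]), rep(1, 5))
  Zna <- Z
  Zna["a", ] <- NA
  expect_error(final_row_factors(Zna, colnames(Z)),
               "no observed calibration-probe")
})

test_that("a constant matrix is a fixed point: X is exactly 1", {
  sm <- make_signal_matrix(matrix(7, 4, 6), status = c("N", "N", "T", "T"),
                           is_reference = c(1, 1, 1, 0, 0, 0))
  fit <- normalize_mlpa(sm, k = 3)
  expect_equal(max(abs(fit$X$values - 1)), 0, tolerance = 1e-12)
})

test_that("row and column scale factors are absorbed", {
  # a separable matrix y = a * dr_i * dc_j is carried to X == 1 exactly
  set.seed(4)
  dr <- runif(8, 0.2, 5)
  dc <- runif(10, 0.2, 5)
  sep <- 1000 * outer(dr, dc)
  status <- rep(c("N", "T"), each = 4)
  is_ref <- c(rep(1, 5), rep(0, 5))
  fit_sep <- normalize_mlpa(make_signal_matrix(sep, status, is_ref), k = 3)
  expect_lt(max(abs(fit_sep$X$values - 1)), 1e-12)
  # per-sample rescaling of an arbitrary matrix never changes X
  base <- matrix(rlnorm(8 * 10, log(1000), 0.3), 8, 10)
  fit <- normalize_mlpa(make_signal_matrix(base, status, is_ref), k = 3)
  fit2 <- normalize_mlpa(make_signal_matrix(diag(dr) %*% base, status,
                                            is_ref), k = 3)
  expect_lt(max(abs(fit2$X$values - fit$X$values)), 1e-12)
  expect_equal(fit2$model$calibration_probes, fit$model$calibration_probes)
})

test_that("every step matches the brute-force oracle on random matrices", {
  set.seed(99)
  for (case in 1:200) {
    Y <- matrix(rlnorm(10 * 12, log(800), 0.4), 10, 12)
    colnames(Y) <- sprintf("p%d", 1:12)
    sm <- make_signal_matrix(Y, status = rep(c("N", "T"), each = 5),
                             is_reference = c(rep(1, 6), rep(0, 6)))
    fit <- normalize_mlpa(sm, k = 4)
    oracle <- bf_normalize(Y, 1:5, 1:6, 4)
    dimnames(oracle$X) <- dimnames(fit$X$values)
    expect_equal(fit$X$values, oracle$X, tolerance = 1e-12)
    expect_equal(unname(fit$model$probe_mad), unname(oracle$mads),
                 tolerance = 1e-12)
    expect_equal(sort(fit$model$calibration_probes), oracle$selected)
  }
})

test_that("the noisiest reference probe earns the largest MAD", {
  # 16-normal stability panel, 8 reference probes; probe 3 has 3x the
  # noise SD of its peers
  hits <- 0L
  for (rep_i in 1:200) {
    set.seed(1000 + rep_i)
    Y <- matrix(rlnorm(16 * 8, log(1000), 0.03), 16, 8)
    Y[, 3] <- rlnorm(16, log(1000), 0.09)
    mads <- probe_stability_mad(Y, 1:16, 1:8)
    if (which.max(mads) == 3L) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("calibration-probe medians of X are exactly 1 per sample", {
  cohort <- generate_cohort(simulation_spec(seed = 17))
  fit <- normalize_mlpa(cohort$signal_matrix)
  cal <- fit$model$calibration_probes
  med <- apply(fit$X$values[, cal], 1, median, na.rm = TRUE)
  expect_equal(unname(med), rep(1, nrow(fit$X$values)), tolerance = 1e-12)
})

test_that("heavily deleted samples survive calibration but not naive scaling", {
  # tumour with 11 of 12 focus probes deleted (truth 0.5): most of the
  # row sits at the deleted level, so its plain median does too
  cn <- rep(2L, 20)
  spec0 <- simulation_spec(seed = 23)
  focus <- which(!spec0$is_reference)
  cn[focus[1:11]] <- 1L
  spec <- simulation_spec(seed = 23, tumour_cn = cn)
  cohort <- generate_cohort(spec)
  fit <- normalize_mlpa(cohort$signal_matrix)
  tum <- cohort$signal_matrix$row_meta$status == "T"
  unaltered <- cohort$kit$probes$probe_id[cn == 2L]
  row_means <- rowMeans(fit$X$values[tum, unaltered])
  expect_lt(max(abs(row_means - 1)), 0.1)
  # naive all-probe row medians sit near the deleted level and inflate
  naive <- naive_median_normalize(cohort$signal_matrix)
  expect_gt(mean(naive[tum, unaltered]), 1.1)
})

test_that("the calibration-probe count barely moves recovered ratios", {
  cohort <- generate_cohort(simulation_spec(seed = 29))
  sm <- cohort$signal_matrix
  truth <- cohort$truth_ratio[sm$row_meta$sample_id, ]
  means <- sapply(c(3, 7), function(k) {
    X <- normalize_mlpa(sm, k = k)$X$values
    sapply(c(0.5, 1, 1.5), function(v) mean(X[truth == v], na.rm = TRUE))
  })
  expect_lt(max(abs(means[, 1] - means[, 2])), 0.05)
})

test_that("excluding a probe or sample is equivalent to dropping it up front", {
  cohort <- generate_cohort(simulation_spec(seed = 37))
  sm <- cohort$signal_matrix
  drop_probe <- sm$col_meta$probe_id[4]
  drop_sample <- "T03"
  fit_excl <- normalize_mlpa(sm, exclude_probes = drop_probe,
                             exclude_samples = drop_sample)
  keep_r <- sm$row_meta$sample_id != drop_sample
  keep_c <- sm$col_meta$probe_id != drop_probe
  sub <- make_signal_matrix(sm$values[keep_r, keep_c],
                            status = sm$row_meta$status[keep_r],
                            is_reference = sm$col_meta$is_reference[keep_c])
  colnames(sub$values) <- sm$col_meta$probe_id[keep_c]
  sub$col_meta$probe_id <- sm$col_meta$probe_id[keep_c]
  sub$col_meta$index <- sm$col_meta$index[keep_c]
  fit_sub <- normalize_mlpa(sub)
  expect_equal(unname(fit_sub$X$values), unname(fit_excl$X$values),
               tolerance = 1e-12)
  expect_false(drop_probe %in% colnames(fit_excl$X$values))
})

test_that("an analysis without normal samples refuses to normalise", {
  sm <- make_signal_matrix(matrix(rlnorm(12, 6, 0.1), 3, 4),
                           status = rep("T", 3),
                           is_reference = c(1, 1, 0, 0))
  expect_error(normalize_mlpa(sm, k = 2), "no normal")
})
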