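peak_file <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("well-formed peak tables parse row for row", {
  f <- peak_file(data.frame(sample = "S1", size = c(100, 130, 64, 94),
                            height = c(500, 600, 100, 700),
                            area = c(1000, 1200, 200, 1400)))
  peaks <- read_peak_table(f)
  expect_equal(nrow(peaks), 4L)
  expect_equal(peaks$height, c(500, 600, 100, 700))
})

test_that("rows with non-numeric fields are dropped with a warning", {
  f <- peak_file(data.frame(sample = "S1", size = c("100", "NA", "130"),
                            height = c("500", "600", "700"),
                            area = c("1", "2", "3")))
  expect_warning(peaks <- read_peak_table(f), "1 peak row")
  expect_equal(nrow(peaks), 2L)
  expect_equal(peaks$size, c(100, 130))
})

test_that("unreadable or empty peak tables are hard errors", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("sample\tsize\theight\tarea", empty)
  expect_error(read_peak_table(empty), "no data rows")
  wrong <- peak_file(data.frame(foo = 1, bar = 2))
  expect_error(read_peak_table(wrong), "missing required column")
})

test_that("peaks bind to the probe within tolerance, strays are discarded", {
  kit <- make_kit(c(130, 160))
  peaks <- data.frame(sample = "S1",
                      size = c(130.3, 160.1, 132.0, 64, 70, 76, 82, 94.2),
                      height = c(500, 400, 99, 100, 100, 100, 100, 600),
                      area = 1)
  tr <- bind_peaks(peaks, kit, tolerance = 1.0)[[1]]
  expect_equal(sort(tr$probe_signals$probe_id), c("p130", "p160"))
  expect_equal(tr$probe_signals$height[tr$probe_signals$probe_id == "p130"],
               500)
  expect_equal(tr$discarded_count, 1L)
  expect_equal(nrow(tr$control_signals), 5L)
})

test_that("duplicate peaks for one probe keep the taller with a warning", {
  kit <- make_kit(c(130, 160))
  peaks <- data.frame(sample = "S1", size = c(129.8, 130.2, 160),
                      height = c(300, 900, 400), area = c(5, 1, 2))
  expect_warning(tr <- bind_peaks(peaks, kit, tolerance = 0.5)[[1]],
                 "multiple peaks")
  sig <- tr$probe_signals[tr$probe_signals$probe_id == "p130", ]
  expect_equal(sig$height, 900)
  expect_equal(sig$area, 1)
})

test_that("a peak matching two kit entries is a hard error", {
  kit <- make_kit(c(130, 131))
  peaks <- data.frame(sample = "S1", size = 130.5, height = 10, area = 1)
  expect_error(bind_peaks(peaks, kit, tolerance = 1.0),
               "more than one kit entry")
})

test_that("binding conserves peaks and ignores input order", {
  cohort <- generate_cohort(simulation_spec(seed = 3, stray_peak_rate = 2))
  key <- paste(cohort$peaks$sample, cohort$peaks$replicate)
  counts <- table(key)
  for (tr in cohort$traces) {
    n_in <- counts[[paste(tr$sample_id, tr$replicate_id)]]
    expect_equal(nrow(tr$probe_signals) + nrow(tr$control_signals) +
                   tr$discarded_count, n_in)
  }
  set.seed(9)
  shuffled <- cohort$peaks[sample(nrow(cohort$peaks)), ]
  tr2 <- bind_peaks(shuffled, cohort$kit, run_id = "synthrun1")
  ids <- vapply(tr2, function(t) paste(t$sample_id, t$replicate_id),
                character(1))
  for (tr in cohort$traces) {
    match_tr <- tr2[[which(ids == paste(tr$sample_id, tr$replicate_id))]]
    o1 <- tr$probe_signals[order(tr$probe_signals$probe_id), ]
    o2 <- match_tr$probe_signals[order(match_tr$probe_signals$probe_id), ]
    expect_equal(o1$height, o2$height)
    expect_equal(match_tr$discarded_count, tr$discarded_count)
  }
})

test_that("the default synthetic export parses to the authored peak count", {
  dir <- tempfile()
  generate_cohort(simulation_spec(seed = 42), dir = dir)
  peaks <- read_peak_table(file.path(dir, "peaks.tsv"))
  # 16 traces x (20 probes + 5 control fragments), no strays
  expect_equal(nrow(peaks), 16L * 25L)
})

test_that("signal matrix carries the chosen measure and real missingness", {
  kit <- make_kit(c(100, 130, 160))
  t1 <- make_trace(kit, c(p100 = 10, p130 = 20, p160 = 30), sample = "A")
  t2 <- make_trace(kit, c(p100 = 40, p160 = 60), sample = "B")
  meta <- data.frame(sample_id = c("A", "B"), status = c("N", "T"))
  sm_h <- build_signal_matrix(list(t1, t2), kit, "height", meta)
  expect_equal(unname(sm_h$values[1, ]), c(10, 20, 30))
  expect_true(is.na(sm_h$values[2, "p130"]))
  expect_false(any(sm_h$values == 0, na.rm = TRUE))
  expect_equal(sm_h$row_meta$status, c("N", "T"))
  sm_a <- build_signal_matrix(list(t1, t2), kit, "area", meta)
  expect_equal(unname(sm_a$values[1, ]), c(20, 40, 60))
})

test_that("traces from different kits cannot be mixed in one matrix", {
  kit_a <- make_kit(c(100, 130), name = "A")
  kit_b <- make_kit(c(100, 130), name = "B")
  ta <- make_trace(kit_a, c(p100 = 1, p130 = 2))
  tb <- make_trace(kit_b, c(p100 = 1, p130 = 2))
  expect_error(build_signal_matrix(list(ta, tb), kit_a),
               "different kits")
})

test_that("sample sheets are sorted by well and byte-stable", {
  layout <- data.frame(well = c("B1", "A12", "A2", "H12", "A1"),
                       sample_id = sprintf("S%d", 1:5),
                       kit_name = "K1")
  f1 <- tempfile(); f2 <- tempfile()
  write_sample_sheet(layout, f1)
  lines <- readLines(f1)
  expect_equal(lines[1], "well\tsample_id\tkit_name")
  expect_equal(sub("\t.*", "", lines[-1]), c("A1", "A2", "A12", "B1", "H12"))
  write_sample_sheet(layout[sample(5), ], f2)
  expect_identical(readLines(f2), lines)
  empty <- layout[0, ]
  f3 <- tempfile()
  write_sample_sheet(empty, f3)
  expect_equal(readLines(f3), "well\tsample_id\tkit_name")
  expect_error(write_sample_sheet(rbind(layout, layout[1, ]), tempfile()),
               "duplicate well")
})
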