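# Fixtures are built in code: small kits, traces and matrices with known
# structure, plus brute-force oracles kept independent of the package
# internals.

write_kit_file <- function(df, file = tempfile(fileext = ".tsv")) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  file
}

make_kit <- function(sizes, is_reference = rep(0L, length(sizes)),
                     genes = sprintf("G%02d", seq_along(sizes)),
                     positions = sprintf("chr1:%d",
                                         1000L * seq_along(sizes)),
                     name = "TESTKIT") {
  df <- data.frame(probe_id = sprintf("p%d", sizes), gene = genes,
                   size = sizes, position = positions,
                   is_reference = is_reference)
  suppressWarnings(read_mlpa_kit(write_kit_file(df), kit_name = name))
}

# Build a trace through the public binding path from named signal vectors:
# `heights` named by probe_id, `controls` named by fragment size.
make_trace <- function(kit, heights, controls = c(`64` = 100, `70` = 100,
                                                  `76` = 100, `82` = 100,
                                                  `94` = 600),
                       sample = "S1", areas = NULL) {
  heights <- heights[!is.na(heights)]
  sizes <- kit$probes$size[match(names(heights), kit$probes$probe_id)]
  if (is.null(areas)) areas <- heights * 2
  peaks <- data.frame(
    sample = sample,
    size = c(sizes, as.numeric(names(controls))),
    height = c(unname(heights), unname(controls)),
    area = c(unname(areas), unname(controls) * 2)
  )
  bind_peaks(peaks, kit, tolerance = 0.5)[[1]]
}

# Signal-matrix object from a bare matrix, bypassing peak IO.
make_signal_matrix <- function(values, status,
                               is_reference = rep(0L, ncol(values)),
                               measure = "height") {
  n <- ncol(values)
  col_meta <- data.frame(
    probe_id = colnames(values) %||% sprintf("p%d", seq_len(n)),
    gene = sprintf("G%02d", seq_len(n)),
    size = 100 + 10 * seq_len(n),
    position = sprintf("chr1:%d", 1000L * seq_len(n)),
    is_reference = as.integer(is_reference),
    index = seq_len(n)
  )
  colnames(values) <- col_meta$probe_id
  m <- nrow(values)
  row_meta <- data.frame(
    sample_id = rownames(values) %||% sprintf("S%02d", seq_len(m)),
    replicate_id = "r1", status = status, run_id = "run1"
  )
  rownames(values) <- row_meta$sample_id
  structure(list(values = values, measure = measure, row_meta = row_meta,
                 col_meta = col_meta),
            class = "mlpa_signal_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# Sort-based median, written without stats::median.
bf_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  stopifnot(n > 0)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

# Loop-based reimplementation of the full normalisation for cross-checks.
bf_normalize <- function(Y, normal_rows, ref_cols, k) {
  r <- apply(Y, 1, bf_median)
  Yr <- Y / r
  cc <- apply(Yr[normal_rows, , drop = FALSE], 2, bf_median)
  Z <- sweep(Yr, 2, cc, "/")
  sub <- Y[normal_rows, ref_cols, drop = FALSE]
  rs <- apply(sub, 1, bf_median)
  subr <- sub / rs
  cs <- apply(subr, 2, bf_median)
  xs <- sweep(subr, 2, cs, "/")
  mads <- apply(abs(xs - 1), 2, bf_median)
  sel <- names(sort(mads))[seq_len(k)]
  r8 <- apply(Z[, sel, drop = FALSE], 1, bf_median)
  list(X = Z / r8, mads = mads, selected = sort(sel), c = cc)
}
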