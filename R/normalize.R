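#' @name mlpa_normalisation
#' @title Median-based MLPA normalisation with calibration-probe selection
#'
#' @description
#' Raw MLPA signals confound copy number with sample quality, probe
#' efficiency and instrument settings. Treating the data as a matrix Y
#' (rows = traces, columns = probes), normalisation divides each cell by a
#' row parameter \eqn{r_i} and a column parameter \eqn{c_j}, giving
#' \eqn{x_{ij} = y_{ij}/(r_i c_j)} on the original (not log) scale, where
#' loss, neutral and gain correspond to ratios near 0.5, 1 and 1.5.
#'
#' Plain row medians fail on samples with many deletions: the row median
#' itself drifts toward the deleted level and dividing by it inflates
#' every ratio. The procedure therefore anchors the per-sample scale on
#' \emph{calibration probes}: among the kit's reference probes (loci not
#' expected to change), the k (default 5) probes with the smallest MAD —
#' median over normal samples of |normalised value - 1| — are selected,
#' and each sample is finally rescaled so its median over those probes
#' is 1.
#'
#' The algorithm:
#' \enumerate{
#'   \item divide every sample (row) by its median — provisional row
#'     factors \eqn{\check{r}};
#'   \item divide every probe (column) by its median across the
#'     row-normalised \emph{normal} samples — column factors \eqn{c};
#'   \item take the kit's reference probes as candidates;
#'   \item restrict to normal samples and reference probes;
#'   \item redo steps 1–2 on that sub-matrix;
#'   \item per probe, MAD = median of |value − 1| over normal samples;
#'   \item keep the k probes with the smallest MAD (ties broken by probe
#'     index) — the calibration probes;
#'   \item per sample, divide the step-2 values by their median over the
#'     calibration probes — final row factors \eqn{r}.
#' }
#'
#' All medians skip missing cells; a median over an empty set, or a row or
#' column factor at or near zero, is a hard error naming the offending
#' sample or probe.
NULL

near_zero_guard <- function(factors, grand_median, what, names) {
  bad <- !is.finite(factors) | factors <= 1e-9 * grand_median
  if (any(bad)) {
    stop_(what, " median is zero or near zero for ",
          paste(names[bad], collapse = ", "),
          "; dividing by it would corrupt every ratio — exclude or fix ",
          "these before normalising")
  }
  invisible(factors)
}

#' Provisional row factors (per-sample medians)
#'
#' Step 1 of the normalisation: the median observed signal of each
#' selected row of Y. Division is left to the caller.
#'
#' @param Y Numeric matrix (traces x probes), `NA` = missing.
#' @param rows Row indices to compute factors for (default all).
#' @return Named numeric vector of row medians.
#' @export
row_median_factors <- function(Y, rows = seq_len(nrow(Y))) {
  grand <- obs_median(Y, "the signal matrix")
  labs <- rownames(Y) %||% as.character(seq_len(nrow(Y)))
  f <- vapply(rows, function(i) {
    obs_median(Y[i, ], paste0("row ", labs[i]))
  }, numeric(1))
  names(f) <- labs[rows]
  near_zero_guard(f, grand, "sample", names(f))
}

#' Column factors (per-probe medians of the row-normalised matrix)
#'
#' Step 2 of the normalisation: the median of each column of the
#' row-normalised matrix, taken across the given rows (the normal
#' samples). After dividing by these, each such column has median exactly
#' 1.
#'
#' @param Y_row Row-normalised numeric matrix.
#' @param rows Rows across which to take the medians (default all).
#' @return Named numeric vector of column medians.
#' @export
column_median_factors <- function(Y_row, rows = seq_len(nrow(Y_row))) {
  grand <- obs_median(Y_row[rows, , drop = FALSE], "the matrix")
  labs <- colnames(Y_row) %||% as.character(seq_len(ncol(Y_row)))
  f <- vapply(seq_len(ncol(Y_row)), function(j) {
    obs_median(Y_row[rows, j], paste0("probe ", labs[j]))
  }, numeric(1))
  names(f) <- labs
  near_zero_guard(f, grand, "probe", names(f))
}

#' Probe stability (MAD across normal samples)
#'
#' Steps 4–6: the normal-sample x reference-probe sub-matrix is
#' re-normalised from scratch (row medians, then column medians within the
#' subset) and each probe's stability is scored as the median over normal
#' samples of the absolute deviation from 1. Smaller MAD = more stable.
#'
#' @param Y Raw numeric signal matrix.
#' @param normal_rows Indices of normal (status N) rows.
#' @param ref_cols Indices (or names) of reference-probe columns.
#' @return Named numeric vector: MAD per reference probe.
#' @export
probe_stability_mad <- function(Y, normal_rows, ref_cols) {
  if (length(normal_rows) == 0L) {
    stop_("no normal samples: external normal controls must be present ",
          "in every experiment")
  }
  if (length(normal_rows) < 2L) {
    warn_("only ", length(normal_rows),
          " normal sample(s); probe stability estimates will be weak")
  }
  sub <- Y[normal_rows, ref_cols, drop = FALSE]
  r <- row_median_factors(sub)
  sub_row <- sweep(sub, 1L, r, "/")
  cc <- column_median_factors(sub_row)
  x <- sweep(sub_row, 2L, cc, "/")
  mads <- apply(abs(x - 1), 2L, function(v) obs_median(v, "probe deviations"))
  names(mads) <- colnames(sub)
  mads
}

#' Select the calibration probes
#'
#' Step 7: the k reference probes with the smallest MAD. Ties are broken
#' by ascending probe index so that selection is deterministic.
#'
#' @param mads Named MAD vector from [probe_stability_mad()].
#' @param k Number of calibration probes (default 5).
#' @param probe_index Optional named vector of probe indices for
#'   tie-breaking; defaults to position in `mads`.
#' @return Character vector of k probe ids, ordered by ascending MAD.
#' @export
select_calibration_probes <- function(mads, k = 5L, probe_index = NULL) {
  if (k < 1L) stop_("k must be at least 1")
  if (length(mads) < k) {
    stop_("only ", length(mads), " reference probes available but k = ", k,
          "; choose a smaller calibration-probe count")
  }
  idx <- probe_index[names(mads)] %||% seq_along(mads)
  ord <- order(mads, idx)
  names(mads)[ord[seq_len(k)]]
}

#' Final row factors (calibration-probe medians)
#'
#' Step 8: for every sample — normal and test alike — the median of its
#' step-2 (row- and column-normalised) values over the calibration-probe
#' columns. Dividing each row by this factor pins its calibration-probe
#' median at exactly 1.
#'
#' @param Z Step-2 normalised matrix.
#' @param calibration_probes Column names of the calibration probes.
#' @return Named numeric vector of final per-row scale factors.
#' @export
final_row_factors <- function(Z, calibration_probes) {
  labs <- rownames(Z) %||% as.character(seq_len(nrow(Z)))
  f <- vapply(seq_len(nrow(Z)), function(i) {
    v <- Z[i, calibration_probes]
    if (all(is.na(v))) {
      stop_("sample ", labs[i], " has no observed calibration-probe ",
            "signal; it cannot be scaled")
    }
    obs_median(v, "calibration values")
  }, numeric(1))
  names(f) <- labs
  near_zero_guard(f, 1, "calibration-probe", names(f))
}

#' Full MLPA normalisation
#'
#' Runs the complete procedure (see [mlpa_normalisation]) on a signal
#' matrix: provisional row factors, column factors from the normal
#' samples, MAD-based calibration-probe selection among the reference
#' probes, and final per-sample scaling. Exclusions are applied before any
#' median is taken. Recomputation with identical inputs is bit-identical.
#'
#' @param Y An `mlpa_signal_matrix` (row_meta$status must mark at least
#'   one `"N"` sample).
#' @param k Number of calibration probes (default 5).
#' @param reference_probes Probe ids to use as the reference pool;
#'   defaults to the kit's `is_reference` flags.
#' @param exclude_probes,exclude_samples Ids removed from the analysis
#'   before any computation.
#' @return List with `X` (an `mlpa_normalized_matrix`: same shape and
#'   metadata as the retained part of `Y`, values \eqn{x = y/(r c)}) and
#'   `model` (an `mlpa_norm_model` recording every factor: provisional row
#'   factors, column factors, per-reference-probe MAD, the ordered
#'   calibration probes, final row factors, and the settings used).
#' @examples
#' spec <- simulation_spec(seed = 7)
#' cohort <- generate_cohort(spec)
#' fit <- normalize_mlpa(cohort$signal_matrix)
#' fit$model$calibration_probes
#' summary(as.vector(fit$X$values))
#' @export
normalize_mlpa <- function(Y, k = 5L, reference_probes = NULL,
                           exclude_probes = character(0),
                           exclude_samples = character(0)) {
  stopifnot(inherits(Y, "mlpa_signal_matrix"))
  keep_col <- !(Y$col_meta$probe_id %in% exclude_probes)
  keep_row <- !(Y$row_meta$sample_id %in% exclude_samples)
  vals <- Y$values[keep_row, keep_col, drop = FALSE]
  row_meta <- Y$row_meta[keep_row, , drop = FALSE]
  col_meta <- Y$col_meta[keep_col, , drop = FALSE]

  if (is.null(reference_probes)) {
    reference_probes <- col_meta$probe_id[col_meta$is_reference == 1L]
  }
  reference_probes <- setdiff(reference_probes, exclude_probes)
  if (!all(reference_probes %in% col_meta$probe_id)) {
    stop_("reference probes not in the kit: ",
          paste(setdiff(reference_probes, col_meta$probe_id), collapse = ", "))
  }
  normal_rows <- which(!is.na(row_meta$status) & row_meta$status == "N")
  if (length(normal_rows) == 0L) {
    stop_("no normal (status N) samples: external normal controls must be ",
          "present in every experiment")
  }
  if (length(unique(row_meta$run_id)) > 1L) {
    warn_("traces from ", length(unique(row_meta$run_id)),
          " different runs combined in one analysis; values from ",
          "experiments performed at a different time should not be mixed")
  }

  # Steps 1-2: provisional row scaling, column factors from normals.
  r_prov <- row_median_factors(vals)
  Y_row <- sweep(vals, 1L, r_prov, "/")
  c_fac <- column_median_factors(Y_row, rows = normal_rows)
  Z <- sweep(Y_row, 2L, c_fac, "/")

  # Steps 4-7: probe stability on normals x reference probes.
  mads <- probe_stability_mad(vals, normal_rows, reference_probes)
  probe_index <- stats::setNames(col_meta$index, col_meta$probe_id)
  calibration <- select_calibration_probes(mads, k, probe_index)

  # Step 8: anchor every sample on its calibration-probe median.
  r_final <- final_row_factors(Z, calibration)
  X <- sweep(Z, 1L, r_final, "/")

  model <- structure(
    list(
      row_factors_provisional = r_prov,
      column_factors = c_fac,
      probe_mad = mads,
      calibration_probes = calibration,
      row_factors_final = r_prov * r_final,
      k = as.integer(k),
      reference_probes = reference_probes,
      normal_samples = row_meta$sample_id[normal_rows],
      exclude_probes = exclude_probes,
      exclude_samples = exclude_samples,
      measure = Y$measure
    ),
    class = "mlpa_norm_model"
  )
  Xobj <- structure(
    list(values = X, measure = Y$measure, row_meta = row_meta,
         col_meta = col_meta),
    class = c("mlpa_normalized_matrix", "mlpa_signal_matrix")
  )
  list(X = Xobj, model = model)
}

#' Naive all-probe row-median normalisation
#'
#' The simple scheme the calibration-probe procedure replaces: every row
#' is divided by its own median over \emph{all} probes, then columns by
#' their medians across all rows. Adequate when aberrations are sparse,
#' but a sample with many deletions drags its own row median down and
#' every ratio in that row is inflated. Provided for comparison and
#' regression testing of that failure mode.
#'
#' @param Y An `mlpa_signal_matrix` or bare numeric matrix.
#' @return Numeric matrix of naively normalised ratios.
#' @export
naive_median_normalize <- function(Y) {
  vals <- if (inherits(Y, "mlpa_signal_matrix")) Y$values else Y
  r <- row_median_factors(vals)
  Y_row <- sweep(vals, 1L, r, "/")
  cc <- column_median_factors(Y_row)
  sweep(Y_row, 2L, cc, "/")
}

#' @export
print.mlpa_norm_model <- function(x, ...) {
  cat("MLPA normalisation model\n")
  cat("  measure:            ", x$measure, "\n")
  cat("  normal samples:     ", length(x$normal_samples), "\n")
  cat("  reference probes:   ", length(x$reference_probes), "\n")
  cat("  calibration probes: ", paste(x$calibration_probes, collapse = ", "),
      "\n")
  invisible(x)
}
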