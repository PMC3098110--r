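#' Read a fragment-analysis peak table
#'
#' Reads the tab-delimited peak-table export of fragment-analysis software
#' (GeneMapper-like dialect): one row per detected peak with columns
#' `sample`, `size` (bp), `height` (RFU) and `area`. Extra columns are
#' ignored; an optional `replicate` column, when present, distinguishes
#' technical replicates of the same sample. Rows with non-numeric size,
#' height or area are dropped with a warning giving the count.
#'
#' @param file Path to the export (or a connection).
#' @param dialect Export dialect; only `"genemapper"` is recognised.
#' @return A data frame of raw peaks: `sample`, `size`, `height`, `area`
#'   and (if supplied) `replicate`.
#' @export
read_peak_table <- function(file, dialect = "genemapper") {
  dialect <- match.arg(dialect, "genemapper")
  df <- read_tsv_checked(file, c("sample", "size", "height", "area"),
                         "peak")
  if (nrow(df) == 0L) stop_("peak table contains no data rows")
  out <- data.frame(
    sample = as.character(df$sample),
    size = suppressWarnings(as.numeric(df$size)),
    height = suppressWarnings(as.numeric(df$height)),
    area = suppressWarnings(as.numeric(df$area)),
    stringsAsFactors = FALSE
  )
  if ("replicate" %in% names(df)) out$replicate <- as.character(df$replicate)
  bad <- !is.finite(out$size) | !is.finite(out$height) | !is.finite(out$area) |
    out$size <= 0 | out$height < 0 | out$area < 0
  if (any(bad)) {
    warn_(sum(bad), " peak row(s) with non-numeric or invalid ",
          "size/height/area dropped")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

new_mlpa_trace <- function(sample_id, replicate_id, kit_name, run_id,
                           probe_signals, control_signals, discarded_count) {
  structure(
    list(sample_id = sample_id, replicate_id = replicate_id,
         kit_name = kit_name, run_id = run_id,
         probe_signals = probe_signals, control_signals = control_signals,
         discarded_count = discarded_count),
    class = "mlpa_trace"
  )
}

# Assign one set of peaks (one trace) to kit probes and control fragments.
bind_one_trace <- function(peaks, kit, tolerance, sample_id, replicate_id,
                           run_id) {
  targets <- rbind(
    data.frame(id = kit$probes$probe_id, size = kit$probes$size,
               type = "probe", stringsAsFactors = FALSE),
    data.frame(id = as.character(kit$controls$size), size = kit$controls$size,
               type = "control", stringsAsFactors = FALSE)
  )
  assign_id <- character(nrow(peaks))
  assign_type <- character(nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    d <- abs(targets$size - peaks$size[p])
    hit <- which(d <= tolerance)
    if (length(hit) > 1L) {
      stop_("peak at ", peaks$size[p], " bp matches more than one kit entry ",
            "within ", tolerance, " bp (", paste(targets$id[hit],
            collapse = ", "), ")")
    }
    if (length(hit) == 1L) {
      assign_id[p] <- targets$id[hit]
      assign_type[p] <- targets$type[hit]
    }
  }
  discarded <- sum(assign_type == "")

  pick_one <- function(rows, label) {
    if (length(rows) > 1L) {
      warn_("sample ", sample_id, ": multiple peaks bound to ", label,
            "; keeping the tallest")
      rows <- rows[which.max(peaks$height[rows])]
    }
    rows
  }
  probe_signals <- data.frame(probe_id = character(0), height = numeric(0),
                              area = numeric(0), stringsAsFactors = FALSE)
  for (id in kit$probes$probe_id) {
    rows <- which(assign_type == "probe" & assign_id == id)
    if (length(rows) == 0L) next
    rows <- pick_one(rows, paste0("probe ", id))
    probe_signals <- rbind(probe_signals, data.frame(
      probe_id = id, height = peaks$height[rows], area = peaks$area[rows],
      stringsAsFactors = FALSE))
  }
  control_signals <- data.frame(size = integer(0), height = numeric(0),
                                area = numeric(0), stringsAsFactors = FALSE)
  for (sz in kit$controls$size) {
    rows <- which(assign_type == "control" & assign_id == as.character(sz))
    if (length(rows) == 0L) next
    rows <- pick_one(rows, paste0("control fragment ", sz, " bp"))
    control_signals <- rbind(control_signals, data.frame(
      size = sz, height = peaks$height[rows], area = peaks$area[rows],
      stringsAsFactors = FALSE))
  }
  new_mlpa_trace(sample_id, replicate_id, kit$kit_name, run_id,
                 probe_signals, control_signals, discarded)
}

#' Bind raw peaks to kit probes and control fragments
#'
#' Each peak is matched by fragment size to the unique kit probe or
#' universal control fragment within `tolerance` bp. Peaks matching nothing
#' are discarded (counted per trace); a probe with no matching peak is
#' recorded as missing, never as zero. When two peaks in one trace bind the
#' same probe the taller one is kept with a warning.
#'
#' @param peaks Data frame from [read_peak_table()].
#' @param kit An `mlpa_kit`.
#' @param tolerance Size-match tolerance in bp (default 1.0).
#' @param run_id Identifier of the electrophoresis run; also the default
#'   replicate id when the peak table has no `replicate` column.
#' @return A list of `mlpa_trace` objects, one per (sample, replicate),
#'   in first-appearance order.
#' @export
bind_peaks <- function(peaks, kit, tolerance = 1.0, run_id = "run1") {
  stopifnot(inherits(kit, "mlpa_kit"))
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop_("tolerance must be a positive number of base pairs")
  }
  rep_id <- if ("replicate" %in% names(peaks)) peaks$replicate else
    rep(run_id, nrow(peaks))
  key <- paste(peaks$sample, rep_id, sep = "\r")
  traces <- lapply(unique(key), function(k) {
    rows <- which(key == k)
    bind_one_trace(peaks[rows, , drop = FALSE], kit, tolerance,
                   sample_id = peaks$sample[rows[1L]],
                   replicate_id = rep_id[rows[1L]], run_id = run_id)
  })
  traces
}

#' @export
print.mlpa_trace <- function(x, ...) {
  cat(sprintf(
    "MLPA trace %s (replicate %s, kit %s): %d probe signals, %d control fragments, %d discarded peak(s)\n",
    x$sample_id, x$replicate_id, x$kit_name, nrow(x$probe_signals),
    nrow(x$control_signals), x$discarded_count))
  invisible(x)
}

#' Assemble the raw signal matrix
#'
#' Builds the samples-by-probes matrix Y of raw signals for the chosen
#' measure (peak height or peak area). Rows are traces (one per sample and
#' replicate), columns are kit probes in index order. Probes without a
#' bound peak are `NA` — missing, never zero — and are excluded from every
#' median downstream.
#'
#' @param traces List of `mlpa_trace` objects sharing one kit.
#' @param kit The `mlpa_kit` all traces were bound against.
#' @param measure `"height"` or `"area"`.
#' @param sample_meta Optional data frame with columns `sample_id` and
#'   `status` (`"N"` normal / `"T"` test); may also carry `tissue_origin`,
#'   `dna_concentration`, `tumour_percentage`. Status defaults to `NA`.
#' @return An object of class `mlpa_signal_matrix`: list with `values`
#'   (numeric matrix), `measure`, `row_meta` (sample_id, replicate_id,
#'   status, run_id) and `col_meta` (the kit probe table).
#' @export
build_signal_matrix <- function(traces, kit, measure = c("height", "area"),
                                sample_meta = NULL) {
  measure <- match.arg(measure)
  stopifnot(inherits(kit, "mlpa_kit"), length(traces) > 0L)
  kits <- vapply(traces, function(t) t$kit_name, character(1))
  if (any(kits != kit$kit_name)) {
    stop_("traces from different kits cannot share a signal matrix: ",
          paste(unique(kits), collapse = ", "))
  }
  n <- nrow(kit$probes)
  m <- length(traces)
  Y <- matrix(NA_real_, nrow = m, ncol = n,
              dimnames = list(NULL, kit$probes$probe_id))
  row_meta <- data.frame(
    sample_id = vapply(traces, function(t) t$sample_id, character(1)),
    replicate_id = vapply(traces, function(t) t$replicate_id, character(1)),
    status = NA_character_,
    run_id = vapply(traces, function(t) t$run_id, character(1)),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(m)) {
    sig <- traces[[i]]$probe_signals
    if (nrow(sig) > 0L) {
      Y[i, sig$probe_id] <- sig[[measure]]
    }
  }
  if (!is.null(sample_meta)) {
    stopifnot(all(c("sample_id", "status") %in% names(sample_meta)))
    idx <- match(row_meta$sample_id, sample_meta$sample_id)
    row_meta$status <- as.character(sample_meta$status)[idx]
    if (any(!is.na(row_meta$status) & !row_meta$status %in% c("N", "T"))) {
      stop_("sample status must be 'N' or 'T'")
    }
  }
  rownames(Y) <- paste(row_meta$sample_id, row_meta$replicate_id, sep = ".")
  structure(
    list(values = Y, measure = measure, row_meta = row_meta,
         col_meta = kit$probes),
    class = "mlpa_signal_matrix"
  )
}

#' @export
print.mlpa_signal_matrix <- function(x, ...) {
  cat(sprintf("MLPA signal matrix (%s): %d traces x %d probes, %d missing cell(s)\n",
              x$measure, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Write a sequencer sample sheet
#'
#' Produces the tab-delimited sheet (columns `well`, `sample_id`,
#' `kit_name`) the capillary sequencer consumes, rows sorted by plate
#' position (A1, A2, ..., H12). Output is byte-identical for identical
#' input.
#'
#' @param layout Data frame with columns `well`, `sample_id`, `kit_name`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_sample_sheet <- function(layout, file) {
  stopifnot(all(c("well", "sample_id", "kit_name") %in% names(layout)))
  if (anyDuplicated(layout$well)) {
    stop_("duplicate well position(s): ",
          paste(unique(layout$well[duplicated(layout$well)]), collapse = ", "))
  }
  row_letter <- substr(layout$well, 1L, 1L)
  col_num <- suppressWarnings(as.integer(sub("^[A-Ha-h]", "", layout$well)))
  ord <- order(row_letter, col_num, method = "radix")
  write_tsv_plain(layout[ord, c("well", "sample_id", "kit_name")], file)
}
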