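#' Classify normalised ratios into loss / normal / gain
#'
#' Applies the dosage thresholds to a normalised matrix: a cell is a loss
#' when its ratio is strictly below `loss_threshold` (default 0.8, single
#' allele lost in pure material gives ~0.5), a gain when strictly above
#' `gain_threshold` (default 1.25; single-copy gain gives ~1.5), normal
#' otherwise. Values exactly at a threshold are normal. Missing cells stay
#' missing and enter neither tally.
#'
#' @param X An `mlpa_normalized_matrix` (or bare numeric matrix).
#' @param loss_threshold,gain_threshold Thresholds with
#'   `0 < loss_threshold < 1 < gain_threshold`.
#' @return An `mlpa_call_matrix`: list with `states` (character matrix of
#'   `"loss"`, `"normal"`, `"gain"`, `"missing"`), the thresholds, and
#'   per-row `gain_count` / `loss_count`.
#' @export
classify_calls <- function(X, loss_threshold = 0.8, gain_threshold = 1.25) {
  if (!(loss_threshold > 0 && loss_threshold < 1 && gain_threshold > 1)) {
    stop_("thresholds must satisfy 0 < loss < 1 < gain (got loss = ",
          loss_threshold, ", gain = ", gain_threshold, ")")
  }
  vals <- if (inherits(X, "mlpa_signal_matrix")) X$values else X
  states <- matrix("normal", nrow = nrow(vals), ncol = ncol(vals),
                   dimnames = dimnames(vals))
  states[vals < loss_threshold] <- "loss"
  states[vals > gain_threshold] <- "gain"
  states[is.na(vals)] <- "missing"
  structure(
    list(states = states,
         loss_threshold = loss_threshold,
         gain_threshold = gain_threshold,
         loss_count = apply(states == "loss", 1L, sum),
         gain_count = apply(states == "gain", 1L, sum)),
    class = "mlpa_call_matrix"
  )
}

#' @export
print.mlpa_call_matrix <- function(x, ...) {
  cat(sprintf(
    "MLPA calls (%d x %d): %d loss, %d gain, %d missing cell(s); thresholds <%g / >%g\n",
    nrow(x$states), ncol(x$states), sum(x$states == "loss"),
    sum(x$states == "gain"), sum(x$states == "missing"),
    x$loss_threshold, x$gain_threshold))
  invisible(x)
}

#' Aggregate technical replicates
#'
#' MLPA assays are typically run at least in duplicate. Rows of the
#' normalised matrix are grouped by `sample_id`; the consensus value per
#' probe is the median across that sample's replicates (robust to a single
#' aberrant replicate), while the individual replicate values are retained
#' for plotting and concordance checks.
#'
#' @param X An `mlpa_normalized_matrix`.
#' @return List with `consensus` (samples x probes matrix) and
#'   `summaries`, a per-sample list carrying `sample_id`, `replicates`
#'   (replicate x probe matrix with replicate ids as row names) and
#'   `consensus` (numeric vector).
#' @export
aggregate_replicates <- function(X) {
  stopifnot(inherits(X, "mlpa_signal_matrix"))
  ids <- unique(X$row_meta$sample_id)
  summaries <- lapply(ids, function(s) {
    rows <- which(X$row_meta$sample_id == s)
    reps <- X$values[rows, , drop = FALSE]
    rownames(reps) <- X$row_meta$replicate_id[rows]
    cons <- apply(reps, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else stats::median(v)
    })
    list(sample_id = s, replicates = reps, consensus = cons)
  })
  names(summaries) <- ids
  consensus <- do.call(rbind, lapply(summaries, `[[`, "consensus"))
  rownames(consensus) <- ids
  list(consensus = consensus, summaries = summaries)
}

# Parse "chrN:pos" into a sortable (chromosome rank, position) pair;
# anything else sorts lexically after parseable positions.
position_sort_key <- function(position) {
  m <- regmatches(position,
                  regexec("^chr([0-9XYM]+):([0-9]+)", position))
  chr_rank <- vapply(m, function(g) {
    if (length(g) == 0L) return(NA_real_)
    chr <- g[2L]
    if (chr == "X") 23 else if (chr == "Y") 24 else if (chr == "M") 25
    else suppressWarnings(as.numeric(chr))
  }, numeric(1))
  pos <- vapply(m, function(g) {
    if (length(g) < 3L) NA_real_ else as.numeric(g[3L])
  }, numeric(1))
  list(chr_rank = chr_rank, pos = pos, raw = as.character(position))
}

#' Probe display order
#'
#' A stable total order over kit probes for heat maps and sample plots:
#' by `"index"` (product size, the kit order), by `"gene"` (gene name,
#' then chromosomal position), or by `"position"` (parsed `chrN:start`
#' when available, lexical otherwise). Ties always fall back to probe
#' index.
#'
#' @param kit An `mlpa_kit`.
#' @param key `"index"`, `"gene"` or `"position"`.
#' @return Character vector of probe ids in display order.
#' @export
sort_probes <- function(kit, key = c("index", "gene", "position")) {
  key <- match.arg(key)
  p <- kit$probes
  ord <- switch(
    key,
    index = order(p$index),
    gene = {
      k <- position_sort_key(p$position)
      order(p$gene, !is.finite(k$chr_rank), k$chr_rank, k$pos, k$raw, p$index,
            method = "radix")
    },
    position = {
      k <- position_sort_key(p$position)
      order(!is.finite(k$chr_rank), k$chr_rank, k$pos, k$raw, p$index,
            method = "radix")
    }
  )
  p$probe_id[ord]
}

# Probe column labels: calibration probes get suffix 'c', other reference
# probes 'r', focus probes none.
probe_display_labels <- function(col_meta, calibration_probes) {
  suffix <- ifelse(col_meta$probe_id %in% calibration_probes, "c",
                   ifelse(col_meta$is_reference == 1L, "r", ""))
  paste0(col_meta$probe_id, suffix)
}

#' Heat-map table (text twin)
#'
#' Assembles the per-trace table behind the heat map: normalised values in
#' display order (column headers suffixed `c` for calibration probes and
#' `r` for other reference probes), per-row gain and loss counts, and the
#' Q1–Q3 quality indicators. Every number displayed in the rendered heat
#' map comes from this table, so text comparisons never parse images.
#'
#' @param X An `mlpa_normalized_matrix`.
#' @param calls Matching `mlpa_call_matrix`.
#' @param qc Data frame from [qc_report()] covering the same traces.
#' @param calibration_probes Probe ids selected as calibration probes.
#' @param order Probe ids in display order (default: matrix column order).
#' @return Data frame, one row per trace.
#' @export
heatmap_table <- function(X, calls, qc, calibration_probes,
                          order = colnames(X$values)) {
  stopifnot(nrow(X$values) == nrow(calls$states),
            nrow(qc) == nrow(X$values))
  col_meta <- X$col_meta[match(order, X$col_meta$probe_id), , drop = FALSE]
  labels <- probe_display_labels(col_meta, calibration_probes)
  vals <- X$values[, order, drop = FALSE]
  out <- data.frame(
    sample_id = X$row_meta$sample_id,
    replicate_id = X$row_meta$replicate_id,
    status = X$row_meta$status,
    stringsAsFactors = FALSE
  )
  for (j in seq_along(order)) out[[labels[j]]] <- fmt_num(vals[, j])
  out$gain <- calls$gain_count
  out$loss <- calls$loss_count
  out$q1 <- fmt_num(qc$q1, 4L)
  out$q2 <- fmt_num(qc$q2_median, 6L)
  out$q3 <- fmt_num(qc$q3, 4L)
  out
}

#' Render the cohort heat map
#'
#' Draws the loss/normal/gain grid (yellow = loss, blue = gain, white =
#' normal, grey = missing) with gain/loss counts and QC indices in the
#' margin text, and writes the tab-delimited twin of the displayed numbers
#' next to it. The twin is byte-identical across re-renders of the same
#' analysis.
#'
#' @inheritParams heatmap_table
#' @param file Output image path (`.png`).
#' @param tsv Path for the text twin; default `file` with a `.tsv`
#'   extension.
#' @return Invisible list with the image and twin paths.
#' @export
render_heatmap <- function(X, calls, qc, calibration_probes,
                           order = colnames(X$values), file,
                           tsv = sub("\\.[^.]*$", ".tsv", file)) {
  tab <- heatmap_table(X, calls, qc, calibration_probes, order)
  write_tsv_plain(tab, tsv)

  states <- calls$states[, order, drop = FALSE]
  code <- matrix(match(states, c("loss", "normal", "gain", "missing")),
                 nrow = nrow(states))
  cols <- c("gold", "white", "steelblue2", "grey70")
  col_meta <- X$col_meta[match(order, X$col_meta$probe_id), , drop = FALSE]
  labels <- probe_display_labels(col_meta, calibration_probes)

  grDevices::png(file, width = 140 + 28 * ncol(states),
                 height = 120 + 22 * nrow(states))
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(6, 8, 3, 6))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(x = seq_len(ncol(code)), y = seq_len(nrow(code)),
                  z = t(code[rev(seq_len(nrow(code))), , drop = FALSE]),
                  zlim = c(1, 4), col = cols, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(code)), labels = labels, las = 2,
                 cex.axis = 0.8, tick = FALSE)
  graphics::axis(2, at = rev(seq_len(nrow(code))),
                 labels = paste(X$row_meta$sample_id,
                                X$row_meta$replicate_id, sep = "."),
                 las = 2, cex.axis = 0.8, tick = FALSE)
  graphics::axis(4, at = rev(seq_len(nrow(code))),
                 labels = sprintf("g%d/l%d", calls$gain_count,
                                  calls$loss_count),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  graphics::box()
  graphics::title(main = sprintf("MLPA calls (loss < %g, gain > %g)",
                                 calls$loss_threshold,
                                 calls$gain_threshold))
  invisible(list(image = file, tsv = tsv))
}

#' Render a per-sample ratio plot
#'
#' Normalised ratios for one sample across probes in display order:
#' replicates as points in distinct colours, the consensus as a line,
#' reference lines at 0.5 (single-copy loss), 1.0 (unaltered) and 1.5
#' (single-copy gain). The y axis runs from 0 (absent probe) to `y_max`
#' (default 2.5; raise it for amplified samples); values above `y_max`
#' are drawn clipped at the top with a distinct marker. The replicate QC
#' indices are printed in the legend.
#'
#' @param summary One element of `aggregate_replicates()$summaries`.
#' @param order Probe ids in display order.
#' @param y_max Upper axis limit, at least 2.5.
#' @param qc Optional [qc_report()] rows for this sample's replicates.
#' @param file Output image path (`.png`).
#' @return Invisible `file`.
#' @export
render_sample_plot <- function(summary, order = colnames(summary$replicates),
                               y_max = 2.5, qc = NULL, file) {
  if (y_max < 2.5) stop_("y_max must be at least 2.5")
  reps <- summary$replicates[, order, drop = FALSE]
  cons <- summary$consensus[order]
  nrep <- nrow(reps)
  pal <- grDevices::hcl.colors(max(nrep, 2L), "Dark 3")[seq_len(nrep)]

  grDevices::png(file, width = 160 + 30 * length(order), height = 480)
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(0.5, length(order) + 0.5), ylim = c(0, y_max),
                 xlab = "", ylab = "normalised ratio", axes = FALSE,
                 main = paste("Sample", summary$sample_id))
  graphics::axis(1, at = seq_along(order), labels = order, las = 2,
                 cex.axis = 0.8)
  graphics::axis(2)
  graphics::box()
  graphics::abline(h = c(0.5, 1.0, 1.5), lty = 3, col = "grey50")
  for (r in seq_len(nrep)) {
    v <- reps[r, ]
    clipped <- !is.na(v) & v > y_max
    graphics::points(seq_along(order)[!clipped], pmin(v, y_max)[!clipped],
                     col = pal[r], pch = 16)
    if (any(clipped)) {
      graphics::points(seq_along(order)[clipped], rep(y_max, sum(clipped)),
                       col = pal[r], pch = 17, cex = 1.3)
    }
  }
  graphics::lines(seq_along(order), pmin(cons, y_max), col = "black",
                  lwd = 1.5)
  leg <- rownames(reps)
  if (!is.null(qc)) {
    qi <- qc[match(rownames(reps), qc$replicate_id), , drop = FALSE]
    leg <- sprintf("%s  Q1=%s Q2=%s Q3=%s", rownames(reps),
                   fmt_num(qi$q1, 3L), fmt_num(qi$q2_median, 4L),
                   fmt_num(qi$q3, 3L))
  }
  graphics::legend("topright", legend = leg, col = pal, pch = 16,
                   cex = 0.8, bg = "white")
  invisible(file)
}
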