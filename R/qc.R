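#' Trace quality indicators
#'
#' Three per-trace indicators summarise capillary trace quality. All three
#' are computed from peak heights regardless of the analysis measure.
#'
#' \describe{
#'   \item{Q1}{Ligation performance: height of the 94 bp
#'     ligation-dependent control fragment divided by the median height of
#'     the observed DNA-dependent fragments (64/70/76/82 bp). Passes when
#'     the ratio exceeds 5; lower ratios can still yield usable patterns,
#'     so the flag is advisory and never auto-excludes a trace.}
#'   \item{Q2}{Overall signal level: median height of the first
#'     \eqn{\min(20, n)} probe peaks by index (ascending product size).
#'     Below 450 RFU the trace is weak; above 4000 RFU the detector
#'     saturates. Passes for medians in [450, 4000] inclusive.}
#'   \item{Q3}{Length bias: probes are split in two by index — short half
#'     indices \eqn{1..\lfloor n/2 \rfloor}, long half the remainder (the
#'     middle probe joins the long half for odd n) — and Q3 is the median
#'     long-half signal over the median short-half signal. Long products
#'     amplify less efficiently; good traces keep the ratio at or above
#'     0.5.}
#' }
#'
#' An indicator whose inputs are absent (e.g. no 94 bp peak) is `NA` and
#' its flag is `FALSE`.
#'
#' @param trace An `mlpa_trace`.
#' @param kit The `mlpa_kit` the trace was bound against.
#' @return `qc_q1()` and `qc_q3()` a single number (or `NA`); `qc_q2()` a
#'   list with `median` (RFU) and `pass`.
#' @name trace_qc
NULL

control_height <- function(trace, size) {
  cs <- trace$control_signals
  h <- cs$height[cs$size == size]
  if (length(h) == 0L) NA_real_ else h[1L]
}

#' @rdname trace_qc
#' @export
qc_q1 <- function(trace) {
  lig <- control_height(trace, 94L)
  dna <- vapply(c(64L, 70L, 76L, 82L), function(s) control_height(trace, s),
                numeric(1))
  dna <- dna[!is.na(dna)]
  if (is.na(lig) || length(dna) == 0L) return(NA_real_)
  lig / stats::median(dna)
}

probe_heights_by_index <- function(trace, kit) {
  probes <- kit$probes[order(kit$probes$index), , drop = FALSE]
  h <- trace$probe_signals$height[match(probes$probe_id,
                                        trace$probe_signals$probe_id)]
  names(h) <- probes$probe_id
  h
}

#' @rdname trace_qc
#' @export
qc_q2 <- function(trace, kit) {
  h <- probe_heights_by_index(trace, kit)
  first <- h[seq_len(min(20L, length(h)))]
  first <- first[!is.na(first)]
  if (length(first) == 0L) {
    return(list(median = NA_real_, pass = FALSE))
  }
  med <- stats::median(first)
  list(median = med, pass = med >= 450 && med <= 4000)
}

#' @rdname trace_qc
#' @export
qc_q3 <- function(trace, kit) {
  h <- probe_heights_by_index(trace, kit)
  n <- length(h)
  lower <- h[seq_len(n %/% 2L)]
  upper <- h[setdiff(seq_len(n), seq_len(n %/% 2L))]
  lower <- lower[!is.na(lower)]
  upper <- upper[!is.na(upper)]
  if (length(lower) == 0L || length(upper) == 0L) return(NA_real_)
  stats::median(upper) / stats::median(lower)
}

#' Quality-control report for a set of traces
#'
#' Computes Q1, Q2 and Q3 (see [trace_qc]) for each trace with pass flags:
#' Q1 > 5, 450 <= Q2 <= 4000, Q3 >= 0.5; `overall_pass` is their
#' conjunction. The report annotates, it never removes traces — inclusion
#' is the analyst's decision.
#'
#' @param traces List of `mlpa_trace` objects.
#' @param kit The shared `mlpa_kit`.
#' @return Data frame with one row per trace in input order: `sample_id`,
#'   `replicate_id`, `q1`, `q2_median`, `q3`, `q1_pass`, `q2_pass`,
#'   `q3_pass`, `overall_pass`.
#' @export
qc_report <- function(traces, kit) {
  rows <- lapply(traces, function(tr) {
    q1 <- qc_q1(tr)
    q2 <- qc_q2(tr, kit)
    q3 <- qc_q3(tr, kit)
    data.frame(
      sample_id = tr$sample_id,
      replicate_id = tr$replicate_id,
      q1 = q1, q2_median = q2$median, q3 = q3,
      q1_pass = !is.na(q1) && q1 > 5,
      q2_pass = q2$pass,
      q3_pass = !is.na(q3) && q3 >= 0.5,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$overall_pass <- out$q1_pass & out$q2_pass & out$q3_pass
  rownames(out) <- NULL
  out
}
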