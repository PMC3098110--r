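#' Specify a synthetic MLPA cohort
#'
#' Defines the generative model for synthetic MLPA runs with known
#' copy-number truth, the substrate for validating the import, QC,
#' normalisation and calling chain. The expected raw signal for sample i
#' at probe j is
#' \deqn{base \cdot s_i \cdot e_j \cdot d(size_j) \cdot \rho_{ij}/2,}
#' where \eqn{s_i} is a lognormal per-sample scale (sample quality and
#' input amount), \eqn{e_j} a lognormal per-probe amplification
#' efficiency, \eqn{d} a length-decay factor making long amplicons weaker
#' (the effect Q3 monitors), and \eqn{\rho_{ij} = f \cdot cn_{ij} +
#' (1-f) \cdot 2} the effective copy ratio of a tumour with fraction `f`
#' diluted by normal DNA. Multiplicative lognormal noise with the given
#' coefficient of variation (mean 1) is applied on the original scale.
#' Copy number 0 gives expected signal 0 plus a baseline noise floor;
#' peaks below the detection limit are not reported, so fully deleted
#' probes may arrive as missing.
#'
#' Normal samples have copy number 2 everywhere. The default tumour
#' profile assigns, among the 12 focus probes, 6 a single-copy loss
#' (cn 1), 4 a single-copy gain (cn 3) and leaves the rest neutral;
#' reference probes are always cn 2. Everything is deterministic given
#' `seed`.
#'
#' @param n_probes Number of kit probes (default 20).
#' @param n_reference Number of reference-flagged probes (default 8,
#'   interleaved across the size range).
#' @param size_range Product-size range in bp (default 100–290).
#' @param n_normal,n_tumour Cohort composition (default 8 + 8).
#' @param tumour_cn Optional integer vector (length `n_probes`, values
#'   0–4) of tumour copy numbers per probe in size order; `NULL` uses the
#'   default profile above.
#' @param tumour_fraction Tumour DNA fraction 0–1 (default 1).
#' @param replicates Technical replicates per sample (default 1).
#' @param base_height Expected height (RFU) of a neutral average probe
#'   (default 1500).
#' @param sample_scale_sd,probe_efficiency_sd Lognormal sdlog of the
#'   sample and probe factors (defaults 0.2 and 0.25).
#' @param length_decay Multiplicative signal retained per +100 bp of
#'   product size (default 0.8, centred mid-kit).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param control_means Named heights for the 64/70/76/82/94 bp control
#'   fragments; default 250 RFU for the DNA-dependent four and 2000 RFU
#'   (8x) for the ligation fragment.
#' @param stray_peak_rate Poisson mean of spurious peaks per trace
#'   (default 0).
#' @param detection_limit Minimum reported peak height, RFU (default 20).
#' @param baseline_floor SD of the residual signal at copy number 0
#'   (default 10 RFU).
#' @param seed Integer RNG seed (default 42).
#' @return An object of class `simulation_spec`.
#' @seealso [generate_cohort()], [truth_calls()]
#' @export
simulation_spec <- function(n_probes = 20L, n_reference = 8L,
                            size_range = c(100, 290),
                            n_normal = 8L, n_tumour = 8L,
                            tumour_cn = NULL, tumour_fraction = 1.0,
                            replicates = 1L,
                            base_height = 1500,
                            sample_scale_sd = 0.2,
                            probe_efficiency_sd = 0.25,
                            length_decay = 0.8,
                            noise_cv = 0.05,
                            control_means = c(`64` = 250, `70` = 250,
                                              `76` = 250, `82` = 250,
                                              `94` = 2000),
                            stray_peak_rate = 0,
                            detection_limit = 20,
                            baseline_floor = 10,
                            seed = 42L) {
  if (n_reference < 2L || n_reference > n_probes) {
    stop_("n_reference must be between 2 and n_probes")
  }
  sizes <- round(seq(size_range[1], size_range[2], length.out = n_probes))
  ref_idx <- unique(round(seq(1L, n_probes, length.out = n_reference)))
  if (length(ref_idx) < n_reference) {
    ref_idx <- seq_len(n_reference)
  }
  is_ref <- seq_len(n_probes) %in% ref_idx
  if (is.null(tumour_cn)) {
    tumour_cn <- rep(2L, n_probes)
    focus <- which(!is_ref)
    tumour_cn[focus[seq_len(min(6L, length(focus)))]] <- 1L
    remaining <- focus[-seq_len(min(6L, length(focus)))]
    tumour_cn[remaining[seq_len(min(4L, length(remaining)))]] <- 3L
  }
  if (length(tumour_cn) != n_probes || !all(tumour_cn %in% 0:4)) {
    stop_("tumour_cn must give one copy number in 0..4 per probe")
  }
  if (tumour_fraction < 0 || tumour_fraction > 1) {
    stop_("tumour_fraction must be in [0, 1]")
  }
  structure(
    list(n_probes = as.integer(n_probes), n_reference = length(ref_idx),
         sizes = sizes, is_reference = is_ref,
         n_normal = as.integer(n_normal), n_tumour = as.integer(n_tumour),
         tumour_cn = as.integer(tumour_cn),
         tumour_fraction = tumour_fraction,
         replicates = as.integer(replicates),
         base_height = base_height, sample_scale_sd = sample_scale_sd,
         probe_efficiency_sd = probe_efficiency_sd,
         length_decay = length_decay, noise_cv = noise_cv,
         control_means = control_means,
         stray_peak_rate = stray_peak_rate,
         detection_limit = detection_limit, baseline_floor = baseline_floor,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

synth_kit_table <- function(spec) {
  n <- spec$n_probes
  genes <- ifelse(spec$is_reference,
                  sprintf("REF%02d", cumsum(spec$is_reference)),
                  sprintf("GENE%02d", cumsum(!spec$is_reference)))
  chrom <- 1L + (seq_len(n) - 1L) %% 12L
  data.frame(
    probe_id = sprintf("P%03d", spec$sizes),
    gene = genes,
    size = spec$sizes,
    position = sprintf("chr%d:%d", chrom, 1000000L + 37000L * seq_len(n)),
    is_reference = as.integer(spec$is_reference),
    stringsAsFactors = FALSE
  )
}

length_decay_factor <- function(spec) {
  mid <- stats::median(spec$sizes)
  spec$length_decay ^ ((spec$sizes - mid) / 100)
}

synth_sample_meta <- function(spec) {
  data.frame(
    sample_id = c(sprintf("N%02d", seq_len(spec$n_normal)),
                  sprintf("T%02d", seq_len(spec$n_tumour))),
    status = c(rep("N", spec$n_normal), rep("T", spec$n_tumour)),
    tissue_origin = c(rep("blood", spec$n_normal),
                      rep("fresh frozen", spec$n_tumour)),
    tumour_percentage = c(rep(NA_real_, spec$n_normal),
                          rep(100 * spec$tumour_fraction, spec$n_tumour)),
    stringsAsFactors = FALSE
  )
}

# Expected normalised ratio per sample x probe, noise-free.
truth_ratio_matrix <- function(spec) {
  meta <- synth_sample_meta(spec)
  ratios <- vapply(seq_len(spec$n_probes), function(j) {
    ifelse(meta$status == "N", 1,
           (spec$tumour_fraction * spec$tumour_cn[j] +
              (1 - spec$tumour_fraction) * 2) / 2)
  }, numeric(nrow(meta)))
  ratios <- matrix(ratios, nrow = nrow(meta))
  dimnames(ratios) <- list(meta$sample_id, sprintf("P%03d", spec$sizes))
  ratios
}

#' Generate a synthetic MLPA cohort
#'
#' Draws a cohort from a [simulation_spec()]: the kit definition, one
#' peak-table row per emitted peak (probe products, the five control
#' fragments and any stray peaks, with sub-bp size jitter), sample
#' metadata, and the noise-free truth. When `dir` is given, the same
#' content is written as the tab-delimited files the import functions
#' consume (`kit.tsv`, `peaks.tsv`, `samples.tsv`, `truth_ratios.tsv`,
#' `truth_cn.tsv`); regeneration with an identical spec is byte-identical.
#' The global RNG state is left untouched.
#'
#' @param spec A `simulation_spec`.
#' @param dir Optional output directory (created if needed).
#' @return List with `kit` (`mlpa_kit`), `peaks` (raw peak data frame),
#'   `sample_meta`, `truth_ratio` (sample x probe expected ratios),
#'   `truth_cn`, `traces` (bound `mlpa_trace` list) and `signal_matrix`
#'   (heights, with status metadata attached).
#' @examples
#' cohort <- generate_cohort(simulation_spec(seed = 1))
#' dim(cohort$signal_matrix$values)
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  kit_tab <- synth_kit_table(spec)
  meta <- synth_sample_meta(spec)
  truth <- truth_ratio_matrix(spec)
  decay <- length_decay_factor(spec)
  eff <- stats::rlnorm(spec$n_probes, 0, spec$probe_efficiency_sd)
  n_samples <- nrow(meta)
  scale_i <- stats::rlnorm(n_samples, 0, spec$sample_scale_sd)
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  noise <- function(n) stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  # peak area = height x a size-dependent width factor
  width <- function(size) 1.5 + 0.004 * size
  ctrl <- control_fragments()

  rows <- list()
  for (i in seq_len(n_samples)) {
    rho <- if (meta$status[i] == "N") rep(1, spec$n_probes) else
      truth[meta$sample_id[i], ]
    for (rep_r in seq_len(spec$replicates)) {
      expected <- spec$base_height * scale_i[i] * eff * decay * rho
      h <- expected * noise(spec$n_probes)
      zero <- rho == 0
      if (any(zero)) {
        h[zero] <- abs(stats::rnorm(sum(zero), 0, spec$baseline_floor))
      }
      obs_size <- spec$sizes + stats::rnorm(spec$n_probes, 0, 0.15)
      keep <- h >= spec$detection_limit
      probe_rows <- data.frame(
        sample = meta$sample_id[i], size = round(obs_size[keep], 2),
        height = round(h[keep], 1),
        area = round(h[keep] * width(spec$sizes[keep]) *
                       noise(sum(keep)), 1),
        replicate = sprintf("r%d", rep_r), stringsAsFactors = FALSE)
      ch <- spec$control_means[as.character(ctrl$size)] *
        scale_i[i] * noise(nrow(ctrl))
      ctrl_rows <- data.frame(
        sample = meta$sample_id[i],
        size = round(ctrl$size + stats::rnorm(nrow(ctrl), 0, 0.1), 2),
        height = round(ch, 1),
        area = round(ch * width(ctrl$size) * noise(nrow(ctrl)), 1),
        replicate = sprintf("r%d", rep_r), stringsAsFactors = FALSE)
      n_stray <- stats::rpois(1L, spec$stray_peak_rate)
      stray_rows <- NULL
      if (n_stray > 0L) {
        targets <- c(spec$sizes, ctrl$size)
        ssize <- numeric(0)
        while (length(ssize) < n_stray) {
          cand <- stats::runif(n_stray, min(spec$sizes) - 20,
                               max(spec$sizes) + 20)
          cand <- cand[vapply(cand, function(s)
            min(abs(targets - s)) > 1.5, logical(1))]
          ssize <- c(ssize, cand)
        }
        ssize <- ssize[seq_len(n_stray)]
        sh <- stats::runif(n_stray, 50, 500)
        stray_rows <- data.frame(
          sample = meta$sample_id[i], size = round(ssize, 2),
          height = round(sh, 1),
          area = round(sh * width(ssize) * noise(n_stray), 1),
          replicate = sprintf("r%d", rep_r), stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- rbind(probe_rows, ctrl_rows, stray_rows)
    }
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL

  tmp_kit <- tempfile(fileext = ".tsv")
  write_tsv_plain(kit_tab, tmp_kit)
  kit <- suppressWarnings(read_mlpa_kit(tmp_kit, kit_name = "SYNTH1"))
  unlink(tmp_kit)

  traces <- bind_peaks(peaks, kit, tolerance = 1.0, run_id = "synthrun1")
  sm <- build_signal_matrix(traces, kit, measure = "height",
                            sample_meta = meta)

  truth_cn <- matrix(rep(2L, n_samples * spec$n_probes),
                     nrow = n_samples, dimnames = dimnames(truth))
  tumours <- meta$status == "T"
  if (any(tumours)) {
    truth_cn[tumours, ] <- matrix(spec$tumour_cn, nrow = sum(tumours),
                                  ncol = spec$n_probes, byrow = TRUE)
  }

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_tsv_plain(kit_tab, file.path(dir, "kit.tsv"))
    write_tsv_plain(peaks, file.path(dir, "peaks.tsv"))
    write_tsv_plain(meta, file.path(dir, "samples.tsv"))
    tr <- data.frame(sample_id = rownames(truth), truth,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_plain(tr, file.path(dir, "truth_ratios.tsv"))
    tc <- data.frame(sample_id = rownames(truth_cn), truth_cn,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_plain(tc, file.path(dir, "truth_cn.tsv"))
  }

  list(kit = kit, peaks = peaks, sample_meta = meta, truth_ratio = truth,
       truth_cn = truth_cn, traces = traces, signal_matrix = sm)
}

#' Expected calls from the simulation truth
#'
#' Applies the loss/gain thresholds to the noise-free expected ratios of a
#' spec — the reference answer for pipeline-recovery tests.
#'
#' @param spec A `simulation_spec`.
#' @param loss_threshold,gain_threshold Call thresholds (defaults
#'   0.8 / 1.25).
#' @return An `mlpa_call_matrix` over samples x probes.
#' @export
truth_calls <- function(spec, loss_threshold = 0.8, gain_threshold = 1.25) {
  classify_calls(truth_ratio_matrix(spec), loss_threshold, gain_threshold)
}
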