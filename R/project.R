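#' MLPA project store
#'
#' Analyses live in a plain directory of text artifacts, diffable and
#' portable: `project.json`, `samples.tsv`, per-kit definitions under
#' `kits/`, per-run peak tables under `runs/`, and per-analysis settings
#' plus results under `analyses/`. Analysis settings are hashed; once an
#' analysis is authorized every setting except visualisation/sorting
#' options is frozen and mutating calls are rejected.
#'
#' @param dir Project directory.
#' @param name Project name (init only; defaults to the directory name).
#' @return An `mlpa_project` handle (list with `dir` and `name`).
#' @name mlpa_project
NULL

#' @rdname mlpa_project
#' @export
project_init <- function(dir, name = basename(dir)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (d in c("kits", "runs", "analyses")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  jsonlite::write_json(list(name = name, format = "mlpaflow-project-1"),
                       file.path(dir, "project.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  project_open(dir)
}

#' @rdname mlpa_project
#' @export
project_open <- function(dir) {
  pj <- file.path(dir, "project.json")
  if (!file.exists(pj)) stop_("not a project directory: ", dir)
  info <- jsonlite::read_json(pj)
  structure(list(dir = dir, name = info$name), class = "mlpa_project")
}

#' Register samples in a project
#'
#' Appends or updates sample metadata (`sample_id`, `status` N/T, and
#' optionally `tissue_origin`, `dna_concentration`, `tumour_percentage`).
#' A tumour percentage on a normal sample draws a warning.
#'
#' @param project An `mlpa_project`.
#' @param meta Data frame of sample metadata.
#' @return The project, invisibly.
#' @export
project_add_samples <- function(project, meta) {
  stopifnot(inherits(project, "mlpa_project"),
            all(c("sample_id", "status") %in% names(meta)))
  if (!all(meta$status %in% c("N", "T"))) {
    stop_("sample status must be 'N' or 'T'")
  }
  for (col in c("tissue_origin", "dna_concentration", "tumour_percentage")) {
    if (!col %in% names(meta)) meta[[col]] <- NA
  }
  if (any(meta$status == "N" & !is.na(meta$tumour_percentage))) {
    warn_("tumour_percentage given for normal sample(s); ignored in analysis")
  }
  path <- file.path(project$dir, "samples.tsv")
  cols <- c("sample_id", "status", "tissue_origin", "dna_concentration",
            "tumour_percentage")
  existing <- if (file.exists(path)) {
    old <- utils::read.delim(path, stringsAsFactors = FALSE)
    old[!old$sample_id %in% meta$sample_id, cols, drop = FALSE]
  } else {
    NULL
  }
  merged <- rbind(existing, meta[, cols, drop = FALSE])
  write_tsv_plain(merged[order(merged$sample_id), , drop = FALSE], path)
  invisible(project)
}

project_samples <- function(project) {
  path <- file.path(project$dir, "samples.tsv")
  if (!file.exists(path)) stop_("project has no samples registered")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Register a kit or a run in a project
#'
#' `project_add_kit()` stores the kit definition under `kits/`.
#' `project_add_run()` stores one electrophoresis run: the peak table plus
#' the kit it was run with; an optional plate layout is kept for sample
#' sheets.
#'
#' @param project An `mlpa_project`.
#' @param kit An `mlpa_kit`.
#' @param run_id Unique run name.
#' @param peaks Raw peak data frame (see [read_peak_table()]).
#' @param kit_name Name of a kit already registered in the project.
#' @param layout Optional plate layout (`well`, `sample_id`, `kit_name`).
#' @return The project, invisibly.
#' @export
project_add_kit <- function(project, kit) {
  stopifnot(inherits(project, "mlpa_project"), inherits(kit, "mlpa_kit"))
  write_mlpa_kit(kit, file.path(project$dir, "kits",
                                paste0(kit$kit_name, ".tsv")))
  invisible(project)
}

project_kit <- function(project, kit_name) {
  path <- file.path(project$dir, "kits", paste0(kit_name, ".tsv"))
  if (!file.exists(path)) stop_("kit not registered: ", kit_name)
  suppressWarnings(read_mlpa_kit(path, kit_name = kit_name))
}

#' @rdname project_add_kit
#' @export
project_add_run <- function(project, run_id, peaks, kit_name,
                            layout = NULL) {
  stopifnot(inherits(project, "mlpa_project"))
  rd <- file.path(project$dir, "runs", run_id)
  if (dir.exists(rd)) stop_("run already exists: ", run_id)
  dir.create(rd, recursive = TRUE)
  write_tsv_plain(peaks, file.path(rd, "peaks.tsv"))
  jsonlite::write_json(list(run_id = run_id, kit_name = kit_name),
                       file.path(rd, "run.json"), auto_unbox = TRUE)
  if (!is.null(layout)) {
    write_sample_sheet(layout, file.path(rd, "sample_sheet.tsv"))
  }
  invisible(project)
}

canonical_settings <- function(s) {
  frozen <- s[setdiff(names(s), c("visual", "authorized", "authorized_at",
                                  "settings_hash"))]
  frozen <- frozen[order(names(frozen))]
  frozen
}

settings_hash <- function(s) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canonical_settings(s), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

analysis_path <- function(project, analysis_id) {
  file.path(project$dir, "analyses", analysis_id)
}

read_analysis <- function(project, analysis_id) {
  path <- file.path(analysis_path(project, analysis_id), "settings.json")
  if (!file.exists(path)) stop_("no such analysis: ", analysis_id)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

write_analysis <- function(project, analysis_id, settings) {
  settings$settings_hash <- settings_hash(settings)
  jsonlite::write_json(
    settings, file.path(analysis_path(project, analysis_id),
                        "settings.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  settings
}

assert_unauthorized <- function(settings, what) {
  if (isTRUE(settings$authorized)) {
    stop_("analysis is authorized; ", what,
          " is frozen (only visualisation and sorting options may change)")
  }
}

#' Create an analysis
#'
#' An analysis combines the traces of one or more runs of a single kit
#' with frozen-to-be settings: the signal measure, calibration-probe
#' count k, call thresholds, binding tolerance and exclusions. The
#' reference-probe set defaults to the kit flags and can instead be
#' copied from a previous analysis of the same kit.
#'
#' @param project An `mlpa_project`.
#' @param analysis_id New analysis name.
#' @param kit_name Registered kit the included runs used.
#' @param runs Run ids to include (default: all runs of that kit).
#' @param measure `"height"` or `"area"`.
#' @param k Calibration-probe count (default 5).
#' @param loss_threshold,gain_threshold Call thresholds.
#' @param tolerance Peak-binding tolerance, bp.
#' @param copy_reference_from Analysis id to copy the reference-probe set
#'   from (must use the same kit).
#' @return The settings list, invisibly.
#' @export
create_analysis <- function(project, analysis_id, kit_name, runs = NULL,
                            measure = "height", k = 5L,
                            loss_threshold = 0.8, gain_threshold = 1.25,
                            tolerance = 1.0,
                            copy_reference_from = NULL) {
  stopifnot(inherits(project, "mlpa_project"))
  ad <- analysis_path(project, analysis_id)
  if (dir.exists(ad)) stop_("analysis already exists: ", analysis_id)
  all_runs <- list.dirs(file.path(project$dir, "runs"), recursive = FALSE)
  run_info <- lapply(all_runs, function(d)
    jsonlite::read_json(file.path(d, "run.json")))
  kit_runs <- vapply(run_info, function(r) r$kit_name == kit_name,
                     logical(1))
  if (is.null(runs)) {
    runs <- vapply(run_info[kit_runs], `[[`, character(1), "run_id")
  } else {
    known <- vapply(run_info, `[[`, character(1), "run_id")
    bad <- setdiff(runs, known[kit_runs])
    if (length(bad) > 0L) {
      stop_("run(s) not found for kit ", kit_name, ": ",
            paste(bad, collapse = ", "))
    }
  }
  if (length(runs) == 0L) stop_("no runs available for kit ", kit_name)
  reference_probes <- NULL
  if (!is.null(copy_reference_from)) {
    src <- read_analysis(project, copy_reference_from)
    if (src$kit_name != kit_name) {
      stop_("cannot copy reference probes from analysis ",
            copy_reference_from, ": it uses kit ", src$kit_name,
            ", not ", kit_name)
    }
    reference_probes <- src$reference_probes
  }
  if (is.null(reference_probes)) {
    kit <- project_kit(project, kit_name)
    reference_probes <- reference_probes(kit)$probe_id
  }
  dir.create(ad, recursive = TRUE)
  settings <- list(
    analysis_id = analysis_id, kit_name = kit_name, runs = sort(runs),
    measure = measure, k = as.integer(k),
    loss_threshold = loss_threshold, gain_threshold = gain_threshold,
    tolerance = tolerance,
    reference_probes = reference_probes,
    exclude_probes = character(0), exclude_samples = character(0),
    authorized = FALSE, authorized_at = NULL,
    visual = list(sort_key = "index", y_max = 2.5)
  )
  invisible(write_analysis(project, analysis_id, settings))
}

#' Exclude probes or samples from an analysis
#'
#' Records exclusions (applied before any normalisation median) and
#' invalidates stored results so the next [run_analysis()] recomputes.
#' Rejected once the analysis is authorized.
#'
#' @param project An `mlpa_project`.
#' @param analysis_id Analysis to modify.
#' @param probes,samples Ids to exclude (replace the current sets).
#' @return The updated settings, invisibly.
#' @export
set_exclusions <- function(project, analysis_id, probes = NULL,
                           samples = NULL) {
  settings <- read_analysis(project, analysis_id)
  assert_unauthorized(settings, "the exclusion list")
  if (!is.null(probes)) settings$exclude_probes <- as.character(probes)
  if (!is.null(samples)) settings$exclude_samples <- as.character(samples)
  unlink(file.path(analysis_path(project, analysis_id), "results"),
         recursive = TRUE)
  invisible(write_analysis(project, analysis_id, settings))
}

#' Change visualisation settings
#'
#' Sort key and y-axis scale are display options and remain mutable after
#' authorization; they do not enter the settings hash.
#'
#' @inheritParams set_exclusions
#' @param sort_key `"index"`, `"gene"` or `"position"`.
#' @param y_max Sample-plot axis maximum (>= 2.5).
#' @return The updated settings, invisibly.
#' @export
set_visual <- function(project, analysis_id, sort_key = NULL, y_max = NULL) {
  settings <- read_analysis(project, analysis_id)
  if (!is.null(sort_key)) {
    settings$visual$sort_key <- match.arg(sort_key,
                                          c("index", "gene", "position"))
  }
  if (!is.null(y_max)) {
    if (y_max < 2.5) stop_("y_max must be at least 2.5")
    settings$visual$y_max <- y_max
  }
  invisible(write_analysis(project, analysis_id, settings))
}

#' Run (or re-run) an analysis
#'
#' Loads the included runs, binds peaks to the kit, assembles the signal
#' matrix for the configured measure, computes the QC report, the full
#' normalisation and the call matrix, and writes the results as
#' tab-delimited files plus a JSON audit of the normalisation model under
#' `analyses/<id>/results/`. Recomputation with unchanged settings is
#' bit-identical, so re-running an authorized analysis reproduces its
#' frozen outputs exactly.
#'
#' @inheritParams set_exclusions
#' @return List with `signal_matrix`, `qc`, `X`, `model`, `calls` and
#'   `table` (the heat-map text twin).
#' @export
run_analysis <- function(project, analysis_id) {
  settings <- read_analysis(project, analysis_id)
  kit <- project_kit(project, settings$kit_name)
  meta <- project_samples(project)
  traces <- list()
  for (run in settings$runs) {
    peaks <- read_peak_table(file.path(project$dir, "runs", run,
                                       "peaks.tsv"))
    traces <- c(traces, bind_peaks(peaks, kit,
                                   tolerance = settings$tolerance,
                                   run_id = run))
  }
  sm <- build_signal_matrix(traces, kit, measure = settings$measure,
                            sample_meta = meta)
  qc <- qc_report(traces, kit)
  fit <- normalize_mlpa(sm, k = settings$k,
                        reference_probes = settings$reference_probes,
                        exclude_probes = settings$exclude_probes,
                        exclude_samples = settings$exclude_samples)
  keep <- !(qc$sample_id %in% settings$exclude_samples)
  qc_kept <- qc[keep, , drop = FALSE]
  calls <- classify_calls(fit$X, settings$loss_threshold,
                          settings$gain_threshold)
  order <- sort_probes(kit, settings$visual$sort_key)
  order <- order[order %in% colnames(fit$X$values)]
  tab <- heatmap_table(fit$X, calls, qc_kept,
                       fit$model$calibration_probes, order)

  rd <- file.path(analysis_path(project, analysis_id), "results")
  if (!dir.exists(rd)) dir.create(rd)
  write_tsv_plain(qc, file.path(rd, "qc.tsv"))
  xout <- data.frame(sample_id = fit$X$row_meta$sample_id,
                     replicate_id = fit$X$row_meta$replicate_id,
                     apply(fit$X$values, 2L, fmt_num),
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(xout, file.path(rd, "normalized.tsv"))
  cout <- data.frame(sample_id = fit$X$row_meta$sample_id,
                     replicate_id = fit$X$row_meta$replicate_id,
                     calls$states, gain = calls$gain_count,
                     loss = calls$loss_count,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(cout, file.path(rd, "calls.tsv"))
  write_tsv_plain(tab, file.path(rd, "heatmap.tsv"))
  jsonlite::write_json(
    list(settings_hash = settings$settings_hash,
         calibration_probes = fit$model$calibration_probes,
         probe_mad = as.list(fit$model$probe_mad),
         column_factors = as.list(fit$model$column_factors),
         row_factors_final = as.list(fit$model$row_factors_final)),
    file.path(rd, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(signal_matrix = sm, qc = qc, X = fit$X,
                 model = fit$model, calls = calls, table = tab))
}

#' Authorize an analysis
#'
#' Marks a successfully computed analysis as final: the settings hash is
#' frozen and every later mutating call (exclusions, thresholds) is
#' rejected; only visualisation and sorting options stay open.
#' Authorizing twice is a warning no-op.
#'
#' @inheritParams set_exclusions
#' @return The updated settings, invisibly.
#' @export
authorize_analysis <- function(project, analysis_id) {
  settings <- read_analysis(project, analysis_id)
  if (isTRUE(settings$authorized)) {
    warn_("analysis ", analysis_id, " is already authorized")
    return(invisible(settings))
  }
  rd <- file.path(analysis_path(project, analysis_id), "results")
  if (!file.exists(file.path(rd, "heatmap.tsv"))) {
    stop_("analysis has no computed results; run run_analysis() first")
  }
  settings$authorized <- TRUE
  settings$authorized_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  invisible(write_analysis(project, analysis_id, settings))
}

#' @export
print.mlpa_project <- function(x, ...) {
  runs <- list.dirs(file.path(x$dir, "runs"), recursive = FALSE)
  analyses <- list.dirs(file.path(x$dir, "analyses"), recursive = FALSE)
  cat(sprintf("MLPA project '%s' at %s: %d run(s), %d analysis(es)\n",
              x$name, x$dir, length(runs), length(analyses)))
  invisible(x)
}
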