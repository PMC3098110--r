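#' Universal MLPA control fragments
#'
#' Every MLPA reaction carries five short control products: four
#' DNA-dependent fragments at 64, 70, 76 and 82 bp (they amplify whenever
#' template DNA is present) and one ligation-dependent fragment at 94 bp
#' (it requires successful ligation). Their relative heights drive the Q1
#' quality indicator.
#'
#' @return A data frame with columns `size` (bp) and `kind`
#'   (`"dna_dependent"` or `"ligation_dependent"`).
#' @export
#' @examples
#' control_fragments()
control_fragments <- function() {
  data.frame(
    size = c(64L, 70L, 76L, 82L, 94L),
    kind = c(rep("dna_dependent", 4L), "ligation_dependent"),
    stringsAsFactors = FALSE
  )
}

new_mlpa_kit <- function(kit_name, probes) {
  structure(
    list(kit_name = kit_name, probes = probes, controls = control_fragments()),
    class = "mlpa_kit"
  )
}

validate_kit_probes <- function(probes) {
  dup_id <- probes$probe_id[duplicated(probes$probe_id)]
  if (length(dup_id) > 0L) {
    stop_("duplicate probe_id in kit: ", paste(unique(dup_id), collapse = ", "))
  }
  dup_size <- probes$size[duplicated(probes$size)]
  if (length(dup_size) > 0L) {
    stop_("ambiguous product size in kit (peaks could not be bound uniquely): ",
          paste(unique(dup_size), collapse = ", "), " bp")
  }
  if (any(!is.finite(probes$size) | probes$size <= 0)) {
    stop_("product sizes must be positive numbers")
  }
  if (!all(probes$is_reference %in% c(0L, 1L))) {
    stop_("is_reference must be 0 or 1")
  }
  invisible(probes)
}

#' Read an MLPA kit definition
#'
#' Parses a tab-delimited kit table with columns `probe_id`, `gene`, `size`
#' (amplicon product size in bp), `position` (cytogenetic and/or physical
#' location, preserved verbatim) and `is_reference` (0/1). Probes are
#' indexed 1..n by ascending product size, the numbering used throughout
#' analysis and QC. The five universal control fragments are attached.
#'
#' Duplicate probe ids and duplicate product sizes are hard errors: peak
#' binding is keyed on size, so two probes at one size would be ambiguous.
#'
#' @param file Path to the kit table (or a connection).
#' @param kit_name Kit name; defaults to the file name without extension.
#' @return An object of class `mlpa_kit`: a list with `kit_name`, `probes`
#'   (data frame with an added `index` column, ordered by `index`) and
#'   `controls` (see [control_fragments()]).
#' @seealso [reference_probes()], [write_mlpa_kit()]
#' @export
read_mlpa_kit <- function(file, kit_name = NULL) {
  if (is.null(kit_name)) {
    kit_name <- if (is.character(file)) {
      sub("\\.[^.]*$", "", basename(file))
    } else {
      "kit"
    }
  }
  df <- read_tsv_checked(
    file, c("probe_id", "gene", "size", "position", "is_reference"),
    "kit definition"
  )
  probes <- data.frame(
    probe_id = as.character(df$probe_id),
    gene = as.character(df$gene),
    size = as.numeric(df$size),
    position = as.character(df$position),
    is_reference = as.integer(df$is_reference),
    stringsAsFactors = FALSE
  )
  validate_kit_probes(probes)
  probes <- probes[order(probes$size), , drop = FALSE]
  probes$index <- seq_len(nrow(probes))
  rownames(probes) <- NULL
  kit <- new_mlpa_kit(kit_name, probes)
  if (nrow(probes) > 50L) {
    warn_("kit has ", nrow(probes),
          " probes; MLPA multiplexes are typically 50 or fewer")
  }
  if (sum(probes$is_reference) < 2L) {
    warn_("kit defines fewer than 2 reference probes; ",
          "calibration-probe selection will not be possible")
  }
  kit
}

#' Write an MLPA kit definition
#'
#' Serialises a kit back to the tab-delimited dialect read by
#' [read_mlpa_kit()]. Reading the written file reproduces the kit
#' (round-trip identity).
#'
#' @param kit An `mlpa_kit`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_mlpa_kit <- function(kit, file) {
  stopifnot(inherits(kit, "mlpa_kit"))
  cols <- c("probe_id", "gene", "size", "position", "is_reference")
  write_tsv_plain(kit$probes[, cols], file)
}

#' Reference probes of a kit
#'
#' Returns the probes flagged as copy-number-stable reference loci, in
#' index (product-size) order. These form the pool from which the
#' calibration probes are chosen during normalisation.
#'
#' @param kit An `mlpa_kit`.
#' @return Data frame of reference-probe rows (possibly zero rows).
#' @export
reference_probes <- function(kit) {
  stopifnot(inherits(kit, "mlpa_kit"))
  p <- kit$probes[kit$probes$is_reference == 1L, , drop = FALSE]
  p[order(p$index), , drop = FALSE]
}

#' @export
print.mlpa_kit <- function(x, ...) {
  n <- nrow(x$probes)
  cat(sprintf("MLPA kit '%s': %d probes (%d reference), sizes %g-%g bp\n",
              x$kit_name, n, sum(x$probes$is_reference),
              min(x$probes$size), max(x$probes$size)))
  invisible(x)
}
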