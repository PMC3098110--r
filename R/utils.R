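#' @keywords internal
"_PACKAGE"

# Median over observed values only. Empty input is an error here, never a
# silent NaN: every median in the normalisation chain must be backed by data.
obs_median <- function(x, what = "values") {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    stop("cannot take the median of an empty set of ", what, call. = FALSE)
  }
  stats::median(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

warn_ <- function(...) warning(..., call. = FALSE)

# Tab-delimited reader shared by kit / peak / metadata parsers.
read_tsv_checked <- function(file, required, what) {
  df <- tryCatch(
    utils::read.delim(file, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = ""),
    error = function(e) stop_("cannot read ", what, " table: ",
                              conditionMessage(e))
  )
  if (nrow(df) == 0L && ncol(df) == 0L) stop_(what, " table is empty")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_(what, " table is missing required column(s): ",
          paste(missing, collapse = ", "))
  }
  df
}

write_tsv_plain <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(file)
}

# Deterministic number formatting for text twins: enough digits to be
# bit-stable across renders, trimmed of trailing zeros.
fmt_num <- function(x, digits = 6L) {
  out <- formatC(x, digits = digits, format = "fg", flag = "#")
  out <- sub("\\.?0+$", "", out)
  out[is.na(x)] <- "NA"
  out
}
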