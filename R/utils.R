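`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as plain TSV
#'
#' Tab-separated, no quoting, `NA` spelled "NA"; the column order of the input
#' is preserved.  Used for all tabular pipeline artifacts so reruns are
#' byte-identical.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a plain TSV written by [write_tsv()]
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE)
}

# stop() with a consistent prefix for user-facing configuration errors
config_error <- function(...) stop(sprintf(...), call. = FALSE)

# derive k reproducible sub-seeds from one master seed (stream splitting:
# each pipeline stage reseeds from its own slot so fixtures are reproducible
# piecewise as well as end to end)
split_seed <- function(seed, k) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}
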