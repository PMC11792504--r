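#' Read a tab-delimited table
#'
#' All pipeline TSVs are UTF-8, tab-delimited, with a mandatory header row.
#' Lines starting with `#` (provenance comments written by the pipeline) are
#' skipped.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

#' Write a tab-delimited table
#'
#' @param x data.frame.
#' @param path file path.
#' @param comment optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Derive k reproducible substream seeds (< 2^31) from one master seed.
substream_seeds <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, k)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  s
}

## round half up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
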