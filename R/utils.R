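#' @keywords internal
"_PACKAGE"

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consistent TSV writers/readers used by every module: plain tab-separated,
# no quoting, NA as empty field, optional "# key: value" comment header.
write_tsv <- function(x, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    na.strings = c("", "NA"), stringsAsFactors = FALSE, ...)
}

#' Log2 fold-change threshold equivalent to a percent fold-change
#'
#' A +/-50\% fold change corresponds to ratios of 1.5 (or 1/1.5); on the
#' log2 scale both map to the same absolute threshold, `|log2(1.5)| = 0.585`,
#' conventionally rounded to 0.58. TMT MS2 quantification compresses ratios,
#' so moderate fold-change cutoffs of this size are standard.
#'
#' @param percent Percent change defining the fold-change cutoff (50 means
#'   a 1.5-fold increase or equivalently a reduction below 1/1.5).
#' @param digits Decimal places to round to (2 by default, the conventional
#'   printed precision).
#' @return Absolute log2 fold-change threshold.
#' @examples
#' log2fc_threshold(50) # 0.58
#' @export
log2fc_threshold <- function(percent = 50, digits = 2) {
  stopifnot(percent > 0)
  round(log2(1 + percent / 100), digits)
}
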