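#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats median p.adjust pbinom pt rbinom rlnorm rnbinom runif
#'   setNames var wilcox.test ave
#' @importFrom utils read.delim write.table head packageVersion
#' @importClassesFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Internal logging: every dropped-read / skipped-record count referenced by the
## modules goes through here so pipeline logs stay machine-parseable.
m7g_log <- function(stage, msg, level = "INFO") {
  message(sprintf("[%s] %s: %s", level, stage, msg))
  invisible(NULL)
}

## Classed condition for configuration/validation failures so callers (and the
## CLI wrapper) can map them to a distinct exit code.
validation_error <- function(msg) {
  stop(structure(
    class = c("m7g_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream. All simulator randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Per-stage seeds are derived from one root seed so stages are independently
## reproducible; kept below 2^31 - 1.
derive_seed <- function(root, offset) {
  as.integer((as.numeric(root) * 1103L + offset * 7919L) %% 2147483647)
}

## sample() treats a scalar first argument as 1:n; this keeps degenerate
## ranges (lo == hi) safe.
sample_range <- function(lo, hi, n) {
  vals <- seq.int(lo, hi)
  vals[sample.int(length(vals), n, replace = TRUE)]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()],
#' used for anticodon to codon conversion (DNA alphabet, T not U).
#'
#' @param x Character vector of DNA strings over A/C/G/T.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("GCA")  # "TGC", the codon decoded by tRNA-Cys-GCA
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
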