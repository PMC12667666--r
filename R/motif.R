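#' Extract fixed-width sequence windows around called sites
#'
#' For each site, the window spans positions `site + offset` to
#' `site + offset + width - 1`. The default `offset = -3` with `width = 7`
#' centres the window on the site (the m7G occupies column 4), matching the
#' convention under which the simulator plants its motif context, so
#' round-trips are exact. Windows overrunning either end of the tRNA are
#' skipped with a logged count.
#'
#' @param sites data.frame with columns `trna_id` and `position`.
#' @param trnas A [TrnaSet-class].
#' @param width Window width, odd, >= 3 (default 7).
#' @param offset Offset of the window start relative to the site (default -3).
#' @return A [Biostrings::DNAStringSet] named `trna_id:position`.
#' @export
extractWindows <- function(sites, trnas, width = 7L, offset = -3L) {
  if (width < 3) validation_error("width must be >= 3")
  if (width %% 2 == 0) validation_error("width must be odd")
  seqs <- setNames(as.character(trnaSeqs(trnas)), trnaIds(trnas))
  from <- sites$position + offset
  to <- from + width - 1L
  lens <- nchar(seqs[sites$trna_id])
  ok <- from >= 1L & to <= lens
  if (any(!ok))
    m7g_log("motif", sprintf("%d window(s) overran a tRNA end and were skipped",
                             sum(!ok)))
  win <- substr(seqs[sites$trna_id[ok]], from[ok], to[ok])
  out <- Biostrings::DNAStringSet(unname(win))
  names(out) <- paste0(sites$trna_id[ok], ":", sites$position[ok])
  out
}

#' Build a position-frequency-matrix motif from aligned windows
#'
#' Counts each base per column (with a pseudocount added to every cell),
#' normalises columns to probabilities, computes per-column information
#' content `2 + sum(p * log2(p))` in bits, and derives the consensus: the
#' argmax base where its probability reaches `consensus_threshold`, else
#' `'N'`. Deterministic; the order of input windows is immaterial.
#'
#' @param windows A [Biostrings::DNAStringSet] (or character vector) of
#'   equal-length windows; at least 5 required.
#' @param consensus_threshold Minimum column probability for a consensus
#'   letter (default 0.8).
#' @param pseudocount Added to every PFM cell (default 0.25).
#' @return A [MotifModel-class].
#' @examples
#' w <- rep(c("TGAACCA", "TGAACCG", "TGAACCT", "TGAACCC"), 5)
#' motifConsensus(buildMotif(w))  # "TGAACCN"
#' @export
buildMotif <- function(windows, consensus_threshold = 0.8, pseudocount = 0.25) {
  windows <- Biostrings::DNAStringSet(windows)
  if (length(windows) < 5)
    validation_error("at least 5 windows are required for a reliable motif")
  w <- unique(Biostrings::width(windows))
  if (length(w) != 1) validation_error("windows must all have the same width")
  cm <- Biostrings::consensusMatrix(windows, baseOnly = TRUE)
  if (sum(cm["other", ]) > 0)
    validation_error("windows must contain only A/C/G/T")
  pfm <- cm[c("A", "C", "G", "T"), , drop = FALSE] + pseudocount
  ppm <- sweep(pfm, 2, colSums(pfm), "/")
  ic <- pmax(0, 2 + colSums(ppm * log2(ppm)))
  best <- apply(ppm, 2, which.max)
  cons <- rownames(ppm)[best]
  cons[ppm[cbind(best, seq_len(w))] < consensus_threshold] <- "N"
  new("MotifModel", width = as.integer(w), pfm = pfm, ppm = ppm,
      ic = unname(ic), consensus = paste(cons, collapse = ""),
      nseq = length(windows))
}

#' Write a motif in MEME minimal format
#'
#' Version line, alphabet, strand and background lines, and the
#' letter-probability matrix block, as consumed by the MEME suite.
#'
#' @param model A [MotifModel-class].
#' @param path Output path.
#' @param name Motif name (default `"m7G_site"`).
#' @return `path`, invisibly.
#' @export
writeMemeMotif <- function(model, path, name = "m7G_site") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       model@width, model@nseq)), con)
  for (k in seq_len(model@width))
    writeLines(paste(sprintf("%.6f", model@ppm[, k]), collapse = " "), con)
  invisible(path)
}

#' Write a motif PFM as TSV
#'
#' @param model A [MotifModel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePfmTsv <- function(model, path) {
  df <- data.frame(base = rownames(model@pfm), model@pfm, check.names = FALSE)
  colnames(df)[-1] <- paste0("pos", seq_len(model@width))
  write_tsv(df, path)
}
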