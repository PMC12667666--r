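#' Reduce alignments to per-position 5'-end pileup tracks
#'
#' For every tRNA with at least one alignment, computes the four
#' per-position vectors of a [PileupSet-class]: `starts` (alignments whose
#' 5' end is at i), `coverage` (alignments overlapping i), `readthrough`
#' (alignments covering i that start before i) and
#' `stop_fraction = starts / (starts + readthrough)` (0 where undefined).
#' The stop fraction at position j is the fraction of molecules covering j
#' that were cleaved (or otherwise truncated) immediately 5' of j, i.e. the
#' cleavage signal for an m7G at j - 1.
#'
#' @param alignments data.frame from [alignReads()] or [importSam()].
#' @param trnas A [TrnaSet-class] (provides tRNA lengths).
#' @param emit_zero Also emit all-zero tracks for tRNAs without alignments.
#' @param library Optional library label stored in the result.
#' @return A [PileupSet-class].
#' @examples
#' cfg <- simConfig(n_trnas = 2, reads_per_library = 500)
#' trnas <- simulateTrnaReference(cfg)
#' aln <- data.frame(read_id = c("r1", "r2"), trna_id = trnaIds(trnas)[1],
#'                   start = c(1L, 47L), end = c(70L, 70L), mismatches = 0L)
#' buildPileup(aln, trnas)
#' @export
buildPileup <- function(alignments, trnas, emit_zero = FALSE,
                        library = NA_character_) {
  ids <- trnaIds(trnas)
  lens <- setNames(Biostrings::width(trnaSeqs(trnas)), ids)
  unknown <- setdiff(unique(alignments$trna_id), ids)
  if (length(unknown))
    validation_error(paste0("alignments reference unknown tRNA(s): ",
                            paste(unknown, collapse = ", ")))
  want <- if (emit_zero) ids else sort(unique(alignments$trna_id))
  tracks <- lapply(want, function(id) {
    L <- lens[[id]]
    a <- alignments[alignments$trna_id == id, , drop = FALSE]
    starts <- tabulate(a$start, nbins = L)
    ends <- tabulate(a$end, nbins = L)
    coverage <- cumsum(starts) - cumsum(c(0L, ends[-L]))
    readthrough <- coverage - starts  # covering i with start < i
    denom <- starts + readthrough
    stop_fraction <- ifelse(denom > 0, starts / denom, 0)
    list(starts = starts, coverage = coverage, readthrough = readthrough,
         stop_fraction = stop_fraction)
  })
  obj <- new("PileupSet", tracks = S4Vectors::SimpleList(setNames(tracks, want)),
             library = as.character(library))
  validObject(obj)
  obj
}

#' Write pileup tracks as TSV
#'
#' One row per (tRNA, position): `trna_id`, `pos`, `starts`, `readthrough`,
#' `coverage`, `stop_fraction`.
#'
#' @param pileup A [PileupSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePileupTsv <- function(pileup, path) {
  dfs <- lapply(trackNames(pileup), function(id) {
    d <- pileupTrack(pileup, id)
    cbind(trna_id = id, d)
  })
  out <- if (length(dfs)) do.call(rbind, dfs) else
    data.frame(trna_id = character(0), pos = integer(0), starts = integer(0),
               readthrough = integer(0), coverage = integer(0),
               stop_fraction = numeric(0))
  out <- out[, c("trna_id", "pos", "starts", "readthrough", "coverage",
                 "stop_fraction")]
  write_tsv(out, path)
}
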