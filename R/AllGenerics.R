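#' @describeIn TrnaSet-class tRNA identifiers.
#' @param x,object A `TrnaSet`.
#' @export
setGeneric("trnaIds", function(x) standardGeneric("trnaIds"))

#' @describeIn TrnaSet-class anticodons (5'->3', DNA alphabet), named by id.
#' @export
setGeneric("anticodons", function(x) standardGeneric("anticodons"))

#' @describeIn TrnaSet-class the sequences as a [Biostrings::DNAStringSet].
#' @export
setGeneric("trnaSeqs", function(x) standardGeneric("trnaSeqs"))

#' @describeIn TrnaSet-class identity table as a data.frame.
#' @export
setGeneric("trnaInfo", function(x) standardGeneric("trnaInfo"))

#' @describeIn PileupSet-class ids of tRNAs with a track.
#' @param x,object A `PileupSet`.
#' @export
setGeneric("trackNames", function(x) standardGeneric("trackNames"))

#' @describeIn PileupSet-class one track as a data.frame with columns
#'   `pos`, `starts`, `readthrough`, `coverage`, `stop_fraction`.
#' @param id tRNA identifier.
#' @export
setGeneric("pileupTrack", function(x, id) standardGeneric("pileupTrack"))

#' @describeIn SiteComparison-class sites called in both conditions.
#' @param x,object A `SiteComparison`.
#' @export
setGeneric("commonSites", function(x) standardGeneric("commonSites"))

#' @describeIn SiteComparison-class sites unique to one condition.
#' @param which `"a"` or `"b"`.
#' @export
setGeneric("uniqueSites", function(x, which = c("b", "a")) standardGeneric("uniqueSites"))

#' @describeIn SiteComparison-class per-site log2 stop-fraction ratios.
#' @export
setGeneric("deltaScores", function(x) standardGeneric("deltaScores"))

#' @describeIn MotifModel-class consensus string (A/C/G/T/N).
#' @param x,object A `MotifModel`.
#' @export
setGeneric("motifConsensus", function(x) standardGeneric("motifConsensus"))

#' @describeIn MotifModel-class pseudocounted position frequency matrix.
#' @export
setGeneric("motifPfm", function(x) standardGeneric("motifPfm"))

#' @describeIn MotifModel-class position probability matrix.
#' @export
setGeneric("motifPpm", function(x) standardGeneric("motifPpm"))

#' @describeIn MotifModel-class per-column information content (bits).
#' @export
setGeneric("informationContent", function(x) standardGeneric("informationContent"))

setMethod("trnaIds", "TrnaSet", function(x) as.character(x@info$trna_id))
setMethod("anticodons", "TrnaSet", function(x)
  setNames(as.character(x@info$anticodon), x@info$trna_id))
setMethod("trnaSeqs", "TrnaSet", function(x) x@seqs)
setMethod("trnaInfo", "TrnaSet", function(x) as.data.frame(x@info))

#' @describeIn TrnaSet-class number of tRNAs.
#' @export
setMethod("length", "TrnaSet", function(x) length(x@seqs))

#' @describeIn TrnaSet-class subset by index or id.
#' @param i index, logical or character vector of ids.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TrnaSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, trnaIds(x))
  new("TrnaSet", seqs = x@seqs[i], info = x@info[i, , drop = FALSE])
})

setMethod("show", "TrnaSet", function(object) {
  cat(sprintf("TrnaSet with %d mature tRNA(s)\n", length(object)))
  if (length(object)) {
    w <- Biostrings::width(object@seqs)
    cat(sprintf("  lengths: %d-%d nt; %d distinct anticodon(s)\n",
                min(w), max(w), length(unique(object@info$anticodon))))
    n <- min(5L, length(object))
    cat("  ", paste(head(trnaIds(object), n), collapse = ", "),
        if (length(object) > n) ", ..." else "", "\n", sep = "")
  }
})

setMethod("trackNames", "PileupSet", function(x) names(x@tracks))

setMethod("pileupTrack", "PileupSet", function(x, id) {
  tr <- x@tracks[[id]]
  if (is.null(tr)) validation_error(sprintf("no pileup track for '%s'", id))
  data.frame(pos = seq_along(tr$starts), starts = tr$starts,
             readthrough = tr$readthrough, coverage = tr$coverage,
             stop_fraction = tr$stop_fraction)
})

#' @describeIn PileupSet-class number of tracks.
#' @export
setMethod("length", "PileupSet", function(x) length(x@tracks))

setMethod("show", "PileupSet", function(object) {
  cat(sprintf("PileupSet: %d track(s)%s\n", length(object),
              if (!is.na(object@library)) paste0(" [library ", object@library, "]") else ""))
  if (length(object)) {
    tot <- sum(vapply(object@tracks, function(t) sum(t$starts), numeric(1)))
    cat(sprintf("  total aligned reads: %d\n", as.integer(tot)))
  }
})

setMethod("commonSites", "SiteComparison", function(x) x@common)
setMethod("uniqueSites", "SiteComparison", function(x, which = c("b", "a")) {
  which <- match.arg(which)
  if (which == "a") x@unique_to_a else x@unique_to_b
})
setMethod("deltaScores", "SiteComparison", function(x) x@delta)

setMethod("show", "SiteComparison", function(object) {
  cat(sprintf("SiteComparison: %s vs %s\n", object@condition_a, object@condition_b))
  cat(sprintf("  common: %d | unique to %s: %d | unique to %s: %d\n",
              nrow(object@common), object@condition_a, nrow(object@unique_to_a),
              object@condition_b, nrow(object@unique_to_b)))
})

setMethod("motifConsensus", "MotifModel", function(x) x@consensus)
setMethod("motifPfm", "MotifModel", function(x) x@pfm)
setMethod("motifPpm", "MotifModel", function(x) x@ppm)
setMethod("informationContent", "MotifModel", function(x) x@ic)

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel (width %d, %d windows)\n", object@width, object@nseq))
  cat("  consensus:", object@consensus, "\n")
  cat("  IC (bits):", paste(sprintf("%.2f", object@ic), collapse = " "), "\n")
})
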