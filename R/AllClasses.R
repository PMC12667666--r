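#' TrnaSet: a validated set of mature tRNA references
#'
#' Holds mature tRNA sequences (DNA alphabet, uppercase) together with the
#' identity parsed from GtRNAdb-style headers such as `tRNA-Cys-GCA-1-1`:
#' the three-letter amino-acid code and the 5'->3' anticodon. This is the
#' substrate of cleavage-site calling and the source of anticodon->codon
#' decoding maps.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of mature tRNA sequences, named by
#'   tRNA id.
#' @slot info A [S4Vectors::DataFrame] with columns `trna_id`, `amino_acid`,
#'   `anticodon`, `length` (one row per sequence, same order as `seqs`).
#'
#' @seealso [readTrnaFasta()], [simulateTrnaReference()], [buildDecodingMap()]
#' @exportClass TrnaSet
setClass("TrnaSet", representation(seqs = "DNAStringSet", info = "DataFrame"))

setValidity("TrnaSet", function(object) {
  msgs <- character(0)
  n <- length(object@seqs)
  if (nrow(object@info) != n)
    msgs <- c(msgs, "info must have one row per sequence")
  req <- c("trna_id", "amino_acid", "anticodon", "length")
  if (!all(req %in% colnames(object@info)))
    return(paste("info must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(object@info$trna_id))
    msgs <- c(msgs, "duplicate trna_id in reference set")
  if (n > 0) {
    if (!all(grepl("^[ACGT]{3}$", object@info$anticodon)))
      msgs <- c(msgs, "anticodons must be 3-nt DNA strings")
    w <- Biostrings::width(object@seqs)
    if (!all(w == object@info$length))
      msgs <- c(msgs, "length column disagrees with sequence widths")
    if (any(w < 60L | w > 120L))
      msgs <- c(msgs, "tRNA sequence lengths must lie in [60, 120] nt")
  }
  if (length(msgs)) msgs else TRUE
})

#' PileupSet: per-tRNA 5'-end pileup tracks
#'
#' For each tRNA with at least one alignment, four per-position vectors of
#' length L (the tRNA length): `starts` (reads whose 5' end is at i),
#' `coverage` (reads overlapping i), `readthrough` (reads covering i that
#' start before i) and `stop_fraction` = starts / (starts + readthrough)
#' (0 where the denominator is 0). The stop fraction at position j is the
#' reverse-transcription-stop / cleavage signal used to infer an m7G at j - 1.
#'
#' @slot tracks A [S4Vectors::SimpleList]; each element is a list with
#'   elements `starts`, `coverage`, `readthrough`, `stop_fraction` (numeric
#'   vectors of equal length), named by tRNA id.
#' @slot library A length-one character label for the sequencing library
#'   (condition/replicate) the tracks came from; may be `NA`.
#'
#' @seealso [buildPileup()], [callSites()]
#' @exportClass PileupSet
setClass("PileupSet", representation(tracks = "SimpleList", library = "character"))

setValidity("PileupSet", function(object) {
  for (id in names(object@tracks)) {
    tr <- object@tracks[[id]]
    if (!all(c("starts", "coverage", "readthrough", "stop_fraction") %in% names(tr)))
      return(sprintf("track '%s' lacks required vectors", id))
    L <- length(tr$starts)
    if (length(tr$coverage) != L || length(tr$readthrough) != L ||
        length(tr$stop_fraction) != L)
      return(sprintf("track '%s' has vectors of unequal length", id))
    if (any(tr$stop_fraction < 0 | tr$stop_fraction > 1))
      return(sprintf("track '%s' has stop fractions outside [0, 1]", id))
    if (any(tr$starts + tr$readthrough > tr$coverage + 1e-9))
      return(sprintf("track '%s' violates starts + readthrough <= coverage", id))
  }
  TRUE
})

#' SiteComparison: common and condition-unique m7G sites
#'
#' Exact set algebra on called sites keyed by (trna_id, position), plus a
#' per-site cross-condition effect `delta_score` = log2((s_b + eps)/(s_a + eps))
#' on the stop-fraction scale.
#'
#' @slot condition_a,condition_b Condition labels.
#' @slot common,unique_to_a,unique_to_b data.frames of sites (columns as
#'   returned by [mergeReplicates()]).
#' @slot delta data.frame with columns `trna_id`, `position`, `score_a`,
#'   `score_b`, `delta_score` for every site present in either condition.
#'
#' @seealso [compareConditions()]
#' @exportClass SiteComparison
setClass("SiteComparison", representation(
  condition_a = "character", condition_b = "character",
  common = "data.frame", unique_to_a = "data.frame", unique_to_b = "data.frame",
  delta = "data.frame"
))

#' MotifModel: position-frequency-matrix consensus of site windows
#'
#' A fixed-width motif built from aligned sequence windows around called m7G
#' sites: pseudocounted position frequency matrix (PFM), column-normalised
#' probability matrix (PPM), per-column information content in bits
#' (2 + sum p log2 p), and a consensus string where a column whose best
#' letter falls below the consensus threshold is written 'N'.
#'
#' @slot width Motif width (columns).
#' @slot pfm 4 x width numeric matrix (rows A, C, G, T), pseudocounted counts.
#' @slot ppm 4 x width column-stochastic matrix.
#' @slot ic Numeric vector of per-column information content (bits, in [0, 2]).
#' @slot consensus Consensus string over A/C/G/T/N.
#' @slot nseq Number of windows the model was built from.
#'
#' @seealso [buildMotif()], [extractWindows()]
#' @exportClass MotifModel
setClass("MotifModel", representation(
  width = "integer", pfm = "matrix", ppm = "matrix",
  ic = "numeric", consensus = "character", nseq = "integer"
))

setValidity("MotifModel", function(object) {
  if (ncol(object@ppm) != object@width) return("ppm width mismatch")
  if (any(abs(colSums(object@ppm) - 1) > 1e-9))
    return("ppm columns must each sum to 1")
  if (any(object@ic < -1e-9 | object@ic > 2 + 1e-9))
    return("information content must lie in [0, 2] bits")
  if (nchar(object@consensus) != object@width)
    return("consensus length must equal width")
  TRUE
})

#' TeExperiment: paired RNC-seq / RNA-seq count container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `counts`
#' assay (genes x samples, non-negative integers) and colData columns
#' `assay_type` ("RNC" or "RNA"), `condition` and `replicate`. Validity
#' requires every (condition, replicate) pair to have exactly one RNC and
#' one RNA sample, so per-replicate translation efficiency is well defined.
#'
#' @seealso [TeExperiment()], [computeTe()], [simulateTeCounts()]
#' @exportClass TeExperiment
setClass("TeExperiment", contains = "SummarizedExperiment")

setValidity("TeExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  req <- c("assay_type", "condition", "replicate")
  if (!all(req %in% colnames(cd)))
    return(paste("colData must have columns", paste(req, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  if (!all(cd$assay_type %in% c("RNC", "RNA")))
    return("assay_type must be 'RNC' or 'RNA'")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    return("counts must be non-negative integers")
  if (anyDuplicated(rownames(object)))
    return("duplicate gene ids")
  key <- paste(cd$condition, cd$replicate)
  for (k in unique(key)) {
    at <- cd$assay_type[key == k]
    if (sum(at == "RNC") != 1L || sum(at == "RNA") != 1L)
      return(sprintf("pair '%s' must have exactly one RNC and one RNA sample", k))
  }
  TRUE
})
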